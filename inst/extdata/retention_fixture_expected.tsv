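intron_id	expected_call
fx01	retained
fx02	retained
fx03	retained
fx04	retained
fx05	retained
fx06	retained
fx07	retained
fx08	retained
fx09	retained
fx10	retained
fx11	retained
fx12	retained
fx13	retained
fx14	retained
fx15	retained
fx16	retained
fx17	retained
fx18	retained
fx19	retained
fx20	retained
fx21	non_retained
fx22	non_retained
fx23	non_retained
fx24	non_retained
fx25	non_retained
fx26	non_retained
fx27	non_retained
fx28	non_retained
fx29	non_retained
fx30	non_retained
fx31	non_retained
fx32	non_retained
fx33	non_retained
fx34	non_retained
fx35	non_retained
fx36	non_retained
fx37	non_retained
fx38	non_retained
fx39	non_retained
fx40	non_retained
fx41	ambiguous
fx42	ambiguous
fx43	ambiguous
fx44	ambiguous
fx45	ambiguous
fx46	ambiguous
fx47	ambiguous
fx48	ambiguous
fx49	ambiguous
fx50	ambiguous
fx51	ambiguous
fx52	ambiguous
fx53	ambiguous
fx54	ambiguous
fx55	ambiguous
fx56	ambiguous
fx57	ambiguous
fx58	ambiguous
fx59	ambiguous
fx60	ambiguous
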