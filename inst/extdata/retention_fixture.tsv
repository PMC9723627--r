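intron_id	irratio	depth	coverage_fraction	psi5	psi3	fpkm	length
fx01	0.509	18	0.968	0.999	0.953	193.4	3001
fx02	0.351	22.3	0.955	0.951	0.919	127.7	7150
fx03	0.172	16.8	0.918	0.923	0.908	164.5	6051
fx04	0.641	34.5	0.901	0.981	0.9	40.9	86
fx05	0.326	34.3	0.955	0.904	0.944	138.5	4919
fx06	0.525	78.4	0.986	0.948	0.977	186.1	7630
fx07	0.399	51.2	0.911	0.971	0.982	150.8	2870
fx08	0.698	16	0.955	0.992	0.939	183.1	2528
fx09	0.572	61.4	0.944	0.985	0.955	184.4	792
fx10	0.689	16	0.963	0.942	0.941	105.9	6005
fx11	0.475	18.2	0.963	0.973	0.955	129.8	3130
fx12	0.502	37.3	0.914	0.906	0.932	17.7	4972
fx13	0.161	69	0.918	0.949	0.919	43.5	1209
fx14	0.14	66.7	0.973	0.909	0.963	137.9	6323
fx15	0.513	19.8	0.916	0.947	0.991	60.6	5812
fx16	0.274	23.2	0.923	0.935	0.944	197.9	5210
fx17	0.513	52.1	0.995	0.914	0.923	19	4103
fx18	0.507	79.7	0.951	0.976	0.933	117.2	4737
fx19	0.605	74.2	0.969	0.907	0.921	117.2	7884
fx20	0.404	24.3	0.996	0.956	0.925	154.3	6661
fx21	0.0092	7.7	0.263	0.533	0.594	91.9	1036
fx22	0.0077	6.1	0.549	0.134	0.924	163	4999
fx23	0.0088	0.5	0.637	0.568	0.525	1.2	251
fx24	0.005	2.4	0.751	0.139	0.478	54.5	3624
fx25	0.0052	9.6	0.778	0.875	0.796	35.5	2035
fx26	0.0048	6.7	0.353	0.606	0.583	148.4	718
fx27	0.0093	7.4	0.789	0.064	0.565	62.3	1026
fx28	0.0011	6.7	0.264	0.569	0.074	22.2	3302
fx29	0.0094	6.9	0.409	0.138	0.283	57.8	6437
fx30	0.004	9.3	0.979	0.173	0.401	34.7	168
fx31	0.0033	1.1	0.611	0.833	0.703	24.4	836
fx32	0.002	2.9	0.341	0.427	0.034	155.4	7002
fx33	0.0065	4.8	0.173	0.775	0.048	145	837
fx34	0.008	7.8	0.055	0.525	0.665	184.3	7070
fx35	0.0047	6.5	0.966	0.414	0.18	159.3	4796
fx36	0.0084	3.3	0.134	0.528	0.945	165.8	915
fx37	3e-04	5.7	0.544	0.252	0.704	16.7	5468
fx38	0.0062	7.5	0.776	0.985	0.295	76.2	4033
fx39	0.004	9.8	0.618	0.767	0.26	15.3	3081
fx40	0.0098	2.9	0.017	0.913	0.356	178.3	1278
fx41	0.036	14.5	0.95	0.95	0.95	10	500
fx42	0.057	21.8	0.95	0.95	0.95	10	500
fx43	0.069	21.9	0.95	0.95	0.95	10	500
fx44	0.089	29.5	0.95	0.95	0.95	10	500
fx45	0.3	25	0.793	0.95	0.95	10	500
fx46	0.3	25	0.829	0.95	0.95	10	500
fx47	0.3	25	0.568	0.95	0.95	10	500
fx48	0.3	25	0.766	0.95	0.95	10	500
fx49	0.3	25	0.95	0.347	0.95	10	500
fx50	0.3	25	0.95	0.759	0.95	10	500
fx51	0.3	25	0.95	0.817	0.95	10	500
fx52	0.3	25	0.95	0.366	0.95	10	500
fx53	0.3	25	0.95	0.95	0.95	0.39	500
fx54	0.3	25	0.95	0.95	0.95	0.16	500
fx55	0.3	25	0.95	0.95	0.95	0.05	500
fx56	0.3	25	0.95	0.95	0.95	0.11	500
fx57	0.3	25	0.95	0.95	0.95	10	20065
fx58	0.3	25	0.95	0.95	0.95	10	13687
fx59	0.3	25	0.95	0.95	0.95	10	24856
fx60	0.3	25	0.95	0.95	0.95	10	20944
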