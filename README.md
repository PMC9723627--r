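# dynamIR

Intron retention (IR) — an intron surviving into the mature transcript — is
widespread in differentiating immune cells, and whether a given intron is
retained often switches between cell types. dynamIR is an R package for
asking *what predicts retention*: it quantifies IR from coverage and
splice-junction data, calls retained / non-retained / dynamic introns,
tests differential retention between cell types, calls nucleosome-free
regions (NFRs) and positioned nucleosomes from NOMe-seq GCH methylation,
assembles region-anchored sequence/methylation/histone feature tables,
trains two complementary classifiers with scaled variable importances,
clusters splice-site-proximal accessibility profiles, and adjusts H3K36me3
signal for nucleosome occupancy. A synthetic multi-omics generator plants
known IR–chromatin structure across five cell types so the whole chain is
testable end to end without any controlled-access data.

It is written for genomics analysts working with RNA-seq + WGBS + NOMe-seq
+ ChIP-seq panels, in Bioconductor idiom (`GRanges`, `DNAStringSet`, S4
containers with accessors).

## The statistics at the core

* **IR level**: `IRratio = A_intron / (A_intron + A_exon)`, where
  `A_intron` is the 30%-trimmed mean per-base intron depth after masking
  annotated overlapping features and `A_exon` is the exact-matching
  splice-junction count. Retained: `IRratio >= 0.1`, depth `>= 10`,
  coverage `>= 90%`, flank PSIs `>= 0.9`; non-retained: `IRratio <= 0.01`
  and depth `< 10`; introns from unexpressed hosts (FPKM < 1) or longer
  than 10 kb are excluded.
* **Differential retention**: the Audic–Claverie posterior predictive
  (`Y | x ~ NB(x + 1, N1 / (N1 + N2))`), two-sided by symmetric cross-tail
  doubling; significant at `p <= 0.05` and `|dIR| >= 0.1` with retention in
  at least one of the two cell types. Dynamic introns are retained in >= 1
  and non-retained in >= 1 cell type.
* **Chromatin calling**: GCH sites chained by elevation and gap rules
  (150 bp gap / >40 bp for NFRs; 20 bp gap / >140 bp for nucleosomes on
  methylation-depleted sites), each candidate tested against its local
  background (±4000 / ±1000 bp) with a one-sided Fisher exact test.
* **Models**: elastic-net logistic regression (glmnet; alpha grid
  {0.1, 0.55, 1.0}, 10-fold stratified CV on ROC AUC) and a
  conditional-inference random forest (association-test split selection
  with Bonferroni stopping, 0.632 subsampling, out-of-bag permutation
  importance), both with importances scaled to sum to 1.
* **Profiles**: percent-GCH matrices over ±200 bp around splice sites,
  complete-linkage hierarchical clustering (outlier-tolerant cut), and a
  Poisson GLM that regresses H3K36me3 counts on GCH methylation to test
  whether group contrasts survive adjustment for accessibility.

## Worked example

```r
library(dynamIR)

params <- simulationParams(n_genes = 30, seed = 7)
sim <- simulateIRData(params)
sim
#> SyntheticIRData: 90 introns in 30 genes; 5 cell types
#>   contig: chrS (104843 bp)
#>   retained states: 151 of 450 intron x cell-type pairs; 14 dynamic introns

ir <- do.call(rbind, lapply(simParams(sim)@cell_types,
                            function(ct) quantifyIR(sim, ct)))
head(subset(ir, sample == "Mo")[, c("intron_id", "irratio", "depth",
                                    "coverage_fraction", "call")], 4)
#>   intron_id   irratio   depth coverage_fraction         call
#> 1   g001_i1 0.3431331 26.6413         1.0000000     retained
#> 2   g001_i2 0.0000000  0.0000         0.1670702 non_retained
#> 3   g001_i3 0.0000000  0.0000         0.1351931 non_retained
#> 4   g002_i1 0.0000000  0.0000         0.1425439 non_retained

length(findDynamicIntrons(ir))
#> [1] 14
diffs <- callDifferential(ir, "Mo", "Ma")
sum(diffs$significant)
#> [1] 6

nfr <- callNFRs(methylomeCalls(sim, "Mo"))
nrow(nfr)
#> [1] 33

res <- runIRPipeline(sim)
res$concordance           # retention calls vs the generator's ground truth
#> [1] 1

bal <- downsampleBalance(res$features, seed = 1)
crf <- fitConditionalForest(bal, n_trees = 150, seed = 1)
crf
#> IRModelFit <cRF> trained on ''
#>   hyperparameters: n_trees=150, mtry=7, split_alpha=0.05, min_node=20
#>   CV ROC AUC: 0.921
#>   top features: gch_meth_5ss 0.311, cpg_meth_5ss 0.295, nfr_5ss 0.233,
#>                 ss3_strength 0.049, nfr_3ss 0.028
```

The first intron of gene `g001` is retained in monocyte-like cells
(IRratio 0.34, depth 27, full coverage) while its neighbours are cleanly
non-retained; 14 introns switch state across the five cell types, 6 are
significantly differentially retained between Mo and Ma. The forest trained
on the assembled feature table classifies retained vs non-retained states
at out-of-bag AUC 0.92, and its top-ranked features are exactly the planted
chromatin couplings: GCH methylation, CpG hypomethylation and NFR presence
at the 5' splice site.

See the methods vignette (`vignettes/dynamIR-methods.Rmd`) for the models,
assumptions, parameter defaults and the design decisions behind them.

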