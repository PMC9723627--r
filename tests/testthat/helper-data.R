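# shared fixtures, built once per test run

.sim_cache <- new.env(parent = emptyenv())

# small linked data set used by most pipeline-level tests
small_sim <- function() {
  if (is.null(.sim_cache$small)) {
    .sim_cache$small <- simulateIRData(
      simulationParams(n_genes = 30, introns_per_gene = 3, seed = 7))
  }
  .sim_cache$small
}

# a tiny hand-built annotation: one plus-strand gene with two transcripts
# (t2 skips the terminal exon), one antisense exon inside intron 1
tiny_annotation <- function() {
  ex <- data.frame(
    start = c(101, 301, 601, 101, 301, 180),
    end = c(200, 400, 700, 200, 400, 230),
    strand = c("+", "+", "+", "+", "+", "-"),
    gene_id = c("g1", "g1", "g1", "g1", "g1", "as1"),
    transcript_id = c("g1.t1", "g1.t1", "g1.t1", "g1.t2", "g1.t2", "as1.t1"),
    exon_id = c("g1_e1", "g1_e2", "g1_e3", "g1_e1", "g1_e2", "as1_e1"),
    exon_rank = c(1, 2, 3, 1, 2, 1))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  S4Vectors::mcols(gr) <- ex[, c("gene_id", "transcript_id", "exon_id",
                                 "exon_rank")]
  gr
}

tiny_introns <- function() {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(201, 401), c(300, 600)), strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    intron_id = c("g1_i1", "g1_i2"), gene_id = "g1",
    intron_rank = 1:2, flank5_id = c("g1_e1", "g1_e2"),
    flank3_id = c("g1_e2", "g1_e3"), first_intron = c(TRUE, FALSE))
  gr
}

# synthetic GCH cytosine report: sites every `spacing` bp with given
# methylation levels per region (data.frame chrom/start/end/level)
make_gch_calls <- function(chrom_len, background, regions = NULL,
                           coverage = 20, spacing = 12, seed = 1) {
  set.seed(seed)
  pos <- seq(5, chrom_len, by = spacing)
  lv <- rep(background, length(pos))
  if (!is.null(regions)) {
    for (i in seq_len(nrow(regions))) {
      sel <- pos >= regions$start[i] & pos <= regions$end[i]
      lv[sel] <- regions$level[i]
    }
  }
  cov <- rpois(length(pos), coverage)
  keep <- cov > 0
  meth <- rbinom(sum(keep), cov[keep], lv[keep])
  data.frame(chrom = "chrN", pos = pos[keep], strand = "+",
             count_methylated = meth,
             count_unmethylated = cov[keep] - meth,
             context = "GCH")
}

# planted-coefficient logistic feature table (class balance ~50%)
make_logistic_table <- function(n, p, beta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  y <- rbinom(n, 1, plogis(X %*% beta))
  data.frame(label = ifelse(y == 1, "retained", "non_retained"), X)
}

# XOR-structured table: two interacting features with weak marginal signal
# on x1 only, plus noise features
make_xor_table <- function(n, seed, n_noise = 8) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  u <- runif(n)
  x1c <- ifelse(y == 1, ifelse(u < 0.65, 1, -1), ifelse(u < 0.35, 1, -1))
  x2c <- ifelse(y == 1, x1c, -x1c)
  X <- cbind(x1 = x1c + rnorm(n, 0, 0.7), x2 = x2c + rnorm(n, 0, 0.7),
             matrix(rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, sprintf("n%02d", seq_len(n_noise)))))
  data.frame(label = ifelse(y == 1, "retained", "non_retained"), X)
}

# analytic Bayes ROC AUC of the generating logistic model y ~ Bern(plogis(s)),
# s = beta'x, x ~ N(0, I): numerical integration over the score distribution
bayes_auc_logistic <- function(beta, grid_n = 4000) {
  sigma <- sqrt(sum(beta^2))
  s <- seq(-8 * sigma, 8 * sigma, length.out = grid_n)
  w <- stats::dnorm(s, 0, sigma)
  p1 <- plogis(s)
  f1 <- w * p1; f0 <- w * (1 - p1)
  f1 <- f1 / sum(f1); f0 <- f0 / sum(f0)
  # P(S1 > S0) + 0.5 P(S1 = S0), scores ordered along the grid
  c0 <- cumsum(f0)
  sum(f1 * (c0 - 0.5 * f0))
}
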