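make_profile_calls <- function(introns, level_fun, coverage = 30,
                               spacing = 6, seed = 1) {
  set.seed(seed)
  lo <- min(GenomicRanges::start(introns)) - 300
  hi <- max(GenomicRanges::end(introns)) + 300
  pos <- seq(lo, hi, by = spacing)
  lv <- level_fun(pos)
  cov <- rpois(length(pos), coverage)
  keep <- cov > 0
  meth <- rbinom(sum(keep), cov[keep], lv[keep])
  data.frame(chrom = "chrP", pos = pos[keep], strand = "+",
             count_methylated = meth,
             count_unmethylated = cov[keep] - meth, context = "GCH")
}

intron_at <- function(starts, strand = "+", width = 600) {
  gr <- GenomicRanges::GRanges("chrP",
    IRanges::IRanges(starts, starts + width - 1), strand = strand)
  gr$intron_id <- sprintf("p%03d", seq_along(gr))
  gr$intron_rank <- rep(1L, length(gr))
  gr
}

test_that("profile matrices reproduce uniform and step methylomes", {
  ins <- intron_at(seq(2000, by = 3000, length.out = 30))
  flat <- make_profile_calls(ins, function(p) rep(0.3, length(p)))
  pm <- buildProfileMatrix(ins, flat, "5ss", 10)
  expect_equal(dim(profileValues(pm)), c(30, 40))
  expect_lt(abs(mean(profileValues(pm), na.rm = TRUE) - 30), 2)
  # step at the 5' splice site: 10% upstream, 40% downstream
  anchors <- GenomicRanges::start(ins)
  stepf <- function(p) {
    lv <- rep(0.10, length(p))
    for (a in anchors) lv[p >= a & p < a + 200] <- 0.40
    lv
  }
  pms <- buildProfileMatrix(ins, make_profile_calls(ins, stepf), "5ss", 10)
  cm <- colMeans(profileValues(pms), na.rm = TRUE)
  expect_lt(mean(cm[1:20]), 15)
  expect_gt(mean(cm[21:40]), 35)
  # a minus-strand intron mirrors the layout
  mi <- intron_at(50000, strand = "-")
  mstep <- function(p) ifelse(p <= GenomicRanges::end(mi), 0.40, 0.10)
  pmm <- buildProfileMatrix(mi, make_profile_calls(mi, mstep), "5ss", 10)
  v <- profileValues(pmm)[1, ]
  expect_lt(mean(v[1:19], na.rm = TRUE), 20)
  expect_gt(mean(v[22:40], na.rm = TRUE), 30)
})

test_that("profile rows agree with pooled region methylation per bin", {
  ins <- intron_at(2000)
  calls <- make_profile_calls(ins, function(p) rep(0.3, length(p)))
  pm <- buildProfileMatrix(ins, calls, "5ss", 10)
  a <- GenomicRanges::start(ins)
  for (b in c(1, 15, 40)) {
    lo <- a - 200 + (b - 1) * 10
    rm_ <- regionMethylation("chrP", lo, lo + 9, calls, "GCH")
    v <- unname(profileValues(pm)[1, b])
    if (is.na(rm_)) expect_true(is.na(v))
    else expect_equal(v, 100 * rm_, tolerance = 1e-9)
  }
})

test_that("clustering is deterministic, permutation-invariant and guarded", {
  set.seed(61)
  m <- rbind(matrix(rnorm(200, 10), 20), matrix(rnorm(200, 60), 20))
  m <- m[, rep(1:10, 4)]
  colnames(m) <- NULL
  pm <- new("ProfileMatrix", matrix = m, anchor = "5ss", bin_size = 10,
            clusters = rep(NA_integer_, 40), state = "retained")
  c1 <- clusterAssignments(clusterProfiles(pm, 2))
  expect_equal(length(unique(c1)), 2)
  # duplicated rows land in the same cluster
  pm2 <- new("ProfileMatrix", matrix = m[c(1, 1, 21, 21), ], anchor = "5ss",
             bin_size = 10, clusters = rep(NA_integer_, 4),
             state = "retained")
  c2 <- clusterAssignments(clusterProfiles(pm2, 2, min_size = 1))
  expect_equal(c2[1], c2[2])
  expect_equal(c2[3], c2[4])
  expect_false(c2[1] == c2[3])
  # permutation invariance up to label renaming
  perm <- sample(nrow(m))
  pmp <- new("ProfileMatrix", matrix = m[perm, ], anchor = "5ss",
             bin_size = 10, clusters = rep(NA_integer_, 40),
             state = "retained")
  cp <- clusterAssignments(clusterProfiles(pmp, 2))
  expect_equal(mclust::adjustedRandIndex(c1[perm], cp), 1)
  expect_error(clusterProfiles(pm, 50), "exceeds")
  # k = 1 puts everything together
  expect_equal(unique(clusterAssignments(clusterProfiles(pm, 1))), 1L)
})

test_that("group curves and matched controls honour their contracts", {
  set.seed(62)
  mk <- function(mu) new("ProfileMatrix",
    matrix = matrix(pmin(100, pmax(0, rnorm(400, mu))), 10),
    anchor = "5ss", bin_size = 10, clusters = rep(NA_integer_, 10),
    state = "retained")
  a <- mk(40)
  curves <- aggregateGroupProfiles(a, a)
  expect_equal(curves$retained, curves$non_retained)
  b <- mk(20)
  curves2 <- aggregateGroupProfiles(a, b)
  expect_true(all(curves2$retained > curves2$non_retained))
  expect_error(aggregateGroupProfiles(a,
    new("ProfileMatrix", matrix = matrix(numeric(0), 0, 40),
        anchor = "5ss", bin_size = 10, clusters = integer(0),
        state = "non_retained")), "empty")
  # matching respects calipers
  set.seed(63)
  ql <- runif(30, 200, 800); qg <- runif(30, 0.4, 0.6)
  pl <- runif(300, 100, 1600); pg <- runif(300, 0.3, 0.7)
  idx <- matchedControls(ql, qg, pl, pg)
  ok <- !is.na(idx)
  expect_true(all(abs(pg[idx[ok]] - qg[ok]) <= 0.05))
  expect_true(all(pmax(pl[idx[ok]] / ql[ok], ql[ok] / pl[idx[ok]]) <= 2))
  expect_false(any(duplicated(idx[ok])))
})

test_that("the count GLM removes a GCH-mediated H3K36me3 confound", {
  set.seed(64)
  null_p <- replicate(60, {
    gch <- runif(300, 5, 60)
    counts <- rpois(300, exp(1 + 0.03 * gch))
    groups <- ifelse(gch > stats::median(gch), "retained", "non_retained")
    h3k36me3GlmAdjust(counts, gch, groups)$p_value
  })
  expect_gte(mean(null_p > 0.05), 0.85)
  # a real residual group effect is detected
  det <- replicate(30, {
    gch <- runif(300, 5, 60)
    groups <- rep(c("retained", "non_retained"), each = 150)
    mu <- exp(1 + 0.03 * gch) * ifelse(groups == "retained", 0.5, 1)
    h3k36me3GlmAdjust(rpois(300, mu), gch, groups)$p_value
  })
  expect_gte(mean(det < 0.01), 0.9)
  # zero slope: the confidence interval covers 0
  gch <- runif(400, 5, 60)
  res <- h3k36me3GlmAdjust(rpois(400, 10), gch,
                           rep(c("retained", "non_retained"), 200))
  expect_true(res$slope_ci[1] < 0 && res$slope_ci[2] > 0)
  expect_error(h3k36me3GlmAdjust(c(1.5, 2), c(1, 2),
                                 c("retained", "non_retained")),
               "integer")
})

test_that("first-intron stratification uses the any-transcript rule", {
  ins <- intron_at(c(1000, 5000, 9000))
  ins$intron_rank <- c(1L, 2L, 1L)
  s <- firstVsInternalStratify(ins)
  expect_setequal(s$first, c("p001", "p003"))
  expect_equal(s$internal, "p002")
})
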