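# exact one-sided hypergeometric tail by explicit enumeration
fisher_oracle <- function(mr, ur, mb, ub) {
  m <- mr + mb; n <- ur + ub; k <- mr + ur
  xs <- max(0, k - n):min(k, m)
  xs <- xs[xs >= mr]
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

region_calls <- function(mr, ur, mb, ub) {
  data.frame(chrom = "c", pos = c(5, 50), strand = "+",
             count_methylated = c(mr, mb), count_unmethylated = c(ur, ub),
             context = "GCH")
}

test_that("CpG coverage filter keeps sites with more than 5 reads", {
  calls <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                      count_methylated = c(3, 2, 10),
                      count_unmethylated = c(3, 3, 2),
                      context = c("CpG", "CpG", "GCH"))
  out <- filterCpGCoverage(calls)
  expect_equal(out$pos, c(1, 3)) # 6 reads kept, 5 dropped, GCH untouched
  expect_equal(nrow(filterCpGCoverage(calls[0, ])), 0)
})

test_that("candidate segmentation chains elevated sites under the gap rule", {
  mk <- function(pos, lv) {
    data.frame(chrom = "c", pos = pos, strand = "+",
               count_methylated = round(lv * 100),
               count_unmethylated = 100 - round(lv * 100), context = "GCH")
  }
  # 5 elevated sites spaced 30 bp over 120 bp + low background sites
  calls <- mk(c(seq(1000, 1120, by = 30), seq(3000, 9000, by = 50)),
              c(rep(0.5, 5), rep(0.05, 121)))
  cand <- segmentCandidates(calls, max_gap = 150, min_len = 40,
                            signal = "methylation")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$end - cand$start + 1, 121)
  # same sites spaced 160 bp apart: all chains break
  calls2 <- mk(c(seq(1000, 1640, by = 160), seq(3000, 9000, by = 50)),
               c(rep(0.5, 5), rep(0.05, 121)))
  expect_equal(nrow(segmentCandidates(calls2, 150, 40, "methylation")), 0)
  # elevated run of exactly 40 bp is dropped (> min_len required)
  calls3 <- mk(c(seq(1000, 1039, by = 13), seq(3000, 9000, by = 50)),
               c(rep(0.5, 4), rep(0.05, 121)))
  cand3 <- segmentCandidates(calls3, 150, 40, "methylation")
  expect_true(nrow(cand3) == 0 || all(cand3$end - cand3$start + 1 > 40))
  expect_error(segmentCandidates(mk(c(5, 1), c(0.5, 0.5)), 150, 40),
               "sorted")
})

test_that("the region Fisher test equals the hypergeometric tail oracle", {
  set.seed(21)
  for (i in 1:500) {
    mr <- sample(0:100, 1); ur <- sample(0:100, 1)
    mb <- sample(0:100, 1); ub <- sample(0:100, 1)
    if (mr + ur == 0 || mb + ub == 0) next
    res <- fisherRegionTest(data.frame(chrom = "c", start = 1, end = 10),
                            region_calls(mr, ur, mb, ub),
                            background_flank = 100)
    expect_lt(abs(res$p_value - fisher_oracle(mr, ur, mb, ub)), 1e-12)
  }
  strong <- fisherRegionTest(data.frame(chrom = "c", start = 1, end = 10),
                             region_calls(70, 30, 100, 900), 100)
  expect_lt(strong$p_value, 1e-10)
  flat <- fisherRegionTest(data.frame(chrom = "c", start = 1, end = 10),
                           region_calls(10, 90, 10, 90), 100)
  expect_gt(flat$p_value, 0.4)
  expect_lt(abs(fisherRegionTest(
    data.frame(chrom = "c", start = 1, end = 10),
    region_calls(3, 7, 30, 70), 100)$p_value -
      fisher_oracle(3, 7, 30, 70)), 1e-12)
})

test_that("planted NFRs are recovered with positional precision", {
  set.seed(31)
  # 40 planted 200-bp NFRs (35% vs 8%), coverage 20
  starts <- seq(5000, by = 2500, length.out = 40)
  regions <- data.frame(start = starts, end = starts + 199, level = 0.35)
  calls <- make_gch_calls(110000, 0.08, regions, coverage = 20, seed = 31)
  nfr <- callNFRs(calls)
  hit <- vapply(seq_len(nrow(regions)), function(i) {
    ov <- nfr$start <= regions$end[i] & nfr$end >= regions$start[i]
    if (!any(ov)) return(0)
    max(pmin(nfr$end[ov], regions$end[i]) -
          pmax(nfr$start[ov], regions$start[i]) + 1) / 200
  }, numeric(1))
  expect_gte(mean(hit >= 0.5), 0.9)
  expect_true(all(nfr$region_meth > nfr$background_meth))
})

test_that("nucleosome caller finds protected runs and respects length rule", {
  set.seed(32)
  starts <- seq(4000, by = 3000, length.out = 20)
  prot <- data.frame(start = starts, end = starts + 146, level = 0.0)
  calls <- make_gch_calls(70000, 0.30, prot, coverage = 20, spacing = 8,
                          seed = 32)
  nuc <- callNucleosomes(calls)
  hit <- vapply(seq_len(nrow(prot)), function(i) {
    any(nuc$start <= prot$end[i] & nuc$end >= prot$start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  # a 100-bp protected run is below the >140 bp length rule
  prot2 <- data.frame(start = 4000, end = 4099, level = 0.0)
  calls2 <- make_gch_calls(20000, 0.30, prot2, coverage = 20, spacing = 8,
                           seed = 33)
  nuc2 <- callNucleosomes(calls2)
  ov <- nuc2$start <= 4099 & nuc2$end >= 4000
  cover <- if (any(ov)) {
    max(pmin(nuc2$end[ov], 4099) - pmax(nuc2$start[ov], 4000) + 1)
  } else 0
  # protected stretch alone cannot form a >140 bp call
  expect_true(all(nuc2$end - nuc2$start + 1 > 140))
  expect_lt(cover, 140)
})

test_that("region methylation pools read counts and reports missing", {
  calls <- data.frame(chrom = "c", pos = c(10, 20), strand = "+",
                      count_methylated = c(5, 0),
                      count_unmethylated = c(5, 10), context = "GCH")
  expect_equal(regionMethylation("c", 1, 15, calls), 0.5)
  expect_equal(regionMethylation("c", 1, 25, calls), 0.25)
  expect_true(is.na(regionMethylation("c", 100, 200, calls)))
})

test_that("Fisher calls on homogeneous methylomes are calibrated", {
  # prespecified tiled windows on a flat methylome: the fraction of tested
  # regions reaching p <= 0.05 stays at or below ~5%
  for (s in 1:3) {
    calls <- make_gch_calls(130000, 0.10, NULL, coverage = 20, seed = 100 + s)
    starts <- seq(2000, 120000, length.out = 200)
    p <- vapply(starts, function(st) {
      fisherRegionTest(data.frame(chrom = "chrN", start = st, end = st + 199),
                       calls, background_flank = 4000)$p_value
    }, numeric(1))
    expect_lte(mean(p <= 0.05), 0.06)
  }
})
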