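test_that("configuration is validated field by field", {
  expect_error(simulationParams(n_genes = 0), "n_genes")
  expect_error(simulationParams(fraction_retained = 1.2), "fraction_retained")
  expect_error(simulationParams(gch_meth_nfr = -0.1), "gch_meth_nfr")
  expect_error(simulationParams(fraction_retained = 0.1,
                                fraction_dynamic = 0.5), "fraction_dynamic")
  expect_s4_class(simulationParams(), "SimulationParams")
})

test_that("annotation layout matches the requested design", {
  p <- simulationParams(n_genes = 10, introns_per_gene = 3, seed = 1)
  a <- simulateAnnotation(p)
  expect_equal(length(a$introns), 30)
  expect_setequal(unique(as.character(GenomicRanges::strand(a$introns))),
                  c("+", "-"))
  # introns never overlap their own flanking exons
  md <- S4Vectors::mcols(a$exons)
  for (i in seq_along(a$introns)) {
    fl <- a$exons[md$exon_id %in% c(a$introns$flank5_id[i],
                                    a$introns$flank3_id[i]) &
                    md$gene_id == a$introns$gene_id[i]]
    expect_equal(length(GenomicRanges::findOverlaps(a$introns[i], fl)), 0L)
  }
  expect_true(all(GenomicRanges::width(a$introns) ==
                    a$truth$introns$length))
})

test_that("fraction_retained = 0 produces no retained state anywhere", {
  p <- simulationParams(n_genes = 6, fraction_retained = 0,
                        fraction_dynamic = 0, seed = 2)
  a <- simulateAnnotation(p)
  expect_false(any(a$truth$states$retained))
  expect_equal(length(a$truth$nfrs), 0)
})

test_that("identical seeds give identical data, different seeds differ", {
  p <- simulationParams(n_genes = 6, seed = 5)
  a1 <- simulateAnnotation(p)
  a2 <- simulateAnnotation(p)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$truth$states, a2$truth$states)
  t1 <- simulateTranscriptome(a1, p)
  t2 <- simulateTranscriptome(a2, p)
  expect_identical(t1$coverage[["Mo"]], t2$coverage[["Mo"]])
  expect_identical(t1$junctions, t2$junctions)
  m1 <- simulateMethylomes(a1, p)
  m2 <- simulateMethylomes(a2, p)
  expect_identical(m1, m2)
  p2 <- simulationParams(n_genes = 6, seed = 6)
  expect_false(identical(as.character(simulateAnnotation(p2)$genome),
                         as.character(a1$genome)))
})

test_that("dynamic introns switch states and NFRs sit on coupled introns", {
  sim <- small_sim()
  tr <- groundTruth(sim)
  st <- tr$states
  for (id in tr$introns$intron_id[tr$introns$dynamic]) {
    s <- st$retained[st$intron_id == id]
    expect_true(any(s) && any(!s))
  }
  expect_true(all(tr$nfrs$intron_id %in%
                    tr$introns$intron_id[tr$introns$nfr_coupled]))
})

test_that("planted retention effects shape the intron population", {
  sim <- simulateIRData(simulationParams(n_genes = 80, seed = 9))
  ti <- groundTruth(sim)$introns
  expect_lt(median(ti$length[ti$retained_any]),
            median(ti$length[!ti$retained_any]))
  expect_gt(median(ti$gc_target[ti$retained_any]),
            median(ti$gc_target[!ti$retained_any]))
  expect_lt(median(ti$ss_z[ti$retained_any]),
            median(ti$ss_z[!ti$retained_any]))
})

test_that("simulated coverage and junctions recover the planted IRratio", {
  # replicate introns at a fixed true IRratio: recomputed ratio concentrates
  # around the planted value
  set.seed(13)
  D <- 200; ir <- 0.25; n <- 500
  est <- replicate(n, {
    depths <- rnbinom(300, mu = ir * D, size = 10)
    jn <- rpois(1, (1 - ir) * D)
    ia <- trimmedIntronicAbundance(depths)
    computeIRratio(ia, jn)
  })
  expect_gte(mean(est), 0.23)
  expect_lte(mean(est), 0.27)
})

test_that("methylome levels follow planted NFRs and counts are consistent", {
  sim <- small_sim()
  m <- methylomeCalls(sim, "Mo")
  expect_true(all(m$count_methylated >= 0))
  expect_true(all(m$count_unmethylated >= 0))
  gch <- m[m$context == "GCH", ]
  nfrs <- plantedNFRs(sim)
  st <- groundTruth(sim)$states
  act <- nfrs[nfrs$intron_id %in%
                st$intron_id[st$cell_type == "Mo" & st$retained] &
                nfrs$level == simParams(sim)@gch_meth_nfr]
  if (length(act)) {
    inside <- rep(FALSE, nrow(gch))
    for (i in seq_along(act)) {
      inside <- inside | (gch$pos >= GenomicRanges::start(act)[i] &
                            gch$pos <= GenomicRanges::end(act)[i])
    }
    lv_in <- sum(gch$count_methylated[inside]) /
      sum(gch$count_methylated[inside] + gch$count_unmethylated[inside])
    lv_out <- sum(gch$count_methylated[!inside]) /
      sum(gch$count_methylated[!inside] + gch$count_unmethylated[!inside])
    expect_gt(lv_in, 0.28)
    expect_lt(lv_in, 0.42)
    expect_lt(lv_out, 0.15)
  }
})

test_that("H3K36me3 is depleted over retained dynamic introns as planted", {
  sim <- simulateIRData(simulationParams(n_genes = 60, fraction_retained = 0.5,
                                         fraction_dynamic = 0.3,
                                         h3k36_depletion = 0.5, seed = 17))
  tr <- groundTruth(sim)
  st <- tr$states
  ct <- "Mo"
  chip <- chipTracks(sim, ct)$H3K36me3
  dyn <- tr$introns$intron_id[tr$introns$dynamic]
  ret <- intersect(dyn, st$intron_id[st$cell_type == ct & st$retained])
  ins <- intronRanges(sim)
  mean_over <- function(ids) {
    sel <- IRanges::overlapsAny(chip$pileup, ins[ins$intron_id %in% ids])
    mean(chip$pileup$score[sel])
  }
  non <- setdiff(ins$intron_id, dyn)
  ratio <- mean_over(ret) / mean_over(non)
  expect_gte(ratio, 0.4)
  expect_lte(ratio, 0.6)
  # depletion factor 1 leaves the ratio at ~1
  sim1 <- simulateIRData(simulationParams(n_genes = 30,
                                          fraction_retained = 0.5,
                                          fraction_dynamic = 0.3,
                                          h3k36_depletion = 1, seed = 18))
  chip1 <- chipTracks(sim1, ct)$H3K36me3
  tr1 <- groundTruth(sim1)
  dyn1 <- tr1$introns$intron_id[tr1$introns$dynamic]
  ret1 <- intersect(dyn1, tr1$states$intron_id[
    tr1$states$cell_type == ct & tr1$states$retained])
  ins1 <- intronRanges(sim1)
  m1 <- mean(chip1$pileup$score[IRanges::overlapsAny(
    chip1$pileup, ins1[ins1$intron_id %in% ret1])])
  m0 <- mean(chip1$pileup$score[IRanges::overlapsAny(
    chip1$pileup, ins1[!ins1$intron_id %in% dyn1])])
  expect_lt(abs(m1 / m0 - 1), 0.15)
})

test_that("peak intervals are consistent with their pileup", {
  sim <- small_sim()
  for (mk in names(chipTracks(sim, "Mo"))) {
    tr <- chipTracks(sim, "Mo")[[mk]]
    if (!length(tr$peaks)) next
    cov <- IRanges::overlapsAny(tr$peaks, tr$pileup[tr$pileup$score > 0])
    expect_true(all(cov))
  }
})
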