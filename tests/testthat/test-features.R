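test_that("analysis windows are 200 bp, strand-oriented and clip-flagged", {
  gr <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 2000),
                               strand = "+")
  r <- defineRegions(gr)
  expect_equal(GenomicRanges::start(r$r5ss), 901)
  expect_equal(GenomicRanges::end(r$r5ss), 1100)
  expect_equal(GenomicRanges::start(r$r3ss), 1901)
  expect_equal(GenomicRanges::end(r$r3ss), 2100)
  expect_equal(GenomicRanges::start(r$rmid), 1401)
  expect_equal(GenomicRanges::end(r$rmid), 1600)
  expect_true(all(GenomicRanges::width(r$r5ss) == 200))
  # minus strand: 5' window sits at the genomic end
  mn <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 2000),
                               strand = "-")
  rm_ <- defineRegions(mn)
  expect_equal(GenomicRanges::start(rm_$r5ss), 1901)
  expect_equal(GenomicRanges::end(rm_$r5ss), 2100)
  expect_equal(GenomicRanges::start(rm_$r3ss), 901)
  # short intron: overlapping windows are permitted
  sh <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 1150),
                               strand = "+")
  rs <- defineRegions(sh)
  expect_true(GenomicRanges::end(rs$r5ss) >= GenomicRanges::start(rs$rmid))
  # contig edge clipping is flagged
  eg <- GenomicRanges::GRanges("c", IRanges::IRanges(50, 400), strand = "+")
  expect_true(defineRegions(eg, c(c = 1000))$r5ss$clipped)
})

test_that("GC content and CpG density follow their definitions", {
  expect_equal(gcContent("GCGC"), 1)
  expect_equal(gcContent("ATAT"), 0)
  expect_equal(gcContent("GCATN"), 0.5)
  expect_true(is.na(gcContent("NNN")))
  expect_equal(cpgDensity("CGCG"), 50)
  expect_equal(cpgDensity("ATAT"), 0)
  expect_equal(cpgDensity(strrep("ACGT", 50)), 25)
})

test_that("PWM scoring has argmax at consensus and zero for uniform PWM", {
  sim <- small_sim()
  pwms <- buildSpliceSitePWM(intronRanges(sim), genomeSeq(sim))
  expect_equal(dim(pwms$donor), c(4, 9))
  expect_equal(dim(pwms$acceptor), c(4, 23))
  cons <- paste(rownames(pwms$donor)[apply(pwms$donor, 2, which.max)],
                collapse = "")
  # consensus sequence scores at least as high as any random window
  smax <- spliceSiteStrength(cons, pwms$donor)
  set.seed(4)
  rnd <- replicate(50, paste(sample(c("A", "C", "G", "T"), 9, TRUE),
                             collapse = ""))
  expect_true(all(spliceSiteStrength(rnd, pwms$donor) <= smax))
  # the planted donor consensus is the PWM consensus
  expect_equal(substr(cons, 4, 5), "GT")
  # uniform PWM scores 0 everywhere
  unif <- matrix(0, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(spliceSiteStrength(rnd, unif), rep(0, 50))
  # hand-computed toy PWM
  toy <- log2(matrix(c(0.7, 0.1, 0.1, 0.1,
                       0.1, 0.7, 0.1, 0.1,
                       0.25, 0.25, 0.25, 0.25), 4, 3,
                     dimnames = list(c("A", "C", "G", "T"), NULL)) / 0.25)
  expect_equal(spliceSiteStrength("ACG", toy),
               log2(0.7 / 0.25) * 2 + 0, tolerance = 1e-12)
  expect_true(is.na(spliceSiteStrength("ACN", toy)))
})

test_that("branch points are scanned with A-anchored scoring and tie rule", {
  base <- strrep("G", 150)
  # plant the consensus heptamer with the branch A 30 bp from the 3' end
  seq <- paste0(substr(base, 1, 150 - 30 - 5 - 1), "TACTAAC",
                strrep("G", 30 - 1))
  expect_equal(nchar(seq), 150)
  bp <- branchPointFeatures(seq)
  expect_equal(bp$distance, 30)
  expect_equal(bp$strength, 7 * log2(0.7 / 0.25), tolerance = 1e-12)
  # adenosine-free scan region -> missing
  expect_true(is.na(branchPointFeatures(strrep("G", 200))$strength))
  # two identical maxima: the one closest to the 3'ss wins
  two <- paste0(strrep("G", 60), "TACTAAC", strrep("G", 20), "TACTAAC",
                strrep("G", 24))
  # branch adenosines sit 52 and 25 bp from the 3' end; closest wins
  expect_equal(branchPointFeatures(two)$distance, 25)
})

test_that("histone codes use the mean+SD strong threshold inclusively", {
  peaks <- GenomicRanges::GRanges("c", IRanges::IRanges(c(100, 500), c(200, 600)),
                                  peak = c(50, 50))
  pileup <- GenomicRanges::GRanges("c",
    IRanges::IRanges(c(100, 500), c(200, 600)), score = c(10, 20))
  st <- hmTrackStats(peaks, pileup)
  expect_equal(st$threshold, 15 + sd(c(10, 20)))
  win <- GenomicRanges::GRanges("c", IRanges::IRanges(
    c(150, 550, 900), c(160, 560, 910)))
  # exactly at mean+SD counts as strong: force that case
  st2 <- list(summit_value = c(10, st$threshold), threshold = st$threshold)
  codes <- hmOverlapCode(win, peaks, st2)
  expect_equal(codes, c(1L, 2L, 0L))
})

test_that("presence flags use >= 1 bp overlap with half-open adjacency", {
  calls <- data.frame(chrom = "c", start = 100, end = 200, kind = "NFR")
  win <- GenomicRanges::GRanges("c", IRanges::IRanges(
    c(150, 201, 250), c(260, 260, 300)))
  expect_equal(presenceFlags(win, calls, "NFR"), c(1L, 0L, 0L))
  both <- rbind(calls, data.frame(chrom = "c", start = 140, end = 260,
                                  kind = "nucleosome"))
  expect_equal(presenceFlags(win[1], both, "NFR"), 1L)
  expect_equal(presenceFlags(win[1], both, "nucleosome"), 1L)
})

test_that("feature assembly is pure, registry-ordered and schema-valid", {
  sim <- small_sim()
  ir <- quantifyIR(sim, "Mo")
  nfr <- callNFRs(methylomeCalls(sim, "Mo"))
  f1 <- assembleFeatures(sim, "Mo", ir, nfr)
  f2 <- assembleFeatures(sim, "Mo", ir, nfr)
  expect_identical(f1, f2)
  reg <- featureRegistry()
  expect_lte(nrow(reg), 48)
  expect_equal(names(f1), c("intron_id", "cell_type", "label", reg$name))
  expect_true(validateFeatureTable(f1))
  expect_true(all(f1$label %in% c("retained", "non_retained")))
  # schema rejects out-of-range values
  bad <- f1
  bad$gc_5ss[1] <- 1.4
  expect_error(validateFeatureTable(bad), "range")
})

test_that("NFR-coupled introns carry higher 5'ss GCH methylation features", {
  sim <- simulateIRData(simulationParams(n_genes = 100,
                                         fraction_retained = 0.5,
                                         fraction_dynamic = 0.1,
                                         nfr_coupling_prob = 0.5, seed = 23))
  ir <- quantifyIR(sim, "Mo")
  nfr <- callNFRs(methylomeCalls(sim, "Mo"))
  f <- suppressMessages(assembleFeatures(sim, "Mo", ir, nfr))
  ti <- groundTruth(sim)$introns
  coupled <- f$intron_id %in% ti$intron_id[ti$nfr_coupled]
  ret <- f$label == "retained"
  tt <- t.test(f$gch_meth_5ss[ret & coupled], f$gch_meth_5ss[ret & !coupled],
               alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
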