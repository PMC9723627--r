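#' Three 200-bp analysis windows per intron
#'
#' Builds the 5' splice-site, 3' splice-site and midpoint windows (+/-100 bp
#' each, 200 bp long, strand-oriented so "5'" follows transcription
#' direction). Windows truncated by a contig edge are flagged `clipped`.
#'
#' @param introns intron `GRanges`.
#' @param seqlen named contig lengths (optional; clipping is flagged against
#'   them).
#' @return list of three `GRanges` (`r5ss`, `r3ss`, `rmid`), parallel to
#'   `introns`, each with a `clipped` metadata column.
#' @export
defineRegions <- function(introns, seqlen = NULL) {
  s <- GenomicRanges::start(introns)
  e <- GenomicRanges::end(introns)
  w <- GenomicRanges::width(introns)
  minus <- as.character(GenomicRanges::strand(introns)) == "-"
  don <- ifelse(minus, e, s)     # first intronic base, transcription order
  acc <- ifelse(minus, s, e)     # last intronic base
  mid <- s + floor(w / 2)

  win <- function(center, left) {
    # left = TRUE puts 100 bases before the boundary, 99 after (donor-style)
    st <- ifelse(left, center - 100L, center - 99L)
    en <- st + 199L
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(introns),
                                 IRanges::IRanges(pmax(1L, st), en),
                                 strand = GenomicRanges::strand(introns))
    clipped <- st < 1L
    if (!is.null(seqlen)) {
      sl <- seqlen[as.character(GenomicRanges::seqnames(introns))]
      clipped <- clipped | en > sl
      GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), sl)
    }
    gr$clipped <- clipped
    gr
  }
  # donor boundary lies before the first intronic base; acceptor after the last
  list(r5ss = win(don, left = !minus),
       r3ss = win(acc, left = minus),
       rmid = win(mid, left = TRUE))
}

#' GC content of a sequence window
#'
#' `(G + C) / counted bases`, case-insensitive; ambiguous bases (anything
#' outside ACGT) are excluded from the denominator. All-ambiguous windows are
#' `NA`.
#'
#' @param seqs character vector (or `DNAStringSet`) of window sequences.
#' @return numeric vector of fractions (or `NA`).
#' @examples
#' gcContent("GCATN") # 0.5
#' @export
gcContent <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  vapply(seqs, function(x) {
    b <- strsplit(x, "", fixed = TRUE)[[1]]
    ok <- b %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    sum(b[ok] %in% c("G", "C")) / sum(ok)
  }, numeric(1), USE.NAMES = FALSE)
}

#' CpG dinucleotide density
#'
#' Count of CG dinucleotides per 100 bp of window (overlap-free scan; CG
#' cannot self-overlap).
#'
#' @param seqs character vector (or `DNAStringSet`) of window sequences.
#' @return CG count per 100 bp.
#' @examples
#' cpgDensity("CGCG") # 50
#' @export
cpgDensity <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  vapply(seqs, function(x) {
    n <- nchar(x)
    if (n < 2L) return(0)
    hits <- gregexpr("CG", x, fixed = TRUE)[[1]]
    k <- if (hits[1] == -1L) 0L else length(hits)
    k / n * 100
  }, numeric(1), USE.NAMES = FALSE)
}

.extract_seq <- function(genome, chrom, start, end, strand) {
  sq <- Biostrings::subseq(genome[[chrom]], start = max(1L, start),
                           end = min(length(genome[[chrom]]), end))
  if (strand == "-") sq <- Biostrings::reverseComplement(sq)
  as.character(sq)
}

#' Estimate splice-site position weight matrices from the annotation
#'
#' Collects donor 9-mers (3 exonic + 6 intronic bases) and acceptor 23-mers
#' (20 intronic + 3 exonic) of type A (constitutive-flank) introns and builds
#' log2-odds position weight matrices against the genome's background base
#' composition. External score tables with the same window conventions can be
#' plugged into [spliceSiteStrength()] in their place.
#'
#' @param introns intron `GRanges` (with `intron_type` if available; type A
#'   introns are used when present).
#' @param genome `DNAStringSet`.
#' @return list with `donor` and `acceptor` 4 x L log2-odds matrices
#'   (rows A, C, G, T).
#' @export
buildSpliceSitePWM <- function(introns, genome) {
  use <- if (!is.null(introns$intron_type)) {
    introns[introns$intron_type == "A"]
  } else introns
  if (!length(use)) use <- introns
  chrom <- as.character(GenomicRanges::seqnames(use))
  s <- GenomicRanges::start(use); e <- GenomicRanges::end(use)
  minus <- as.character(GenomicRanges::strand(use)) == "-"
  don <- acc <- character(length(use))
  for (i in seq_along(use)) {
    if (!minus[i]) {
      don[i] <- .extract_seq(genome, chrom[i], s[i] - 3L, s[i] + 5L, "+")
      acc[i] <- .extract_seq(genome, chrom[i], e[i] - 19L, e[i] + 3L, "+")
    } else {
      don[i] <- .extract_seq(genome, chrom[i], e[i] - 5L, e[i] + 3L, "-")
      acc[i] <- .extract_seq(genome, chrom[i], s[i] - 3L, s[i] + 19L, "-")
    }
  }
  bg <- Biostrings::letterFrequency(genome, c("A", "C", "G", "T"))[1, ]
  bg <- bg / sum(bg)
  pwm_from <- function(kmers) {
    m <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
    L <- ncol(m)
    cnt <- sapply(seq_len(L), function(j) {
      table(factor(m[, j], levels = c("A", "C", "G", "T")))
    })
    p <- sweep(cnt + 0.5, 2, colSums(cnt + 0.5), "/")
    log2(p / bg)
  }
  list(donor = pwm_from(don), acceptor = pwm_from(acc))
}

#' Score splice-site sequences against a position weight matrix
#'
#' Sum of per-position log2-odds. Windows containing ambiguous bases score
#' `NA` (missing).
#'
#' @param seqs character vector of site sequences (length must match the PWM
#'   width: 9 for donors, 23 for acceptors with the default builder).
#' @param pwm a 4 x L log2-odds matrix with rows A, C, G, T (from
#'   [buildSpliceSitePWM()] or an external score table).
#' @return numeric scores.
#' @export
spliceSiteStrength <- function(seqs, pwm) {
  seqs <- toupper(as.character(seqs))
  vapply(seqs, function(x) {
    b <- strsplit(x, "", fixed = TRUE)[[1]]
    if (length(b) != ncol(pwm) || any(!b %in% rownames(pwm))) {
      return(NA_real_)
    }
    sum(pwm[cbind(match(b, rownames(pwm)), seq_along(b))])
  }, numeric(1), USE.NAMES = FALSE)
}

# branch-point heptamer log2-odds weight matrix (consensus TACTAAC,
# branch adenosine at position 6)
.branch_wm <- local({
  cons <- c("T", "A", "C", "T", "A", "A", "C")
  m <- matrix(0.1, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 0.7
  log2(m / 0.25)
})

#' Branch-point strength and distance
#'
#' Scans candidate branch positions 15-100 bp upstream of the 3' splice site
#' (truncated for shorter introns) with a branch-point heptamer weight matrix
#' (consensus TACTAAC); the branch position must be an adenosine. Returns the
#' best score and its distance to the 3' splice site; ties go to the
#' candidate closest to the 3' splice site. `NA` when no adenosine candidate
#' exists.
#'
#' @param intron_seq character, the intron sequence in transcription
#'   orientation.
#' @param wm branch-point weight matrix (4 x 7 log2-odds; default built-in).
#' @param scan_range distances (bp from the 3' end) to scan.
#' @return list with `strength` and `distance` (both `NA` when missing).
#' @export
branchPointFeatures <- function(intron_seq, wm = .branch_wm,
                                scan_range = c(15L, 100L)) {
  b <- strsplit(toupper(as.character(intron_seq)), "", fixed = TRUE)[[1]]
  L <- length(b)
  dmax <- min(scan_range[2], L - 6L)
  if (dmax < scan_range[1]) return(list(strength = NA_real_,
                                        distance = NA_integer_))
  best_s <- -Inf; best_d <- NA_integer_
  for (d in scan_range[1]:dmax) {     # ascending: first max is closest to 3'ss
    pa <- L - d
    if (pa < 6L || b[pa] != "A") next
    win <- b[(pa - 5L):(pa + 1L)]
    if (any(!win %in% rownames(wm))) next
    s <- sum(wm[cbind(match(win, rownames(wm)), 1:7)])
    if (s > best_s) { best_s <- s; best_d <- d }
  }
  if (!is.finite(best_s)) return(list(strength = NA_real_,
                                      distance = NA_integer_))
  list(strength = best_s, distance = best_d)
}

#' Summit pile-up statistics of a histone-mark track
#'
#' Reads the pile-up value at every peak summit and returns the strong-signal
#' threshold `mean + SD` over all peaks of the track.
#'
#' @param peaks narrowPeak-style `GRanges` (metadata `peak` = summit offset).
#' @param pileup `GRanges` of pile-up bins with `score`.
#' @return list: `summit_value` (per peak, `NA` when no pile-up under the
#'   summit), `threshold` (mean + SD).
#' @export
hmTrackStats <- function(peaks, pileup) {
  if (!length(peaks)) return(list(summit_value = numeric(0), threshold = NA))
  summit <- GenomicRanges::start(peaks) + peaks$peak
  sgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                IRanges::IRanges(summit, summit))
  hit <- GenomicRanges::findOverlaps(sgr, pileup, select = "first")
  sv <- ifelse(is.na(hit), NA_real_, pileup$score[hit])
  thr <- mean(sv, na.rm = TRUE) + sd(sv, na.rm = TRUE)
  list(summit_value = sv, threshold = thr)
}

#' Histone-mark overlap code for analysis windows
#'
#' 0 = the window overlaps no peak of the mark; 1 = it overlaps a peak whose
#' summit pile-up is below the strong-signal threshold (mean + SD over all
#' peak summits of the track); 2 = it overlaps a peak at or above the
#' threshold. Peaks without pile-up under the summit count as code 1 (with a
#' warning at stats time).
#'
#' @param windows `GRanges` of analysis windows.
#' @param peaks narrowPeak `GRanges` of the mark.
#' @param stats result of [hmTrackStats()] for the same track.
#' @return integer vector of codes in `{0, 1, 2}`.
#' @export
hmOverlapCode <- function(windows, peaks, stats) {
  out <- integer(length(windows))
  if (!length(peaks)) return(out)
  sv <- stats$summit_value
  if (anyNA(sv)) warning("peaks without pile-up at summit score as code 1")
  ov <- GenomicRanges::findOverlaps(windows, peaks, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  for (i in unique(qh)) {
    vals <- sv[sh[qh == i]]
    out[i] <- if (all(is.na(vals))) 1L
              else if (max(vals, na.rm = TRUE) >= stats$threshold) 2L else 1L
  }
  out
}

#' NFR / nucleosome presence flags for analysis windows
#'
#' 1 when any call of the kind overlaps the window by at least one base.
#'
#' @param windows `GRanges` of analysis windows.
#' @param calls chromatin-region call data.frame (chrom, start, end, kind).
#' @param kind `"NFR"` or `"nucleosome"`.
#' @return integer vector of 0/1 flags.
#' @export
presenceFlags <- function(windows, calls, kind = "NFR") {
  cc <- calls[calls$kind == kind, , drop = FALSE]
  if (!nrow(cc)) return(integer(length(windows)))
  gr <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(cc$start, cc$end))
  as.integer(IRanges::overlapsAny(windows, gr, ignore.strand = TRUE))
}

# batch pooled region methylation via interval overlap
.region_meth_batch <- function(windows, calls, context) {
  cc <- calls[calls$context == context, , drop = FALSE]
  out <- rep(NA_real_, length(windows))
  if (!nrow(cc)) return(out)
  sgr <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(cc$pos, cc$pos))
  ov <- GenomicRanges::findOverlaps(windows, sgr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (!length(qh)) return(out)
  m <- tapply(cc$count_methylated[sh], qh, sum)
  t <- tapply(cc$count_methylated[sh] + cc$count_unmethylated[sh], qh, sum)
  out[as.integer(names(m))] <- as.numeric(m) / as.numeric(t)
  out
}

#' The default feature registry
#'
#' The ordered, versioned list of features assembled by
#' [assembleFeatures()]: 11 intrinsic sequence features, 2 transcriptomic
#' (flanking-exon PSIs) and 10 epigenetic features per analysis window
#' (3 windows), 43 in total.
#'
#' @return data.frame with columns `name`, `class`, `type`, `min`, `max`.
#' @export
featureRegistry <- function() {
  regions <- c("5ss", "3ss", "mid")
  intrinsic <- data.frame(
    name = c("intron_length", paste0("gc_", regions),
             paste0("cpg_density_", regions),
             "ss5_strength", "ss3_strength",
             "bp_strength", "bp_distance"),
    class = "intrinsic",
    type = c("count", rep("fraction", 3), rep("density", 3),
             rep("score", 2), "score", "count"),
    min = c(1, rep(0, 3), rep(0, 3), -Inf, -Inf, -Inf, 1),
    max = c(1e4, rep(1, 3), rep(50, 3), Inf, Inf, Inf, 100))
  transcr <- data.frame(
    name = c("psi_5", "psi_3"), class = "transcriptomic",
    type = "fraction", min = 0, max = 1)
  marks <- c("H3K9me3", "H3K27me3", "H3K27ac", "H3K36me3",
             "H3K4me1", "H3K4me3")
  epi <- do.call(rbind, lapply(regions, function(r) {
    data.frame(
      name = c(paste0("cpg_meth_", r), paste0("gch_meth_", r),
               paste0("nfr_", r), paste0("nucleosome_", r),
               paste0(tolower(marks), "_", r)),
      class = "epigenetic",
      type = c("fraction", "fraction", "binary", "binary", rep("code", 6)),
      min = 0, max = c(1, 1, 1, 1, rep(2, 6)))
  }))
  out <- rbind(intrinsic, transcr, epi)
  rownames(out) <- NULL
  out
}

#' Validate a feature table against the registry schema
#'
#' Checks column presence, numeric type and the documented ranges; binary and
#' code features must take only their admissible integer values.
#'
#' @param table a feature data.frame from [assembleFeatures()].
#' @param registry a registry data.frame (default [featureRegistry()]).
#' @return invisibly `TRUE`; errors describe the violation.
#' @export
validateFeatureTable <- function(table, registry = featureRegistry()) {
  for (i in seq_len(nrow(registry))) {
    nm <- registry$name[i]
    if (!nm %in% names(table)) stop("missing feature column '", nm, "'",
                                    call. = FALSE)
    v <- table[[nm]]
    if (!is.numeric(v)) stop("feature '", nm, "' must be numeric",
                             call. = FALSE)
    fin <- v[is.finite(v)]
    if (any(fin < registry$min[i] - 1e-9) ||
        any(fin > registry$max[i] + 1e-9)) {
      stop("feature '", nm, "' out of documented range", call. = FALSE)
    }
    if (registry$type[i] %in% c("binary", "code") &&
        any(fin != floor(fin))) {
      stop("feature '", nm, "' must be integer-coded", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assemble the per-intron feature table for one cell type
#'
#' Builds the registry-ordered feature vector for every intron with an
#' unambiguous retention call in the cell type: sequence features from the
#' genome, PSIs from the IR table, CpG/GCH methylation from the (coverage
#' filtered) cytosine report, NFR/nucleosome presence from the chromatin
#' calls, and 0/1/2 histone codes from peaks + pile-up. Introns with a
#' missing intrinsic feature are dropped (logged via `message`); missing
#' epigenetic values are imputed as 0/absent.
#'
#' @param sim a [SyntheticIRData-class] (or NULL when layers are explicit).
#' @param cell_type cell-type label.
#' @param ir_table the [quantifyIR()] output for this cell type.
#' @param chromatin_calls data.frame of NFR and nucleosome calls (rbind of
#'   [callNFRs()] and [callNucleosomes()] output).
#' @param pwms splice-site PWMs (default built from the annotation).
#' @param introns,genome,methylome,chip explicit layers when `sim` is NULL.
#' @return data.frame: intron_id, cell_type, label, then the registry
#'   features.
#' @export
assembleFeatures <- function(sim, cell_type, ir_table, chromatin_calls,
                             pwms = NULL, introns = NULL, genome = NULL,
                             methylome = NULL, chip = NULL) {
  if (!is.null(sim)) {
    introns <- sim@introns
    genome <- sim@genome
    methylome <- sim@methylomes[[cell_type]]
    chip <- sim@chip[[cell_type]]
  }
  if (is.null(pwms)) pwms <- buildSpliceSitePWM(introns, genome)
  keep <- ir_table$call %in% c("retained", "non_retained")
  tab <- ir_table[keep, , drop = FALSE]
  idx <- match(tab$intron_id, introns$intron_id)
  ins <- introns[idx]
  n <- length(ins)
  if (!n) stop("no intron with an unambiguous label", call. = FALSE)

  seqlen <- setNames(Biostrings::width(genome), names(genome))
  regions <- defineRegions(ins, seqlen)
  chrom <- as.character(GenomicRanges::seqnames(ins))
  s <- GenomicRanges::start(ins); e <- GenomicRanges::end(ins)
  minus <- as.character(GenomicRanges::strand(ins)) == "-"

  region_seq <- function(gr) {
    vapply(seq_len(n), function(i) {
      .extract_seq(genome, chrom[i], GenomicRanges::start(gr)[i],
                   GenomicRanges::end(gr)[i],
                   if (minus[i]) "-" else "+")
    }, character(1))
  }
  seq5 <- region_seq(regions$r5ss)
  seq3 <- region_seq(regions$r3ss)
  seqm <- region_seq(regions$rmid)

  don_seq <- acc_seq <- intron_seq <- character(n)
  for (i in seq_len(n)) {
    if (!minus[i]) {
      don_seq[i] <- .extract_seq(genome, chrom[i], s[i] - 3L, s[i] + 5L, "+")
      acc_seq[i] <- .extract_seq(genome, chrom[i], e[i] - 19L, e[i] + 3L, "+")
      intron_seq[i] <- .extract_seq(genome, chrom[i], s[i], e[i], "+")
    } else {
      don_seq[i] <- .extract_seq(genome, chrom[i], e[i] - 5L, e[i] + 3L, "-")
      acc_seq[i] <- .extract_seq(genome, chrom[i], s[i] - 3L, s[i] + 19L, "-")
      intron_seq[i] <- .extract_seq(genome, chrom[i], s[i], e[i], "-")
    }
  }
  bp <- lapply(intron_seq, branchPointFeatures)

  feat <- data.frame(
    intron_id = tab$intron_id, cell_type = cell_type,
    label = tab$call,
    intron_length = GenomicRanges::width(ins),
    gc_5ss = gcContent(seq5), gc_3ss = gcContent(seq3),
    gc_mid = gcContent(seqm),
    cpg_density_5ss = cpgDensity(seq5), cpg_density_3ss = cpgDensity(seq3),
    cpg_density_mid = cpgDensity(seqm),
    ss5_strength = spliceSiteStrength(don_seq, pwms$donor),
    ss3_strength = spliceSiteStrength(acc_seq, pwms$acceptor),
    bp_strength = vapply(bp, `[[`, numeric(1), "strength"),
    bp_distance = vapply(bp, function(b) as.numeric(b$distance), numeric(1)),
    psi_5 = tab$psi5, psi_3 = tab$psi3,
    row.names = NULL)

  meth <- filterCpGCoverage(methylome)
  reg_list <- list(`5ss` = regions$r5ss, `3ss` = regions$r3ss,
                   mid = regions$rmid)
  hm_stats <- lapply(chip, function(m) hmTrackStats(m$peaks, m$pileup))
  for (rn in names(reg_list)) {
    gr <- reg_list[[rn]]
    feat[[paste0("cpg_meth_", rn)]] <- .region_meth_batch(gr, meth, "CpG")
    feat[[paste0("gch_meth_", rn)]] <- .region_meth_batch(gr, meth, "GCH")
    feat[[paste0("nfr_", rn)]] <- presenceFlags(gr, chromatin_calls, "NFR")
    feat[[paste0("nucleosome_", rn)]] <-
      presenceFlags(gr, chromatin_calls, "nucleosome")
    for (mk in c("H3K9me3", "H3K27me3", "H3K27ac", "H3K36me3",
                 "H3K4me1", "H3K4me3")) {
      code <- if (mk %in% names(chip)) {
        hmOverlapCode(gr, chip[[mk]]$peaks, hm_stats[[mk]])
      } else integer(n)
      feat[[paste0(tolower(mk), "_", rn)]] <- code
    }
  }

  registry <- featureRegistry()
  intrinsic_cols <- registry$name[registry$class %in%
                                    c("intrinsic", "transcriptomic")]
  ok <- complete.cases(feat[, intrinsic_cols, drop = FALSE])
  if (any(!ok)) {
    message(sum(!ok), " introns dropped for missing intrinsic features")
    feat <- feat[ok, , drop = FALSE]
  }
  epi_cols <- registry$name[registry$class == "epigenetic"]
  for (cn in epi_cols) {
    miss <- is.na(feat[[cn]])
    if (any(miss)) {
      feat[[cn]][miss] <- 0
    }
  }
  feat <- feat[, c("intron_id", "cell_type", "label", registry$name)]
  validateFeatureTable(feat, registry)
  rownames(feat) <- NULL
  feat
}
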