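#' Trimmed mean intronic abundance
#'
#' The intronic abundance of an intron is the trimmed mean of its per-base
#' read depths after masking bases covered by any annotated feature
#' overlapping the intron and discarding the lowest and highest
#' `floor(trim * n)` values.
#'
#' @param depths numeric vector of per-base read depths over the intron.
#' @param mask integer positions (1-based, relative to the intron) to exclude.
#' @param trim fraction trimmed from each end (default 0.3).
#' @return the trimmed mean depth (non-negative scalar).
#' @examples
#' trimmedIntronicAbundance(0:9) # 4.5
#' @export
trimmedIntronicAbundance <- function(depths, mask = integer(0), trim = 0.3) {
  if (!is.numeric(depths) || any(depths < 0)) {
    stop("per-base depths must be non-negative", call. = FALSE)
  }
  if (length(mask)) depths <- depths[-mask]
  if (!length(depths)) {
    stop("empty measurement: all intron positions are masked", call. = FALSE)
  }
  mean(depths, trim = trim)
}

#' Exonic abundance of an intron from a splice-junction table
#'
#' Returns the read count of the junction whose genomic boundaries exactly
#' match the intron on its strand, in the given sample; 0 when absent.
#' Junction coordinates are the first and last intronic base (1-based,
#' inclusive).
#'
#' @param junctions data.frame with columns chrom, start, end, strand, count,
#'   sample.
#' @param intron a single-range `GRanges` (or data.frame row with chrom,
#'   start, end, strand).
#' @param sample sample / cell-type label.
#' @return non-negative junction read count.
#' @export
exonicAbundance <- function(junctions, intron, sample) {
  if (is(intron, "GRanges")) {
    chrom <- as.character(GenomicRanges::seqnames(intron))[1]
    s <- GenomicRanges::start(intron)[1]
    e <- GenomicRanges::end(intron)[1]
    str <- as.character(GenomicRanges::strand(intron))[1]
  } else {
    chrom <- intron$chrom; s <- intron$start; e <- intron$end
    str <- intron$strand
  }
  hit <- junctions$chrom == chrom & junctions$start == s &
    junctions$end == e & junctions$strand == str &
    junctions$sample == sample
  n <- sum(hit)
  if (n == 0L) return(0)
  if (n > 1L && length(unique(junctions$count[hit])) > 1L) {
    stop("multiple distinct junction records for the same junction/sample",
         call. = FALSE)
  }
  junctions$count[which(hit)[1]]
}

#' Intron retention ratio
#'
#' `IRratio = intronic / (intronic + exonic)`, defined as 0 when both
#' abundances are 0.
#'
#' @param intronic non-negative intronic abundance (trimmed mean depth).
#' @param exonic non-negative exonic abundance (junction reads).
#' @return fraction in `[0, 1]`; vectorized.
#' @examples
#' computeIRratio(10, 30) # 0.25
#' @export
computeIRratio <- function(intronic, exonic) {
  if (any(intronic < 0, na.rm = TRUE) || any(exonic < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  denom <- intronic + exonic
  ifelse(denom > 0, intronic / denom, 0)
}

#' Fraction of unmasked intron bases with nonzero coverage
#'
#' @inheritParams trimmedIntronicAbundance
#' @return fraction in `[0, 1]`.
#' @export
coverageFraction <- function(depths, mask = integer(0)) {
  if (length(mask)) depths <- depths[-mask]
  if (!length(depths)) {
    stop("empty measurement: all intron positions are masked", call. = FALSE)
  }
  mean(depths > 0)
}

#' Call retention status of intron measurements
#'
#' An intron/sample measurement is eligible when the host gene is expressed
#' (FPKM >= 1) and the intron is shorter than 10 kb. Eligible measurements are
#' `retained` when IRratio >= 0.1, intron depth >= 10, coverage fraction >=
#' 0.9 and both flanking-exon PSIs >= 0.9; `non_retained` when IRratio <= 0.01
#' and depth < 10; otherwise `ambiguous`. Ineligible measurements are
#' `ambiguous`. Missing PSI never supports a retained call.
#'
#' @param irratio,depth,coverage_fraction,psi5,psi3,host_fpkm,intron_length
#'   numeric vectors (recycled to common length).
#' @return character vector: `"retained"`, `"non_retained"` or `"ambiguous"`.
#' @export
callRetention <- function(irratio, depth, coverage_fraction,
                          psi5 = 1, psi3 = 1, host_fpkm = 1,
                          intron_length = 0) {
  n <- max(lengths(list(irratio, depth, coverage_fraction, psi5, psi3,
                        host_fpkm, intron_length)))
  irratio <- rep_len(irratio, n); depth <- rep_len(depth, n)
  coverage_fraction <- rep_len(coverage_fraction, n)
  psi5 <- rep_len(psi5, n); psi3 <- rep_len(psi3, n)
  host_fpkm <- rep_len(host_fpkm, n)
  intron_length <- rep_len(intron_length, n)

  eligible <- !is.na(host_fpkm) & host_fpkm >= 1 & intron_length < 10000
  ret <- !is.na(irratio) & irratio >= 0.1 & depth >= 10 &
    coverage_fraction >= 0.9 &
    !is.na(psi5) & psi5 >= 0.9 & !is.na(psi3) & psi3 >= 0.9
  nonret <- !is.na(irratio) & irratio <= 0.01 & depth < 10
  out <- rep("ambiguous", n)
  out[eligible & ret] <- "retained"
  out[eligible & !ret & nonret] <- "non_retained"
  out
}

#' Classify introns into types A, B and C
#'
#' Type A: length < 10 kb, both flanking exons spliced in, no annotated exon
#' overlapping the intron, both flanks constitutive. Type B: as A but with a
#' known overlapping exon (e.g. antisense). Type C: no overlapping exon but an
#' alternative 5' or 3' flanking exon. Anything else (including introns >= 10
#' kb) is `excluded`. An exon is constitutive when it appears in every
#' transcript of its gene.
#'
#' @param introns `GRanges` with metadata columns `gene_id`, `flank5_id`,
#'   `flank3_id`.
#' @param exons annotation `GRanges` with `gene_id`, `transcript_id`,
#'   `exon_id`.
#' @return character vector of types, one per intron.
#' @export
classifyIntronType <- function(introns, exons) {
  md <- S4Vectors::mcols(exons)
  n_tx <- tapply(md$transcript_id, md$gene_id,
                 function(x) length(unique(x)))
  key <- paste(md$gene_id, md$exon_id)
  tx_per_exon <- tapply(md$transcript_id, key, function(x) length(unique(x)))
  constitutive <- function(gene, exon_id) {
    k <- paste(gene, exon_id)
    if (is.na(tx_per_exon[k])) {
      stop("flanking exon '", exon_id, "' absent from annotation",
           call. = FALSE)
    }
    tx_per_exon[[k]] == n_tx[[gene]]
  }
  overlap <- IRanges::overlapsAny(introns, exons, ignore.strand = TRUE)
  im <- S4Vectors::mcols(introns)
  out <- character(length(introns))
  for (i in seq_along(introns)) {
    if (GenomicRanges::width(introns)[i] >= 10000L) {
      out[i] <- "excluded"
      next
    }
    c5 <- constitutive(im$gene_id[i], im$flank5_id[i])
    c3 <- constitutive(im$gene_id[i], im$flank3_id[i])
    out[i] <- if (c5 && c3) {
      if (overlap[i]) "B" else "A"
    } else if (!overlap[i]) "C" else "excluded"
  }
  out
}

#' Percent-spliced-in of an exon from junction counts
#'
#' Inclusion support `I` is the mean, over the exon's existing upstream and
#' downstream sides, of summed junction counts ending at the exon's acceptor
#' or starting at its donor; skipping support `E` is the summed count of
#' junctions spanning the exon entirely. `psi = I / (I + E)`, equal to 1 when
#' `E = 0` and `I > 0`, and undefined (NA) when `I + E = 0`.
#'
#' @param exon_id exon identifier.
#' @param exons annotation `GRanges` (with `exon_id`, `gene_id`, `exon_rank`,
#'   `transcript_id`).
#' @param junctions junction data.frame (chrom, start, end, strand, count,
#'   sample).
#' @param sample sample label.
#' @return list with `psi` (fraction or NA) and `included` (psi >= 0.9).
#' @export
computePSI <- function(exon_id, exons, junctions, sample) {
  md <- S4Vectors::mcols(exons)
  sel <- which(md$exon_id == exon_id)
  if (!length(sel)) stop("exon '", exon_id, "' not found", call. = FALSE)
  ex <- exons[sel[1]]
  gene <- md$gene_id[sel[1]]
  chrom <- as.character(GenomicRanges::seqnames(ex))
  s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
  str <- as.character(GenomicRanges::strand(ex))

  jn <- junctions[junctions$sample == sample & junctions$chrom == chrom &
                    junctions$strand == str, , drop = FALSE]
  gene_ex <- exons[md$gene_id == gene]
  has_upstream <- any(GenomicRanges::end(gene_ex) < s)
  has_downstream <- any(GenomicRanges::start(gene_ex) > e)

  sides <- numeric(0)
  if (has_upstream) sides <- c(sides, sum(jn$count[jn$end == s - 1L]))
  if (has_downstream) sides <- c(sides, sum(jn$count[jn$start == e + 1L]))
  I <- if (length(sides)) mean(sides) else 0
  E <- sum(jn$count[jn$start < s & jn$end > e])
  if (I + E == 0) {
    return(list(psi = NA_real_, included = NA))
  }
  psi <- I / (I + E)
  list(psi = psi, included = psi >= 0.9)
}

#' Bin introns by length and host-gene expression
#'
#' Length bins: short (< 100 nt), medium (100-500 nt, boundaries inclusive),
#' long (> 500 nt). Expression bins: low (1 <= FPKM < 25), medium
#' (25 <= FPKM < 75), high (FPKM >= 75); FPKM < 1 is `excluded`.
#'
#' @param lengths integer intron lengths.
#' @param fpkm host-gene FPKM values.
#' @return data.frame with `length_bin` and `expr_bin` factors.
#' @export
binIntrons <- function(lengths, fpkm) {
  lb <- ifelse(lengths < 100, "short",
               ifelse(lengths <= 500, "medium", "long"))
  eb <- ifelse(is.na(fpkm) | fpkm < 1, "excluded",
               ifelse(fpkm < 25, "low",
                      ifelse(fpkm < 75, "medium", "high")))
  data.frame(length_bin = factor(lb, c("short", "medium", "long")),
             expr_bin = factor(eb, c("excluded", "low", "medium", "high")))
}

#' Quantify intron retention for one sample
#'
#' Runs the full per-intron IR measurement for one cell type: per-base depths
#' are read from the coverage track, bases under any annotated exon
#' overlapping the intron are masked, intronic abundance is the trimmed mean,
#' exonic abundance is the exact-matching junction count, and retention is
#' called with the flanking-exon PSI and host-expression filters.
#'
#' @param x a [SyntheticIRData-class], or an intron `GRanges` when the layers
#'   are passed explicitly.
#' @param cell_type sample / cell-type label.
#' @param exons,coverage,junctions,expression explicit layers (annotation
#'   `GRanges`, `RleList`, junction data.frame, expression data.frame); taken
#'   from `x` when it is a [SyntheticIRData-class].
#' @param trim trimming fraction for the intronic abundance.
#' @return data.frame with one row per intron: abundances, IRratio, depth,
#'   coverage fraction, PSIs, FPKM, intron type, retention call and bins.
#' @export
quantifyIR <- function(x, cell_type, exons = NULL, coverage = NULL,
                       junctions = NULL, expression = NULL, trim = 0.3) {
  if (is(x, "SyntheticIRData")) {
    introns <- x@introns
    exons <- x@exons
    coverage <- x@coverage[[cell_type]]
    junctions <- x@junctions
    expression <- x@expression
  } else {
    introns <- x
  }
  if (is.null(coverage)) stop("no coverage track for '", cell_type, "'",
                              call. = FALSE)
  jn <- junctions[junctions$sample == cell_type, , drop = FALSE]
  fpkm <- expression$fpkm[expression$sample == cell_type][
    match(introns$gene_id,
          expression$gene_id[expression$sample == cell_type])]

  types <- if (!is.null(introns$intron_type)) introns$intron_type
           else classifyIntronType(introns, exons)

  n <- length(introns)
  intronic <- exonic <- covfrac <- psi5 <- psi3 <- numeric(n)
  psi_cache <- new.env(parent = emptyenv())
  get_psi <- function(eid) {
    if (is.null(psi_cache[[eid]])) {
      psi_cache[[eid]] <- computePSI(eid, exons, jn, cell_type)$psi
    }
    psi_cache[[eid]]
  }
  chrom_cov <- coverage
  widths <- GenomicRanges::width(introns)
  starts <- GenomicRanges::start(introns)
  ends <- GenomicRanges::end(introns)
  chroms <- as.character(GenomicRanges::seqnames(introns))
  ov <- GenomicRanges::findOverlaps(introns, exons, ignore.strand = TRUE)

  for (i in seq_len(n)) {
    depths <- as.numeric(S4Vectors::window(chrom_cov[[chroms[i]]],
                                           starts[i], ends[i]))
    mask_idx <- integer(0)
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    if (length(hit)) {
      for (h in hit) {
        a <- max(GenomicRanges::start(exons)[h], starts[i]) - starts[i] + 1L
        b <- min(GenomicRanges::end(exons)[h], ends[i]) - starts[i] + 1L
        mask_idx <- c(mask_idx, a:b)
      }
      mask_idx <- unique(mask_idx)
    }
    if (length(mask_idx) >= widths[i]) {
      intronic[i] <- NA; covfrac[i] <- NA
    } else {
      intronic[i] <- trimmedIntronicAbundance(depths, mask_idx, trim)
      covfrac[i] <- coverageFraction(depths, mask_idx)
    }
    exonic[i] <- exonicAbundance(jn, introns[i], cell_type)
    # flank5_id/flank3_id follow transcription direction already
    p5 <- get_psi(introns$flank5_id[i])
    p3 <- get_psi(introns$flank3_id[i])
    psi5[i] <- if (is.null(p5)) NA else p5
    psi3[i] <- if (is.null(p3)) NA else p3
  }
  irratio <- computeIRratio(ifelse(is.na(intronic), 0, intronic), exonic)
  irratio[is.na(intronic)] <- NA
  call <- callRetention(irratio, intronic, covfrac, psi5, psi3, fpkm, widths)
  call[types == "excluded"] <- "ambiguous"
  bins <- binIntrons(widths, fpkm)
  data.frame(
    intron_id = introns$intron_id, gene_id = introns$gene_id,
    sample = cell_type, length = widths,
    intronic = intronic, exonic = exonic,
    irratio = irratio, depth = intronic, coverage_fraction = covfrac,
    psi5 = psi5, psi3 = psi3, fpkm = fpkm, intron_type = types,
    call = call, length_bin = bins$length_bin, expr_bin = bins$expr_bin,
    row.names = NULL)
}
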