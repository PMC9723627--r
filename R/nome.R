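#' Filter CpG calls by read coverage
#'
#' Keeps CpG sites covered by more than `min_coverage` reads (default > 5,
#' the WGBS coverage filter).
#'
#' @param calls cytosine-report data.frame (columns `context`,
#'   `count_methylated`, `count_unmethylated`).
#' @param min_coverage strict lower bound on total reads.
#' @return the filtered data.frame.
#' @export
filterCpGCoverage <- function(calls, min_coverage = 5) {
  total <- calls$count_methylated + calls$count_unmethylated
  keep <- calls$context != "CpG" | total > min_coverage
  calls[keep, , drop = FALSE]
}

.site_levels <- function(calls, signal = c("methylation", "occupancy")) {
  signal <- match.arg(signal)
  total <- calls$count_methylated + calls$count_unmethylated
  lv <- calls$count_methylated / total
  if (signal == "occupancy") lv <- 1 - lv
  lv
}

#' Chain elevated GCH sites into candidate regions
#'
#' Greedily chains consecutive elevated GCH sites, breaking whenever the
#' distance between consecutive elevated sites exceeds `max_gap`. A site is
#' elevated when its methylation exceeds `threshold_mult` times the
#' chromosome-wide read-weighted mean (methylation mode, accessible regions)
#' or falls below the mean divided by `threshold_mult` (occupancy mode,
#' methylation-depleted protected regions). Candidate intervals span the first to last chained site
#' (1-based inclusive) and must be strictly longer than `min_len`.
#'
#' @param calls GCH cytosine-report data.frame sorted by position (columns
#'   `chrom`, `pos`, `count_methylated`, `count_unmethylated`).
#' @param max_gap maximum distance (bp) between consecutive chained sites
#'   (150 for NFRs, 20 for nucleosomes).
#' @param min_len minimum interval length in bp, exclusive (40 NFR / 140
#'   nucleosome).
#' @param signal `"methylation"` or `"occupancy"`.
#' @param threshold_mult multiplier on the chromosome-wide mean used as the
#'   elevation threshold.
#' @param extend_to_midpoint when TRUE, each interval boundary is pushed
#'   halfway towards the nearest flanking GCH site (capped at `max_gap / 2`);
#'   the true footprint boundary lies between the last elevated site and its
#'   unelevated neighbour, which matters for short protected footprints.
#' @return data.frame of candidate intervals: chrom, start, end, n_sites.
#' @export
segmentCandidates <- function(calls, max_gap = 150, min_len = 40,
                              signal = c("methylation", "occupancy"),
                              threshold_mult = 1,
                              extend_to_midpoint = FALSE) {
  signal <- match.arg(signal)
  out <- list()
  for (chrom in unique(calls$chrom)) {
    cc <- calls[calls$chrom == chrom, , drop = FALSE]
    if (is.unsorted(cc$pos)) {
      stop("GCH calls must be sorted by position", call. = FALSE)
    }
    lv <- .site_levels(cc, "methylation")
    total <- cc$count_methylated + cc$count_unmethylated
    chrom_mean <- sum(cc$count_methylated) / sum(total)
    # accessible sites are methylation-enriched; protected (occupied) sites
    # are methylation-depleted relative to the chromosome-wide mean
    keep <- if (signal == "methylation") {
      which(lv > chrom_mean * threshold_mult)
    } else {
      which(lv < chrom_mean / threshold_mult)
    }
    if (!length(keep)) next
    pos <- cc$pos[keep]
    brk <- c(TRUE, diff(pos) > max_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      p <- pos[grp == g]
      lo <- min(p); hi <- max(p)
      if (extend_to_midpoint) {
        cap <- max_gap %/% 2L
        prev <- cc$pos[cc$pos < lo]
        nxt <- cc$pos[cc$pos > hi]
        lo <- lo - if (length(prev)) min((lo - max(prev)) %/% 2L, cap) else cap
        hi <- hi + if (length(nxt)) min((min(nxt) - hi) %/% 2L, cap) else cap
      }
      len <- hi - lo + 1L
      if (len > min_len) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = lo, end = hi, n_sites = length(p))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0)))
  }
  do.call(rbind, out)
}

#' One-sided Fisher test of a candidate region against local background
#'
#' Builds the 2x2 table of summed (methylated, unmethylated) read counts in
#' the candidate versus the flanking background (`background_flank` bp on each
#' side, candidate excluded) and computes the one-sided Fisher exact p-value
#' for enrichment of the signal (methylation for NFRs; occupancy swaps the
#' two count columns).
#'
#' @param candidate one-row data.frame (chrom, start, end).
#' @param calls GCH cytosine-report data.frame.
#' @param background_flank flank width in bp (4000 NFR / 1000 nucleosome).
#' @param signal `"methylation"` or `"occupancy"`.
#' @return list: `p_value`, `region_meth`, `background_meth`, `n_sites`
#'   (region GCH sites), or NULL when the background holds no GCH site.
#' @export
fisherRegionTest <- function(candidate, calls, background_flank = 4000,
                             signal = c("methylation", "occupancy")) {
  signal <- match.arg(signal)
  cc <- calls[calls$chrom == candidate$chrom, , drop = FALSE]
  in_region <- cc$pos >= candidate$start & cc$pos <= candidate$end
  in_bg <- !in_region &
    cc$pos >= candidate$start - background_flank &
    cc$pos <= candidate$end + background_flank
  if (!any(in_region)) stop("candidate contains no GCH site", call. = FALSE)
  if (!any(in_bg)) {
    message("candidate at ", candidate$chrom, ":", candidate$start,
            " skipped: empty background")
    return(NULL)
  }
  m_r <- sum(cc$count_methylated[in_region])
  u_r <- sum(cc$count_unmethylated[in_region])
  m_b <- sum(cc$count_methylated[in_bg])
  u_b <- sum(cc$count_unmethylated[in_bg])
  if (signal == "occupancy") {
    tmp <- m_r; m_r <- u_r; u_r <- tmp
    tmp <- m_b; m_b <- u_b; u_b <- tmp
  }
  # P(X >= m_r) for X ~ hypergeometric over the pooled reads
  p <- phyper(m_r - 1, m_r + m_b, u_r + u_b, m_r + u_r, lower.tail = FALSE)
  list(p_value = p,
       region_meth = m_r / (m_r + u_r),
       background_meth = m_b / (m_b + u_b),
       n_sites = sum(in_region))
}

.call_regions <- function(calls, max_gap, min_len, background_flank, signal,
                          p_cutoff = 0.05, threshold_mult = 1,
                          extend_to_midpoint = FALSE) {
  gch <- calls[calls$context == "GCH", , drop = FALSE]
  gch <- gch[order(gch$chrom, gch$pos), , drop = FALSE]
  # pool both strands by position
  agg <- stats::aggregate(
    cbind(count_methylated, count_unmethylated) ~ chrom + pos, gch, sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  agg$context <- "GCH"
  cand <- segmentCandidates(agg, max_gap = max_gap, min_len = min_len,
                            signal = signal, threshold_mult = threshold_mult,
                            extend_to_midpoint = extend_to_midpoint)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    res <- fisherRegionTest(cand[i, ], agg, background_flank, signal)
    if (is.null(res)) next
    if (res$p_value <= p_cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cand$chrom[i], start = cand$start[i], end = cand$end[i],
        kind = if (signal == "methylation") "NFR" else "nucleosome",
        p_value = res$p_value, region_meth = res$region_meth,
        background_meth = res$background_meth, n_sites = res$n_sites)
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), kind = character(0),
                      p_value = numeric(0), region_meth = numeric(0),
                      background_meth = numeric(0), n_sites = integer(0)))
  }
  do.call(rbind, rows)
}

#' Call nucleosome-free regions from GCH methylation
#'
#' Chains GCH sites with methylation above 1.5x the chromosome-wide mean
#' (max gap 150 bp), keeps intervals > 40 bp, and retains those whose summed
#' methylated/unmethylated read counts are significantly enriched over the
#' +/-4000 bp background (one-sided Fisher, p <= 0.05).
#'
#' @param calls cytosine-report data.frame (GCH rows are used).
#' @param max_gap,min_len,background_flank,p_cutoff,threshold_mult caller
#'   parameters (defaults per the NFR definition).
#' @return data.frame of NFR calls (chrom, start, end, kind, p_value,
#'   region_meth, background_meth, n_sites).
#' @export
callNFRs <- function(calls, max_gap = 150, min_len = 40,
                     background_flank = 4000, p_cutoff = 0.05,
                     threshold_mult = 1.5) {
  .call_regions(calls, max_gap, min_len, background_flank, "methylation",
                p_cutoff, threshold_mult)
}

#' Call positioned nucleosomes from GCH occupancy
#'
#' Same procedure as [callNFRs()] but seeded on methylation-depleted
#' (protected) sites, with max gap 20 bp, minimum length 140 bp and +/-1000
#' bp background; called footprints extend halfway to the nearest flanking
#' GCH site, since the protection boundary lies between the last depleted
#' site and its accessible neighbour.
#'
#' @inheritParams callNFRs
#' @return data.frame of nucleosome calls.
#' @export
callNucleosomes <- function(calls, max_gap = 20, min_len = 140,
                            background_flank = 1000, p_cutoff = 0.05,
                            threshold_mult = 1.5) {
  .call_regions(calls, max_gap, min_len, background_flank, "occupancy",
                p_cutoff, threshold_mult, extend_to_midpoint = TRUE)
}

#' Pooled methylation level of an interval
#'
#' Summed methylated over summed total read counts across the sites of the
#' requested context inside the interval; `NA` when the interval holds no
#' site.
#'
#' @param chrom,start,end interval (1-based inclusive).
#' @param calls cytosine-report data.frame.
#' @param context `"GCH"` or `"CpG"`.
#' @return fraction in `[0, 1]` or `NA`.
#' @export
regionMethylation <- function(chrom, start, end, calls, context = "GCH") {
  cc <- calls[calls$context == context & calls$chrom == chrom &
                calls$pos >= start & calls$pos <= end, , drop = FALSE]
  if (!nrow(cc)) return(NA_real_)
  sum(cc$count_methylated) /
    sum(cc$count_methylated + cc$count_unmethylated)
}
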