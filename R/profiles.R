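#' Build a position-binned GCH methylation profile matrix
#'
#' For every intron, pools GCH methylated/total read counts per `bin_size`-bp
#' bin over the +/-200 bp window around the anchor (5' splice site, 3' splice
#' site or intron midpoint) into percent methylation. Profiles are
#' strand-oriented: column 1 is always the transcriptionally most upstream
#' bin. Bins without GCH sites are `NA`; introns whose rows are entirely
#' missing are dropped with a message.
#'
#' @param introns intron `GRanges` (with `intron_id`).
#' @param calls cytosine-report data.frame (GCH rows used; strands pooled by
#'   position).
#' @param anchor `"5ss"`, `"3ss"` or `"mid"`.
#' @param bin_size bin width in bp (default 10; 400 must be divisible by it).
#' @param state retention-state tag stored on the result.
#' @return a [ProfileMatrix-class] (rows named by intron id).
#' @export
buildProfileMatrix <- function(introns, calls, anchor = c("5ss", "3ss", "mid"),
                               bin_size = 10, state = "retained") {
  anchor <- match.arg(anchor)
  if (400 %% bin_size != 0) stop("bin_size must divide 400", call. = FALSE)
  nb <- as.integer(400 / bin_size)
  gch <- calls[calls$context == "GCH", , drop = FALSE]

  s <- GenomicRanges::start(introns)
  e <- GenomicRanges::end(introns)
  minus <- as.character(GenomicRanges::strand(introns)) == "-"
  pos_anchor <- switch(anchor,
    "5ss" = ifelse(minus, e, s),
    "3ss" = ifelse(minus, s, e),
    "mid" = s + floor(GenomicRanges::width(introns) / 2))

  n <- length(introns)
  # bin b (1..nb) covers transcription offsets [-200 + (b-1)*bs, -200 + b*bs)
  starts <- matrix(0L, n, nb)
  for (b in seq_len(nb)) {
    off <- -200L + (b - 1L) * bin_size
    starts[, b] <- ifelse(minus,
                          pos_anchor - off - bin_size + 1L,
                          pos_anchor + off)
  }
  bin_gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(introns)), nb),
    IRanges::IRanges(pmax(1L, as.vector(starts)),
                     pmax(1L, as.vector(starts)) + bin_size - 1L))
  sgr <- GenomicRanges::GRanges(gch$chrom, IRanges::IRanges(gch$pos, gch$pos))
  ov <- GenomicRanges::findOverlaps(bin_gr, sgr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  m <- matrix(NA_real_, n, nb)
  if (length(qh)) {
    msum <- tapply(gch$count_methylated[sh], qh, sum)
    tsum <- tapply(gch$count_methylated[sh] + gch$count_unmethylated[sh],
                   qh, sum)
    cells <- as.integer(names(msum))
    m[cells] <- 100 * as.numeric(msum) / as.numeric(tsum)
  }
  rownames(m) <- introns$intron_id
  all_missing <- rowSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " introns dropped: no GCH sites in any bin")
    m <- m[!all_missing, , drop = FALSE]
  }
  new("ProfileMatrix", matrix = m, anchor = anchor, bin_size = bin_size,
      clusters = rep(NA_integer_, nrow(m)), state = state)
}

#' Cluster accessibility profiles by complete-linkage hierarchical clustering
#'
#' Rows are lightly smoothed with an NA-aware running mean (half-width
#' `smooth_halfwidth` bins), rows observed in fewer than `min_observed` of
#' their bins are set aside as unassigned (`NA` cluster), remaining missing
#' bins are mean-imputed per column (for the clustering only), and the rows
#' are clustered with complete linkage on Euclidean distance. Because
#' complete linkage is sensitive to stray profiles, the tree is cut at the
#' shallowest depth that yields `k` clusters of at least `min_size` rows;
#' rows falling in smaller (outlier) clusters are reassigned to the nearest
#' major-cluster centroid. Fully deterministic.
#'
#' @param pm a [ProfileMatrix-class].
#' @param k number of clusters (default 5).
#' @param smooth_halfwidth running-mean half-width in bins (0 disables).
#' @param min_observed minimum fraction of non-missing bins a row needs to be
#'   clustered.
#' @param min_size minimum size of a major cluster (default
#'   `max(5, 2.5%)` of clustered rows; ignored when the plain `k`-cut
#'   already yields `k` such clusters).
#' @return the [ProfileMatrix-class] with `clusters` filled in (`NA` for rows
#'   set aside as too sparse).
#' @export
clusterProfiles <- function(pm, k = 5L, smooth_halfwidth = 2L,
                            min_observed = 0.5, min_size = NULL) {
  m <- pm@matrix
  if (k > nrow(m)) stop("k exceeds the number of profiles", call. = FALSE)
  assign <- rep(NA_integer_, nrow(m))
  keep <- rowMeans(!is.na(m)) >= min_observed
  if (sum(keep) < k) keep <- rep(TRUE, nrow(m))
  mm <- m[keep, , drop = FALSE]
  if (smooth_halfwidth > 0L) {
    h <- smooth_halfwidth
    mm <- t(apply(mm, 1, function(r) {
      vapply(seq_along(r), function(j) {
        w <- r[max(1, j - h):min(length(r), j + h)]
        if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
      }, numeric(1))
    }))
  }
  cmeans <- colMeans(mm, na.rm = TRUE)
  cmeans[is.nan(cmeans)] <- 0
  for (j in seq_len(ncol(mm))) {
    miss <- is.na(mm[, j])
    if (any(miss)) mm[miss, j] <- cmeans[j]
  }
  n <- nrow(mm)
  hc <- hclust(dist(mm), method = "complete")
  if (is.null(min_size)) min_size <- max(5L, ceiling(0.025 * n))
  if (k >= n || min_size <= 1L) {
    assign[keep] <- as.integer(cutree(hc, k = min(k, n)))
    pm@clusters <- assign
    return(pm)
  }
  cl <- cutree(hc, k = k)
  big <- as.integer(names(which(table(cl) >= min_size)))
  if (length(big) < k) {
    for (kk in (k + 1L):min(n, k + 30L)) {
      cl <- cutree(hc, k = kk)
      big <- as.integer(names(which(table(cl) >= min_size)))
      if (length(big) >= k) break
    }
    big <- head(big, k)
  }
  cent <- t(vapply(big, function(b) colMeans(mm[cl == b, , drop = FALSE]),
                   numeric(ncol(mm))))
  lab <- match(cl, big)
  for (i in which(is.na(lab))) {
    lab[i] <- which.min(rowSums(sweep(cent, 2, mm[i, ])^2))
  }
  assign[keep] <- lab
  pm@clusters <- assign
  pm
}

#' Mean accessibility curves per retention state
#'
#' Column means (missing bins excluded) of the retained-state and
#' non-retained-state profile matrices of the same introns, or of a matched
#' control set.
#'
#' @param pm_retained,pm_non [ProfileMatrix-class] objects.
#' @return data.frame: bin, offset (bp of bin start relative to anchor),
#'   retained, non_retained.
#' @export
aggregateGroupProfiles <- function(pm_retained, pm_non) {
  if (!nrow(pm_retained@matrix) || !nrow(pm_non@matrix)) {
    stop("empty profile group", call. = FALSE)
  }
  nb <- ncol(pm_retained@matrix)
  data.frame(
    bin = seq_len(nb),
    offset = -200 + (seq_len(nb) - 1) * pm_retained@bin_size,
    retained = colMeans(pm_retained@matrix, na.rm = TRUE),
    non_retained = colMeans(pm_non@matrix, na.rm = TRUE))
}

#' Select length/GC-matched control introns
#'
#' Nearest-neighbour matching (without replacement) of each query intron to a
#' control pool on intron length and GC content, with calipers |deltaGC| <=
#' 0.05 and length ratio <= 2. Queries with no admissible control are
#' unmatched (`NA`).
#'
#' @param query_len,query_gc query intron lengths and GC fractions.
#' @param pool_len,pool_gc control pool lengths and GC fractions.
#' @param gc_caliper,len_ratio caliper settings.
#' @return integer vector of pool indices (or `NA`), one per query.
#' @export
matchedControls <- function(query_len, query_gc, pool_len, pool_gc,
                            gc_caliper = 0.05, len_ratio = 2) {
  used <- logical(length(pool_len))
  out <- integer(length(query_len))
  for (i in seq_along(query_len)) {
    ratio <- pmax(pool_len / query_len[i], query_len[i] / pool_len)
    ok <- !used & abs(pool_gc - query_gc[i]) <= gc_caliper & ratio <= len_ratio
    if (!any(ok)) { out[i] <- NA_integer_; next }
    d <- (log(pool_len) - log(query_len[i]))^2 / log(len_ratio)^2 +
      (pool_gc - query_gc[i])^2 / gc_caliper^2
    d[!ok] <- Inf
    out[i] <- which.min(d)
    used[out[i]] <- TRUE
  }
  out
}

#' Adjust H3K36me3 counts for chromatin accessibility
#'
#' Fits a log-link Poisson regression of per-intron H3K36me3 counts on
#' percent GCH methylation (reporting the overdispersion scale), takes
#' Pearson residuals and tests the retained versus non-retained residual
#' difference with a two-sample t test. When group differences in counts are
#' entirely mediated by accessibility, the adjusted contrast is null.
#'
#' @param counts non-negative integer H3K36me3 counts per intron window.
#' @param gch percent (or fraction) GCH methylation per window.
#' @param groups factor/character: `"retained"` or `"non_retained"`.
#' @return list: `slope`, `slope_ci` (95%), `dispersion`, `residual_diff`
#'   (retained minus non-retained mean Pearson residual), `p_value`.
#' @export
h3k36me3GlmAdjust <- function(counts, gch, groups) {
  .assert_count(counts, "counts")
  fit <- glm(counts ~ gch, family = poisson())
  pr <- stats::residuals(fit, type = "pearson")
  disp <- sum(pr^2) / fit$df.residual
  ci <- suppressMessages(stats::confint.default(fit))["gch", ]
  g <- groups == "retained"
  tt <- t.test(pr[g], pr[!g])
  list(slope = unname(stats::coef(fit)["gch"]),
       slope_ci = unname(ci),
       dispersion = disp,
       residual_diff = unname(diff(rev(tt$estimate))),
       p_value = tt$p.value)
}

#' Split introns into first-in-transcript versus internal
#'
#' An intron is "first" when it is the first intron of any transcript of its
#' gene (promoter-proximal); everything else is internal.
#'
#' @param introns intron `GRanges` with `intron_rank` metadata.
#' @return list with `first` and `internal` intron-id vectors.
#' @export
firstVsInternalStratify <- function(introns) {
  first <- introns$intron_id[introns$intron_rank == 1L]
  list(first = unique(first),
       internal = unique(setdiff(introns$intron_id, first)))
}
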