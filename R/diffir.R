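#' Audic-Claverie p-value for two digital counts
#'
#' Under the Audic-Claverie posterior predictive, given `x` reads in a library
#' of size `N1`, the count `Y` in a library of size `N2` follows
#' `p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))` (a negative
#' binomial with size `x + 1` and success probability `N1 / (N1 + N2)`).
#' The two-sided p-value doubles (capped at 1) the smaller of the two
#' cross-direction lower tails, `P(Y <= y | x)` and `P(X <= x | y)`, each by
#' direct summation in log space so counts up to 1e5 do not overflow. This
#' doubling convention is exactly symmetric under swapping the samples.
#'
#' @param x,y observed counts in the two samples (non-negative integers).
#' @param N1,N2 library sizes (positive finite reals).
#' @param alternative `"two.sided"` (default) or `"one.sided"` (lower tail of
#'   `y` given `x`, i.e. evidence that sample 2 is depleted).
#' @return p-value in `(0, 1]`.
#' @examples
#' audicClaveriePValue(0, 30, 1, 1) # < 1e-6
#' @export
audicClaveriePValue <- function(x, y, N1 = 1, N2 = 1,
                                alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  .assert_count(x, "x"); .assert_count(y, "y")
  if (!is.finite(N1) || !is.finite(N2) || N1 <= 0 || N2 <= 0) {
    stop("library sizes must be positive and finite", call. = FALSE)
  }
  lower_tail <- function(x, y, r) {
    # P(Y <= y | x) with Y ~ AC predictive at library ratio r = N2/N1
    k <- 0:y
    lf <- k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(r)
    min(1, exp(logsumexp(lf)))
  }
  lower <- lower_tail(x, y, N2 / N1)
  if (alternative == "one.sided") return(lower)
  cross <- lower_tail(y, x, N1 / N2)
  min(1, 2 * min(lower, cross))
}

#' Differential retention calls between two cell types
#'
#' Compares the IR measurements of two cell types intron by intron with the
#' Audic-Claverie test on rounded trimmed intronic depths. An intron is
#' significantly differentially retained when p <= 0.05, |delta IR| >= 0.1
#' and the retention criteria are met in at least one of the two cell types.
#' Ineligible introns (host FPKM < 1 or length >= 10 kb) are skipped.
#'
#' @param ir_tables data.frame of per-sample IR measurements (rbind of
#'   [quantifyIR()] outputs).
#' @param cell_a,cell_b the two cell-type labels.
#' @param lib_a,lib_b library sizes (summed over replicates when counts are
#'   pooled); only their ratio matters.
#' @param p_cutoff,delta_cutoff significance thresholds (defaults 0.05, 0.1).
#' @param adjust multiple-testing adjustment: `"none"` (default, raw p-values)
#'   or `"BH"`.
#' @return data.frame: intron_id, cell_a, cell_b, xA, xB, delta_ir, p_value,
#'   significant.
#' @export
callDifferential <- function(ir_tables, cell_a, cell_b, lib_a = 1, lib_b = 1,
                             p_cutoff = 0.05, delta_cutoff = 0.1,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ta <- ir_tables[ir_tables$sample == cell_a, , drop = FALSE]
  tb <- ir_tables[ir_tables$sample == cell_b, , drop = FALSE]
  common <- intersect(ta$intron_id, tb$intron_id)
  ta <- ta[match(common, ta$intron_id), , drop = FALSE]
  tb <- tb[match(common, tb$intron_id), , drop = FALSE]
  eligible <- !is.na(ta$fpkm) & !is.na(tb$fpkm) &
    ta$fpkm >= 1 & tb$fpkm >= 1 & ta$length < 10000 &
    !is.na(ta$depth) & !is.na(tb$depth)
  if (any(!eligible)) {
    message(sum(!eligible), " ineligible introns skipped in ",
            cell_a, " vs ", cell_b)
  }
  ta <- ta[eligible, , drop = FALSE]
  tb <- tb[eligible, , drop = FALSE]
  xA <- round(ta$depth)
  xB <- round(tb$depth)
  p <- vapply(seq_along(xA), function(i) {
    audicClaveriePValue(xA[i], xB[i], lib_a, lib_b)
  }, numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  delta <- ta$irratio - tb$irratio
  sig <- p <= p_cutoff & abs(delta) >= delta_cutoff &
    (ta$call == "retained" | tb$call == "retained")
  data.frame(intron_id = ta$intron_id, cell_a = cell_a, cell_b = cell_b,
             xA = xA, xB = xB, delta_ir = delta, p_value = p,
             significant = sig, row.names = NULL)
}

#' Identify dynamic introns across cell types
#'
#' Dynamic introns are retained (IRratio >= 0.1, depth >= 10, coverage >= 90%,
#' flank PSIs >= 0.9) in at least one cell type and non-retained (IRratio <=
#' 0.01, depth < 10) in at least one other; ambiguous states qualify for
#' neither side.
#'
#' @param ir_tables data.frame of per-sample IR measurements with a `call`
#'   column (rbind of [quantifyIR()] outputs across >= 2 cell types).
#' @return character vector of dynamic intron ids.
#' @export
findDynamicIntrons <- function(ir_tables) {
  if (length(unique(ir_tables$sample)) < 2L) {
    stop("at least two cell types are required", call. = FALSE)
  }
  ret <- unique(ir_tables$intron_id[ir_tables$call == "retained"])
  nonret <- unique(ir_tables$intron_id[ir_tables$call == "non_retained"])
  sort(intersect(ret, nonret))
}

#' Retention-state transition table between two cell types
#'
#' Cross-tabulates retention calls of one cell type against another (the
#' state-flow summary behind alluvial-style displays).
#'
#' @inheritParams callDifferential
#' @return a contingency table of calls in `cell_a` versus `cell_b`.
#' @export
stateTransitionTable <- function(ir_tables, cell_a, cell_b) {
  ta <- ir_tables[ir_tables$sample == cell_a, , drop = FALSE]
  tb <- ir_tables[ir_tables$sample == cell_b, , drop = FALSE]
  common <- intersect(ta$intron_id, tb$intron_id)
  table(ta$call[match(common, ta$intron_id)],
        tb$call[match(common, tb$intron_id)],
        dnn = c(cell_a, cell_b))
}
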