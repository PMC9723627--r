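#' Parameters for the synthetic multi-omics generator
#'
#' Holds the study-design parameters used by [simulateIRData()]: the number of
#' genes and introns, the cell-type panel, the fractions of retained and
#' dynamic introns, the planted logistic coupling between intrinsic features
#' and retention, the NFR coupling probability, NOMe/WGBS methylation levels,
#' and sequencing depths.
#'
#' @slot n_genes number of simulated genes.
#' @slot introns_per_gene introns per gene.
#' @slot cell_types character vector of cell-type labels.
#' @slot fraction_retained fraction of introns retained in at least one cell
#'   type.
#' @slot fraction_dynamic fraction of introns that switch retention state
#'   between cell types.
#' @slot effect_weights named numeric vector of planted logistic coefficients
#'   on standardized log-length, GC content and splice-site strength.
#' @slot nfr_coupling_prob probability that a retained intron carries a
#'   splice-site-proximal nucleosome-free region.
#' @slot gch_meth_nfr GCH methylation level inside planted NFRs.
#' @slot gch_meth_background GCH methylation level outside NFRs.
#' @slot cpg_bimodal_modes the two modes of the bimodal CpG methylation
#'   distribution.
#' @slot mean_coverage mean per-base sequencing depth of a gene.
#' @slot nb_dispersion negative-binomial dispersion of per-base read depth.
#' @slot nome_coverage mean per-site NOMe-seq read coverage.
#' @slot h3k36_depletion multiplicative H3K36me3 depletion over retained
#'   introns in dynamic-chromatin mode (1 = no depletion).
#' @slot seed integer seed; identical seed and parameters give byte-identical
#'   output.
#' @export
setClass("SimulationParams",
  representation(
    n_genes = "integer",
    introns_per_gene = "integer",
    cell_types = "character",
    fraction_retained = "numeric",
    fraction_dynamic = "numeric",
    effect_weights = "numeric",
    nfr_coupling_prob = "numeric",
    gch_meth_nfr = "numeric",
    gch_meth_background = "numeric",
    cpg_bimodal_modes = "numeric",
    mean_coverage = "numeric",
    nb_dispersion = "numeric",
    nome_coverage = "numeric",
    h3k36_depletion = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  chk_frac <- function(x, name) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      msg <<- c(msg, sprintf("'%s' must lie in [0, 1]", name))
    }
  }
  if (length(object@n_genes) != 1L || object@n_genes < 1L) {
    msg <- c(msg, "'n_genes' must be a positive integer")
  }
  if (length(object@introns_per_gene) != 1L || object@introns_per_gene < 1L) {
    msg <- c(msg, "'introns_per_gene' must be a positive integer")
  }
  if (length(object@cell_types) < 1L || anyDuplicated(object@cell_types)) {
    msg <- c(msg, "'cell_types' must be distinct non-empty labels")
  }
  chk_frac(object@fraction_retained, "fraction_retained")
  chk_frac(object@fraction_dynamic, "fraction_dynamic")
  chk_frac(object@nfr_coupling_prob, "nfr_coupling_prob")
  chk_frac(object@gch_meth_nfr, "gch_meth_nfr")
  chk_frac(object@gch_meth_background, "gch_meth_background")
  chk_frac(object@cpg_bimodal_modes, "cpg_bimodal_modes")
  if (length(object@cpg_bimodal_modes) != 2L) {
    msg <- c(msg, "'cpg_bimodal_modes' must have length 2")
  }
  if (!all(c("length", "gc", "ss_strength") %in% names(object@effect_weights))) {
    msg <- c(msg, "'effect_weights' must name 'length', 'gc' and 'ss_strength'")
  }
  if (object@mean_coverage <= 0) msg <- c(msg, "'mean_coverage' must be positive")
  if (object@nb_dispersion <= 0) msg <- c(msg, "'nb_dispersion' must be positive")
  if (object@nome_coverage <= 0) msg <- c(msg, "'nome_coverage' must be positive")
  if (object@h3k36_depletion < 0) msg <- c(msg, "'h3k36_depletion' must be >= 0")
  if (object@fraction_dynamic > object@fraction_retained) {
    msg <- c(msg, "'fraction_dynamic' cannot exceed 'fraction_retained'")
  }
  if (length(msg)) msg else TRUE
})

#' Linked synthetic multi-omics data set
#'
#' Container for one run of the generator: annotation (exons and introns as
#' `GRanges`), genome sequence, per-cell-type coverage tracks, splice-junction
#' counts, expression table, CpG/GCH methylomes, histone-mark tracks, and the
#' ground truth the data were generated from.
#'
#' @slot params the [SimulationParams-class] used.
#' @slot exons annotation exons (`GRanges` with `gene_id`, `transcript_id`,
#'   `exon_rank`).
#' @slot introns intron records (`GRanges` with ids, flanks, type).
#' @slot genome `DNAStringSet` of the simulated contig(s).
#' @slot truth list with per-intron-per-cell-type states (`states`),
#'   per-intron attributes (`introns`) and planted NFR intervals (`nfrs`).
#' @slot coverage named list (cell type) of `RleList` per-base read depth.
#' @slot junctions data.frame of splice-junction counts.
#' @slot expression data.frame of gene FPKM per cell type.
#' @slot methylomes named list (cell type) of cytosine-report data.frames.
#' @slot chip named list (cell type) of per-mark `list(pileup=, peaks=)`.
#' @export
setClass("SyntheticIRData",
  representation(
    params = "SimulationParams",
    exons = "GRanges",
    introns = "GRanges",
    genome = "DNAStringSet",
    truth = "list",
    coverage = "list",
    junctions = "data.frame",
    expression = "data.frame",
    methylomes = "list",
    chip = "list"
  )
)

#' Fitted IR classifier with scaled variable importance
#'
#' Wraps either an elastic-net logistic regression or a conditional-inference
#' forest fitted to an intron feature table, together with its hyperparameters,
#' the scaled variable-importance ranking and (optionally) cross-validated
#' performance.
#'
#' @slot kind `"EN"` or `"cRF"`.
#' @slot fit the underlying fit object (glmnet fit or forest list).
#' @slot hyperparameters named list (EN: alpha, lambda; cRF: n_trees, mtry,
#'   split alpha).
#' @slot importance named numeric vector of scaled importances (sums to 1).
#' @slot feature_names feature registry order used at fit time.
#' @slot training_label free-text label of the training data (e.g. cell type).
#' @slot cv_auc cross-validated ROC AUC at the selected hyperparameters
#'   (`NA` if not computed).
#' @slot seed integer seed the fit is reproducible from.
#' @export
setClass("IRModelFit",
  representation(
    kind = "character",
    fit = "list",
    hyperparameters = "list",
    importance = "numeric",
    feature_names = "character",
    training_label = "character",
    cv_auc = "numeric",
    seed = "integer"
  )
)

setValidity("IRModelFit", function(object) {
  msg <- character()
  if (!object@kind %in% c("EN", "cRF")) {
    msg <- c(msg, "'kind' must be 'EN' or 'cRF'")
  }
  s <- sum(object@importance)
  if (length(object@importance) && s > 0 && abs(s - 1) > 1e-9) {
    msg <- c(msg, "importances must sum to 1 (or be all zero)")
  }
  if (any(object@importance < 0)) msg <- c(msg, "importances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Position-binned GCH methylation profiles around an anchor
#'
#' Rows are introns in a stated retention state, columns are position bins
#' over +/-200 bp around the chosen anchor (5' splice site, 3' splice site or
#' intron midpoint), values are percent GCH methylation. Missing bins are `NA`
#' in the stored matrix; mean imputation happens only inside the clustering
#' step.
#'
#' @slot matrix numeric matrix, introns x bins, values in `[0, 100]` or `NA`.
#' @slot anchor `"5ss"`, `"3ss"` or `"mid"`.
#' @slot bin_size bin width in bp.
#' @slot clusters integer cluster assignment per row (`NA` before clustering).
#' @slot state the IR state of the rows (`"retained"` or `"non_retained"`).
#' @export
setClass("ProfileMatrix",
  representation(
    matrix = "matrix",
    anchor = "character",
    bin_size = "numeric",
    clusters = "integer",
    state = "character"
  )
)

setValidity("ProfileMatrix", function(object) {
  msg <- character()
  v <- object@matrix
  if (any(v < 0 | v > 100, na.rm = TRUE)) {
    msg <- c(msg, "profile values must be percentages in [0, 100]")
  }
  if (ncol(v) != round(400 / object@bin_size)) {
    msg <- c(msg, "column count must equal 400 / bin_size")
  }
  if (!object@anchor %in% c("5ss", "3ss", "mid")) {
    msg <- c(msg, "'anchor' must be one of '5ss', '3ss', 'mid'")
  }
  if (length(object@clusters) &&
      length(object@clusters) != nrow(v)) {
    msg <- c(msg, "one cluster assignment per row required")
  }
  if (length(msg)) msg else TRUE
})
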