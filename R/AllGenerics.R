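#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @import methods
NULL

#' Accessors for dynamIR containers
#'
#' Accessor generics for [SyntheticIRData-class], [IRModelFit-class] and
#' [ProfileMatrix-class] objects.
#'
#' @param x a dynamIR S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("coverageTracks", function(x) standardGeneric("coverageTracks"))

#' @rdname accessors
#' @export
setGeneric("junctionCounts", function(x) standardGeneric("junctionCounts"))

#' @rdname accessors
#' @export
setGeneric("expressionTable", function(x) standardGeneric("expressionTable"))

#' @rdname accessors
#' @export
setGeneric("methylomeCalls", function(x, cell_type) standardGeneric("methylomeCalls"))

#' @rdname accessors
#' @export
setGeneric("chipTracks", function(x, cell_type) standardGeneric("chipTracks"))

#' @rdname accessors
#' @export
setGeneric("plantedNFRs", function(x) standardGeneric("plantedNFRs"))

#' @rdname accessors
#' @export
setGeneric("varImportance", function(x) standardGeneric("varImportance"))

#' @rdname accessors
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' Predict generic for dynamIR model fits
#'
#' @param object an [IRModelFit-class].
#' @param ... passed to methods; `newdata` is the feature matrix/data.frame.
#' @return numeric vector of class-1 scores.
#' @export
setGeneric("predictScores", function(object, ...) standardGeneric("predictScores"))

#' @rdname accessors
setMethod("simParams", "SyntheticIRData", function(x) x@params)

#' @rdname accessors
setMethod("intronRanges", "SyntheticIRData", function(x) x@introns)

#' @rdname accessors
setMethod("exonRanges", "SyntheticIRData", function(x) x@exons)

#' @rdname accessors
setMethod("genomeSeq", "SyntheticIRData", function(x) x@genome)

#' @rdname accessors
setMethod("groundTruth", "SyntheticIRData", function(x) x@truth)

#' @rdname accessors
setMethod("coverageTracks", "SyntheticIRData", function(x) x@coverage)

#' @rdname accessors
setMethod("junctionCounts", "SyntheticIRData", function(x) x@junctions)

#' @rdname accessors
setMethod("expressionTable", "SyntheticIRData", function(x) x@expression)

#' @rdname accessors
setMethod("methylomeCalls", "SyntheticIRData", function(x, cell_type) {
  if (missing(cell_type)) x@methylomes else x@methylomes[[cell_type]]
})

#' @rdname accessors
setMethod("chipTracks", "SyntheticIRData", function(x, cell_type) {
  if (missing(cell_type)) x@chip else x@chip[[cell_type]]
})

#' @rdname accessors
setMethod("plantedNFRs", "SyntheticIRData", function(x) x@truth$nfrs)

#' @rdname accessors
setMethod("varImportance", "IRModelFit", function(x) x@importance)

#' @rdname accessors
setMethod("modelKind", "IRModelFit", function(x) x@kind)

#' @rdname accessors
setMethod("profileValues", "ProfileMatrix", function(x) x@matrix)

#' @rdname accessors
setMethod("clusterAssignments", "ProfileMatrix", function(x) x@clusters)

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@n_genes, "genes x",
      object@introns_per_gene, "introns,",
      length(object@cell_types), "cell types\n")
  cat("  retained:", object@fraction_retained,
      " dynamic:", object@fraction_dynamic,
      " NFR coupling:", object@nfr_coupling_prob, "\n")
  cat("  mean coverage:", object@mean_coverage,
      " GCH (NFR/background):", object@gch_meth_nfr, "/",
      object@gch_meth_background, " seed:", object@seed, "\n")
})

setMethod("show", "SyntheticIRData", function(object) {
  st <- object@truth$states
  cat("SyntheticIRData:", length(object@introns), "introns in",
      object@params@n_genes, "genes;",
      length(object@params@cell_types), "cell types\n")
  cat("  contig:", names(object@genome),
      paste0("(", sum(Biostrings::width(object@genome)), " bp)"), "\n")
  cat("  retained states:", sum(st$retained),
      "of", nrow(st), "intron x cell-type pairs;",
      sum(object@truth$introns$dynamic), "dynamic introns\n")
})

setMethod("show", "IRModelFit", function(object) {
  cat("IRModelFit <", object@kind, "> trained on '",
      object@training_label, "'\n", sep = "")
  hp <- object@hyperparameters
  cat("  hyperparameters:",
      paste(names(hp), unlist(lapply(hp, format)), sep = "=", collapse = ", "),
      "\n")
  if (!is.na(object@cv_auc)) cat("  CV ROC AUC:", round(object@cv_auc, 3), "\n")
  top <- head(sort(object@importance, decreasing = TRUE), 5)
  cat("  top features:", paste(names(top), round(top, 3), collapse = ", "), "\n")
})

setMethod("show", "ProfileMatrix", function(object) {
  cat("ProfileMatrix:", nrow(object@matrix), "introns x",
      ncol(object@matrix), "bins (", object@bin_size, "bp ) around ",
      object@anchor, "; state: ", object@state, "\n", sep = "")
  if (length(object@clusters) && !all(is.na(object@clusters))) {
    cat("  clusters:", paste(names(table(object@clusters)),
                             table(object@clusters),
                             sep = ":", collapse = " "), "\n")
  }
})
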