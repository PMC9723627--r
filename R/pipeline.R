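#' Run the IR quantification and chromatin-calling pipeline
#'
#' Quantifies IR for every cell type, calls dynamic introns, calls NFRs (and
#' optionally nucleosomes) from each cell type's GCH methylome and assembles
#' the pooled feature table, together with recovery summaries against the
#' generator's ground truth.
#'
#' @param sim a [SyntheticIRData-class].
#' @param call_nucleosomes also run the nucleosome caller (default FALSE;
#'   the NFR layer is what the feature table consumes here).
#' @return list: `ir_tables` (pooled data.frame), `dynamic_ids`,
#'   `nfr_calls` (per cell type), `features` (pooled feature table),
#'   `concordance` (retention-state recovery among confidently-planted
#'   introns), `dynamic_sensitivity`, `nfr_sensitivity`.
#' @export
runIRPipeline <- function(sim, call_nucleosomes = FALSE) {
  params <- sim@params
  cts <- params@cell_types
  ir_tables <- do.call(rbind, lapply(cts, function(ct) quantifyIR(sim, ct)))
  dynamic_ids <- findDynamicIntrons(ir_tables)

  truth <- sim@truth
  st <- truth$states
  key <- paste(ir_tables$intron_id, ir_tables$sample)
  st_key <- paste(st$intron_id, st$cell_type)
  m <- match(key, st_key)
  true_state <- ifelse(st$retained[m], "retained", "non_retained")
  confident <- st$true_ir[m] <= 0.005 | st$true_ir[m] >= 0.15
  usable <- confident & ir_tables$intron_type != "excluded" &
    !is.na(ir_tables$fpkm) & ir_tables$fpkm >= 1
  concordance <- mean(ir_tables$call[usable] == true_state[usable])

  truth_dyn <- truth$introns$intron_id[truth$introns$dynamic]
  dynamic_sensitivity <- if (length(truth_dyn)) {
    mean(truth_dyn %in% dynamic_ids)
  } else NA_real_

  nfr_calls <- list()
  nuc_calls <- list()
  hits <- 0L; total <- 0L
  for (ct in cts) {
    calls <- callNFRs(sim@methylomes[[ct]])
    nfr_calls[[ct]] <- calls
    if (call_nucleosomes) {
      nuc_calls[[ct]] <- callNucleosomes(sim@methylomes[[ct]])
    }
    ret_ids <- st$intron_id[st$cell_type == ct & st$retained]
    planted <- truth$nfrs[truth$nfrs$intron_id %in% ret_ids &
                            truth$nfrs$level >= params@gch_meth_nfr]
    if (length(planted)) {
      rec <- .nfr_recovery(calls, planted)
      hits <- hits + rec$hits
      total <- total + rec$total
    }
  }
  nfr_sensitivity <- if (total > 0) hits / total else NA_real_

  features <- do.call(rbind, lapply(cts, function(ct) {
    tab <- ir_tables[ir_tables$sample == ct, , drop = FALSE]
    if (!any(tab$call %in% c("retained", "non_retained"))) return(NULL)
    cc <- nfr_calls[[ct]]
    if (call_nucleosomes && nrow(nuc_calls[[ct]])) {
      cc <- rbind(cc, nuc_calls[[ct]])
    }
    assembleFeatures(sim, ct, tab, cc)
  }))

  list(ir_tables = ir_tables, dynamic_ids = dynamic_ids,
       nfr_calls = nfr_calls, nucleosome_calls = nuc_calls,
       features = features, concordance = concordance,
       dynamic_sensitivity = dynamic_sensitivity,
       nfr_sensitivity = nfr_sensitivity)
}

# fraction of planted intervals covered >= min_frac of their width by a call
.nfr_recovery <- function(calls, planted, min_frac = 0.5) {
  if (!nrow(calls)) return(list(hits = 0L, total = length(planted)))
  cgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$start, calls$end))
  ov <- GenomicRanges::findOverlaps(planted, cgr, ignore.strand = TRUE)
  cov <- numeric(length(planted))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(planted[qh], cgr[sh]))
    agg <- tapply(w, qh, max)
    cov[as.integer(names(agg))] <- agg / GenomicRanges::width(
      planted[as.integer(names(agg))])
  }
  list(hits = sum(cov >= min_frac), total = length(planted))
}
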