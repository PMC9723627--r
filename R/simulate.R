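#' Construct simulation parameters
#'
#' Builds a validated [SimulationParams-class] object describing the synthetic
#' study design: five immune-like cell types, a planted logistic coupling of
#' retention to intron length, GC content and splice-site strength, and a
#' planted coupling of retained introns to splice-site-proximal
#' nucleosome-free regions (NFRs) carrying one of five positional GCH
#' accessibility archetypes.
#'
#' @param n_genes number of host genes to simulate.
#' @param introns_per_gene introns per gene.
#' @param cell_types character vector of cell-type labels.
#' @param fraction_retained fraction of introns retained in >= 1 cell type.
#' @param fraction_dynamic fraction of introns that are dynamic (retained in
#'   some cell types, non-retained in others); cannot exceed
#'   `fraction_retained`.
#' @param effect_weights named numeric vector (`length`, `gc`, `ss_strength`)
#'   of logistic coefficients on the standardized intrinsic features; negative
#'   `length` and `ss_strength` with positive `gc` make retained introns
#'   shorter, GC-richer and weaker-spliced.
#' @param nfr_coupling_prob probability a retained intron carries a planted
#'   NFR at its 5' splice site.
#' @param gch_meth_nfr GCH methylation level inside planted NFRs.
#' @param gch_meth_background GCH methylation level elsewhere.
#' @param cpg_bimodal_modes two modes of the bimodal CpG methylation
#'   distribution.
#' @param mean_coverage mean per-base read depth over a gene body.
#' @param nb_dispersion negative-binomial dispersion of per-base depth
#'   (variance = mu + dispersion * mu^2).
#' @param nome_coverage mean NOMe-seq read coverage per GCH site.
#' @param h3k36_depletion H3K36me3 depletion factor over retained introns of
#'   dynamic-chromatin introns (1 = none).
#' @param seed integer random seed.
#' @return a [SimulationParams-class] object.
#' @examples
#' p <- simulationParams(n_genes = 10, introns_per_gene = 3, seed = 1)
#' p
#' @export
simulationParams <- function(n_genes = 120L,
                             introns_per_gene = 3L,
                             cell_types = c("Mo", "Ma", "TN", "CM", "EM"),
                             fraction_retained = 0.35,
                             fraction_dynamic = 0.15,
                             effect_weights = c(length = -1, gc = 1,
                                                ss_strength = -1),
                             nfr_coupling_prob = 0.8,
                             gch_meth_nfr = 0.35,
                             gch_meth_background = 0.08,
                             cpg_bimodal_modes = c(0.05, 0.95),
                             mean_coverage = 80,
                             nb_dispersion = 0.1,
                             nome_coverage = 20,
                             h3k36_depletion = 0.5,
                             seed = 1L) {
  for (nm in c("n_genes", "introns_per_gene", "mean_coverage",
               "nb_dispersion", "nome_coverage", "seed")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("invalid configuration field '%s'", nm), call. = FALSE)
    }
  }
  for (nm in c("fraction_retained", "fraction_dynamic", "nfr_coupling_prob",
               "gch_meth_nfr", "gch_meth_background")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("invalid configuration field '%s'", nm), call. = FALSE)
    }
  }
  new("SimulationParams",
      n_genes = as.integer(n_genes),
      introns_per_gene = as.integer(introns_per_gene),
      cell_types = as.character(cell_types),
      fraction_retained = fraction_retained,
      fraction_dynamic = fraction_dynamic,
      effect_weights = effect_weights,
      nfr_coupling_prob = nfr_coupling_prob,
      gch_meth_nfr = gch_meth_nfr,
      gch_meth_background = gch_meth_background,
      cpg_bimodal_modes = cpg_bimodal_modes,
      mean_coverage = mean_coverage,
      nb_dispersion = nb_dispersion,
      nome_coverage = nome_coverage,
      h3k36_depletion = h3k36_depletion,
      seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(.BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# sample a motif around a consensus: invariant positions always match,
# others match with probability match_p, else a uniform non-consensus base
.consensus_sample <- function(consensus, match_p, invariant = integer(0)) {
  n <- length(consensus)
  out <- consensus
  hit <- runif(n) < match_p
  hit[invariant] <- TRUE
  for (i in which(!hit)) {
    out[i] <- sample(setdiff(.BASES, consensus[i]), 1L)
  }
  out
}

# map a transcript-oriented segment [s, e] (1-based within a gene of length L
# starting at genomic position gstart) to genomic coordinates
.tx2genomic <- function(s, e, gstart, L, strand) {
  if (strand == "+") c(gstart + s - 1L, gstart + e - 1L)
  else c(gstart + L - e, gstart + L - s)
}

.DONOR_EX <- c("C", "A", "G")               # last 3 exonic bases
.DONOR_IN <- c("G", "T", "A", "A", "G", "T") # first 6 intronic bases
.ACC_IN <- c("T", "T", "T", "T", "T", "T", "T", "T", "T", "T",
             "T", "T", "T", "T", "T", "T", "T", "C", "A", "G") # last 20 intronic
.ACC_EX <- c("G", "T", "C")                 # first 3 exonic bases
.BRANCH <- c("T", "A", "C", "T", "A", "A", "C") # branch A at position 6

# GCH archetype step profiles: offsets are transcription-oriented bp relative
# to the 5' splice site (negative = exonic/upstream); level_shift is added to
# gch_meth_nfr (arch 2 is a weak narrow NFR, arch 5 a strong broad one)
.ARCHETYPES <- list(
  `1` = list(from = -120L, to = 120L, shift = 0),
  `2` = list(from = -60L,  to = 60L,  shift = -0.17),
  `3` = list(from = -180L, to = -20L, shift = 0),
  `4` = list(from = 20L,   to = 180L, shift = 0),
  `5` = list(from = -200L, to = 200L, shift = 0.30)
)

#' Simulate annotation, genome sequence and ground truth
#'
#' Lays out `n_genes` multi-exon genes (alternating strands) on one contig,
#' draws intron lengths log-normally and GC content uniformly, plants canonical
#' splice sites whose consensus match degrades with a per-intron strength
#' latent, and assigns each intron a retention state per cell type from a
#' logistic model on the standardized intrinsic features. A subset of introns
#' is dynamic (retained in >= 1 and non-retained in >= 1 cell type). Retained
#' introns carry, with probability `nfr_coupling_prob`, a planted NFR interval
#' at the 5' splice site shaped by one of five positional archetypes. Type B
#' introns are created by planting antisense exons inside introns; type C by
#' adding a host transcript that skips the terminal exon.
#'
#' @param params a [SimulationParams-class].
#' @return list with elements `exons` (GRanges), `introns` (GRanges),
#'   `genome` (DNAStringSet), `genes` (data.frame) and `truth` (list of
#'   `states`, `introns`, `nfrs`).
#' @export
simulateAnnotation <- function(params) {
  validObject(params)
  set.seed(.derive_seed(params@seed, 1L))
  ng <- params@n_genes
  ni <- params@introns_per_gene
  K <- length(params@cell_types)
  N <- ng * ni

  len <- pmin(pmax(round(exp(rnorm(N, log(400), 0.5))), 90L), 3000L)
  gc <- runif(N, 0.35, 0.65)
  ss_z <- rnorm(N)

  w <- params@effect_weights
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  lin <- w[["length"]] * zs(log(len)) + w[["gc"]] * zs(gc) +
    w[["ss_strength"]] * ss_z
  fr <- params@fraction_retained
  if (fr <= 0) {
    retained_any <- rep(FALSE, N)
  } else if (fr >= 1) {
    retained_any <- rep(TRUE, N)
  } else {
    b0 <- uniroot(function(b) mean(plogis(lin + b)) - fr, c(-30, 30))$root
    retained_any <- runif(N) < plogis(lin + b0)
  }

  dynamic <- rep(FALSE, N)
  n_dyn <- round(params@fraction_dynamic * N)
  if (K >= 2L && n_dyn > 0L && any(retained_any)) {
    dyn_ids <- sample(which(retained_any), min(n_dyn, sum(retained_any)))
    dynamic[dyn_ids] <- TRUE
  }

  states <- matrix(FALSE, N, K)
  states[retained_any & !dynamic, ] <- TRUE
  for (i in which(dynamic)) {
    k <- sample.int(K - 1L, 1L)
    states[i, sample.int(K, k)] <- TRUE
  }
  ir_ret <- runif(N, 0.25, 0.65)
  true_ir <- matrix(runif(N * K, 0, 0.005), N, K)
  true_ir[states] <- rep(ir_ret, K)[as.vector(states)]

  coupled <- retained_any & (runif(N) < params@nfr_coupling_prob)
  archetype <- rep(NA_integer_, N)
  archetype[coupled] <- sample.int(5L, sum(coupled), replace = TRUE)

  planted_type <- rep("A", N)
  b_cand <- which(len >= 260L)
  n_b <- min(length(b_cand), max(0L, round(0.06 * N)))
  if (n_b > 0L) planted_type[sample(b_cand, n_b)] <- "B"
  last_idx <- seq(ni, N, by = ni) # last intron of each gene
  c_cand <- setdiff(last_idx, which(planted_type == "B"))
  n_c <- min(length(c_cand), max(0L, round(0.06 * N)))
  if (n_c > 0L && ni >= 1L) planted_type[sample(c_cand, n_c)] <- "C"
  if (ni == 1L) planted_type[planted_type == "C"] <- "A" # single-exon t2 not allowed

  spacer <- 1500L
  seq_parts <- list(.rand_dna(spacer, 0.40))
  offset <- spacer
  exon_rows <- list()
  intron_rows <- list()
  gene_rows <- list()
  nfr_rows <- list()
  as_count <- 0L

  for (g in seq_len(ng)) {
    idx <- ((g - 1L) * ni + 1L):(g * ni)
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%03d", g)
    ew <- sample(120:180, ni + 1L, replace = TRUE)
    iw <- len[idx]
    widths <- integer(2L * ni + 1L)
    widths[seq(1L, 2L * ni + 1L, by = 2L)] <- ew
    widths[seq(2L, 2L * ni, by = 2L)] <- iw
    L <- sum(widths)
    tx_end <- cumsum(widths)
    tx_start <- tx_end - widths + 1L

    segs <- vector("list", length(widths))
    for (s in seq_along(widths)) {
      is_exon <- s %% 2L == 1L
      if (is_exon) {
        segs[[s]] <- .rand_dna(widths[s], 0.52)
      } else {
        j <- idx[s %/% 2L]
        segs[[s]] <- .rand_dna(widths[s], gc[j])
      }
    }
    # plant splice-site and branch-point motifs (transcript orientation)
    for (s in seq(2L, 2L * ni, by = 2L)) {
      j <- idx[s %/% 2L]
      mp <- plogis(1.0 + 0.9 * ss_z[j])
      il <- widths[s]
      segs[[s]][1:6] <- .consensus_sample(.DONOR_IN, mp, invariant = 1:2)
      ex5 <- segs[[s - 1L]]
      ex5[(length(ex5) - 2L):length(ex5)] <- .consensus_sample(.DONOR_EX, mp)
      segs[[s - 1L]] <- ex5
      segs[[s]][(il - 19L):il] <- .consensus_sample(.ACC_IN, mp,
                                                    invariant = 19:20)
      ex3 <- segs[[s + 1L]]
      ex3[1:3] <- .consensus_sample(.ACC_EX, mp)
      segs[[s + 1L]] <- ex3
      bp_d <- sample(25:45, 1L) # branch A this many bp upstream of the 3'ss
      pa <- il - bp_d
      if (pa >= 13L) {
        segs[[s]][(pa - 5L):(pa + 1L)] <- .consensus_sample(.BRANCH, 0.85)
      }
    }
    gene_seq <- unlist(segs, use.names = FALSE)
    gstart <- offset + 1L
    if (strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      gene_seq <- rev(unname(comp[gene_seq]))
    }
    seq_parts[[length(seq_parts) + 1L]] <- gene_seq
    seq_parts[[length(seq_parts) + 1L]] <- .rand_dna(spacer, 0.40)
    offset <- offset + L + spacer

    for (e in seq_len(ni + 1L)) {
      s <- 2L * e - 1L
      gco <- .tx2genomic(tx_start[s], tx_end[s], gstart, L, strand)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        start = gco[1], end = gco[2], strand = strand, gene_id = gid,
        transcript_id = paste0(gid, ".t1"),
        exon_id = sprintf("%s_e%d", gid, e), exon_rank = e)
    }
    # transcript skipping the terminal exon makes that exon alternative
    if (any(planted_type[idx] == "C")) {
      for (e in seq_len(ni)) {
        s <- 2L * e - 1L
        gco <- .tx2genomic(tx_start[s], tx_end[s], gstart, L, strand)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          start = gco[1], end = gco[2], strand = strand, gene_id = gid,
          transcript_id = paste0(gid, ".t2"),
          exon_id = sprintf("%s_e%d", gid, e), exon_rank = e)
      }
    }
    for (ii in seq_len(ni)) {
      s <- 2L * ii
      j <- idx[ii]
      gco <- .tx2genomic(tx_start[s], tx_end[s], gstart, L, strand)
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        start = gco[1], end = gco[2], strand = strand,
        intron_id = sprintf("%s_i%d", gid, ii), gene_id = gid,
        intron_rank = ii,
        flank5_id = sprintf("%s_e%d", gid, ii),
        flank3_id = sprintf("%s_e%d", gid, ii + 1L),
        first_intron = ii == 1L)
      if (planted_type[j] == "B") {
        # antisense single-exon gene inside the intron
        as_count <- as_count + 1L
        mid_tx <- (tx_start[s] + tx_end[s]) %/% 2L
        aco <- .tx2genomic(mid_tx - 44L, mid_tx + 45L, gstart, L, strand)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          start = aco[1], end = aco[2],
          strand = if (strand == "+") "-" else "+",
          gene_id = sprintf("as%03d", as_count),
          transcript_id = sprintf("as%03d.t1", as_count),
          exon_id = sprintf("as%03d_e1", as_count), exon_rank = 1L)
      }
      if (coupled[j]) {
        arch <- .ARCHETYPES[[archetype[j]]]
        ss5 <- if (strand == "+") gco[1] else gco[2]
        if (strand == "+") {
          nstart <- ss5 + arch$from; nend <- ss5 + arch$to
        } else {
          nstart <- ss5 - arch$to; nend <- ss5 - arch$from
        }
        nfr_rows[[length(nfr_rows) + 1L]] <- data.frame(
          start = nstart, end = nend,
          intron_id = sprintf("%s_i%d", gid, ii),
          archetype = archetype[j],
          level = min(0.95, max(0.01, params@gch_meth_nfr + arch$shift)))
      }
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = gid, strand = strand, start = gstart,
      end = gstart + L - 1L,
      tss = if (strand == "+") gstart else gstart + L - 1L)
  }

  chrom_seq <- paste(unlist(seq_parts, use.names = FALSE), collapse = "")
  genome <- Biostrings::DNAStringSet(chrom_seq)
  names(genome) <- "chrS"

  exdf <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(exdf$start, exdf$end), strand = exdf$strand)
  S4Vectors::mcols(exons) <- exdf[, c("gene_id", "transcript_id", "exon_id",
                                      "exon_rank")]
  indf <- do.call(rbind, intron_rows)
  introns <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(indf$start, indf$end), strand = indf$strand)
  S4Vectors::mcols(introns) <- indf[, c("intron_id", "gene_id", "intron_rank",
                                        "flank5_id", "flank3_id",
                                        "first_intron")]
  introns$intron_type <- classifyIntronType(introns, exons)

  if (length(nfr_rows)) {
    ndf <- do.call(rbind, nfr_rows)
    nfrs <- GenomicRanges::GRanges("chrS", IRanges::IRanges(ndf$start, ndf$end))
    S4Vectors::mcols(nfrs) <- ndf[, c("intron_id", "archetype", "level")]
  } else {
    nfrs <- GenomicRanges::GRanges()
  }

  states_df <- data.frame(
    intron_id = rep(indf$intron_id, K),
    cell_type = rep(params@cell_types, each = N),
    retained = as.vector(states),
    true_ir = as.vector(true_ir))
  truth_introns <- data.frame(
    intron_id = indf$intron_id, gene_id = indf$gene_id,
    length = len, gc_target = gc, ss_z = ss_z,
    retained_any = retained_any, dynamic = dynamic,
    nfr_coupled = coupled, archetype = archetype,
    planted_type = planted_type,
    first_intron = indf$first_intron)

  list(exons = exons, introns = introns, genome = genome,
       genes = do.call(rbind, gene_rows),
       truth = list(states = states_df, introns = truth_introns, nfrs = nfrs))
}

#' Simulate coverage, junction counts and expression
#'
#' Per-base read depth over exons is negative-binomial with mean equal to the
#' gene depth (held at `mean_coverage`); intronic depth has mean
#' `true_IRratio * gene depth`; junction counts are Poisson with mean
#' `(1 - true_IRratio) * gene depth`, so the recomputed IRratio is centred on
#' the planted one. Antisense exon regions planted inside type B introns get
#' independent antisense coverage (excluded later by the annotation mask).
#'
#' @param annot result of [simulateAnnotation()].
#' @param params the matching [SimulationParams-class].
#' @return list with `coverage` (named list of `RleList` per cell type),
#'   `junctions` (data.frame: chrom, start, end, strand, count, sample) and
#'   `expression` (data.frame: gene_id, sample, fpkm).
#' @export
simulateTranscriptome <- function(annot, params) {
  set.seed(.derive_seed(params@seed, 2L))
  cts <- params@cell_types
  K <- length(cts)
  D <- params@mean_coverage
  size <- 1 / params@nb_dispersion
  chrom_len <- Biostrings::width(annot$genome)[1]
  genes <- annot$genes
  introns <- annot$introns
  exons <- annot$exons
  st <- annot$truth$states

  # expression: bimodal-free FPKM classes; a lineage-shifted subset gives
  # up/down strata between myeloid (first two) and lymphoid cell types
  ng <- nrow(genes)
  expr_class <- sample(c("low", "medium", "high"), ng, replace = TRUE,
                       prob = c(0.35, 0.40, 0.25))
  base_fpkm <- ifelse(expr_class == "low", runif(ng, 2, 25),
                      ifelse(expr_class == "medium", runif(ng, 25, 75),
                             runif(ng, 75, 300)))
  shifted <- runif(ng) < 0.12
  shift_dir <- sample(c(-3, 3), ng, replace = TRUE)
  expr_rows <- list()
  for (k in seq_len(K)) {
    f <- base_fpkm * 2^rnorm(ng, 0, 0.2)
    if (K >= 3L && k <= 2L) f[shifted] <- f[shifted] * 2^shift_dir[shifted]
    expr_rows[[k]] <- data.frame(gene_id = genes$gene_id, sample = cts[k],
                                 fpkm = pmax(f, 1.01))
  }
  expression <- do.call(rbind, expr_rows)

  anti <- exons[grepl("^as", exons$gene_id)]
  if (length(anti)) {
    expression <- rbind(expression, data.frame(
      gene_id = rep(unique(anti$gene_id), each = K),
      sample = rep(cts, length(unique(anti$gene_id))),
      fpkm = runif(length(unique(anti$gene_id)) * K, 1.5, 5)))
  }

  ir_map <- split(setNames(st$true_ir, st$intron_id), st$cell_type)
  host_exons <- exons[!grepl("^as", exons$gene_id) &
                        exons$transcript_id %in%
                          paste0(unique(exons$gene_id), ".t1")]

  coverage <- list()
  junc_rows <- list()
  for (k in seq_len(K)) {
    vec <- numeric(chrom_len)
    for (e in seq_along(host_exons)) {
      s <- GenomicRanges::start(host_exons)[e]
      en <- GenomicRanges::end(host_exons)[e]
      vec[s:en] <- rnbinom(en - s + 1L, mu = D, size = size)
    }
    irs <- ir_map[[cts[k]]][introns$intron_id]
    for (i in seq_along(introns)) {
      s <- GenomicRanges::start(introns)[i]
      en <- GenomicRanges::end(introns)[i]
      mu <- irs[i] * D
      vec[s:en] <- if (mu > 0) rnbinom(en - s + 1L, mu = mu, size = size)
                   else 0
    }
    if (length(anti)) {
      for (a in seq_along(anti)) {
        s <- GenomicRanges::start(anti)[a]
        en <- GenomicRanges::end(anti)[a]
        vec[s:en] <- vec[s:en] + rnbinom(en - s + 1L, mu = 1.5 * D, size = size)
      }
    }
    coverage[[cts[k]]] <- IRanges::RleList(chrS = S4Vectors::Rle(vec))
    junc_rows[[k]] <- data.frame(
      chrom = "chrS",
      start = GenomicRanges::start(introns),
      end = GenomicRanges::end(introns),
      strand = as.character(GenomicRanges::strand(introns)),
      count = rpois(length(introns), pmax(0, (1 - irs)) * D),
      sample = cts[k])
  }
  list(coverage = coverage, junctions = do.call(rbind, junc_rows),
       expression = expression,
       gene_classes = data.frame(gene_id = genes$gene_id,
                                 expr_class = expr_class,
                                 shifted = shifted))
}

#' Simulate CpG and GCH methylomes
#'
#' GCH sites (GC followed by A/C/T, both strands pooled by position later) are
#' located in the simulated sequence; methylated counts are binomial at
#' `gch_meth_background` except inside planted NFR intervals of introns that
#' are retained in the given cell type, where the archetype level applies.
#' CpG sites get a per-site bimodal methylation mode; sites inside active NFRs
#' are forced to the low mode (accessible regions are hypomethylated).
#'
#' @inheritParams simulateTranscriptome
#' @return named list (cell type) of cytosine-report data.frames with columns
#'   chrom, pos (1-based), strand, count_methylated, count_unmethylated,
#'   context (`"CpG"`/`"GCH"`).
#' @export
simulateMethylomes <- function(annot, params) {
  set.seed(.derive_seed(params@seed, 3L))
  s <- strsplit(as.character(annot$genome[[1]]), "", fixed = TRUE)[[1]]
  n <- length(s)
  # GCH: plus-strand C at i+1 where s[i]=G, s[i+1]=C, s[i+2]!=G;
  #      minus-strand C (genomic G) at j where s[j]=G, s[j+1]=C, s[j-1]!=C
  i <- seq_len(n - 2L)
  gch_plus <- i[s[i] == "G" & s[i + 1L] == "C" & s[i + 2L] != "G"] + 1L
  j <- 2L:(n - 1L)
  gch_minus <- j[s[j] == "G" & s[j + 1L] == "C" & s[j - 1L] != "C"]
  cpg_plus <- i[s[i] == "C" & s[i + 1L] == "G"]
  cpg_minus <- cpg_plus + 1L

  gch_pos <- c(gch_plus, gch_minus)
  gch_strand <- rep(c("+", "-"), c(length(gch_plus), length(gch_minus)))
  ord <- order(gch_pos)
  gch_pos <- gch_pos[ord]; gch_strand <- gch_strand[ord]

  cpg_pos <- c(cpg_plus, cpg_minus)
  cpg_strand <- rep(c("+", "-"), c(length(cpg_plus), length(cpg_minus)))
  ord <- order(cpg_pos)
  cpg_pos <- cpg_pos[ord]; cpg_strand <- cpg_strand[ord]
  cpg_mode <- sample(params@cpg_bimodal_modes, length(cpg_pos),
                     replace = TRUE)

  nfrs <- annot$truth$nfrs
  st <- annot$truth$states
  out <- list()
  for (ct in params@cell_types) {
    ret_ids <- st$intron_id[st$cell_type == ct & st$retained]
    act <- nfrs[nfrs$intron_id %in% ret_ids]
    gch_level <- rep(params@gch_meth_background, length(gch_pos))
    cpg_level <- cpg_mode
    if (length(act)) {
      gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(gch_pos, gch_pos))
      hits <- GenomicRanges::findOverlaps(gr, act, select = "first")
      inside <- !is.na(hits)
      gch_level[inside] <- act$level[hits[inside]]
      grc <- GenomicRanges::GRanges("chrS", IRanges::IRanges(cpg_pos, cpg_pos))
      hc <- GenomicRanges::findOverlaps(grc, act, select = "first")
      cpg_level[!is.na(hc)] <- min(params@cpg_bimodal_modes)
    }
    gcov <- rpois(length(gch_pos), params@nome_coverage)
    keep <- gcov > 0L
    gmeth <- rbinom(sum(keep), gcov[keep], gch_level[keep])
    gch_df <- data.frame(chrom = "chrS", pos = gch_pos[keep],
                         strand = gch_strand[keep],
                         count_methylated = gmeth,
                         count_unmethylated = gcov[keep] - gmeth,
                         context = "GCH")
    ccov <- rpois(length(cpg_pos), 15)
    keep <- ccov > 0L
    cmeth <- rbinom(sum(keep), ccov[keep],
                    pmin(0.98, pmax(0.02, cpg_level[keep])))
    cpg_df <- data.frame(chrom = "chrS", pos = cpg_pos[keep],
                         strand = cpg_strand[keep],
                         count_methylated = cmeth,
                         count_unmethylated = ccov[keep] - cmeth,
                         context = "CpG")
    out[[ct]] <- rbind(cpg_df, gch_df)
  }
  out
}

#' Simulate histone-mark pileup tracks and peak calls
#'
#' H3K36me3 covers gene bodies at a constant base level, multiplied by the
#' depletion factor over retained introns of dynamic-chromatin (dynamic)
#' introns; H3K4me3 and H3K27ac mark promoters, H3K4me1 marks an upstream
#' enhancer, and H3K9me3/H3K27me3 mark random gene subsets, all independent of
#' IR. Peaks are emitted in narrowPeak form consistent with the pileup.
#'
#' @inheritParams simulateTranscriptome
#' @return named list (cell type) of per-mark lists with elements `pileup`
#'   (GRanges of 25-bp bins with `score`) and `peaks` (GRanges with narrowPeak
#'   metadata columns).
#' @export
simulateChip <- function(annot, params) {
  set.seed(.derive_seed(params@seed, 4L))
  genes <- annot$genes
  introns <- annot$introns
  st <- annot$truth$states
  dyn <- annot$truth$introns$intron_id[annot$truth$introns$dynamic]
  bw <- 25L
  ng <- nrow(genes)
  k9 <- runif(ng) < 0.15
  k27 <- runif(ng) < 0.15

  # per-gene regions per mark, built once; scores drawn per cell type
  region_for <- function(m, g) {
    switch(m,
      H3K36me3 = c(genes$start[g], genes$end[g]),
      H3K4me3 = c(max(1L, genes$tss[g] - 250L), genes$tss[g] + 250L),
      H3K27ac = c(max(1L, genes$tss[g] - 250L), genes$tss[g] + 250L),
      H3K4me1 = c(max(1L, genes$start[g] - 900L),
                  max(1L, genes$start[g] - 900L) + 300L),
      H3K9me3 = if (k9[g]) c(genes$start[g], genes$end[g]) else NULL,
      H3K27me3 = if (k27[g]) c(genes$start[g], genes$end[g]) else NULL)
  }
  lvl_for <- c(H3K36me3 = 10, H3K4me3 = 14, H3K27ac = 9, H3K4me1 = 8,
               H3K9me3 = 6, H3K27me3 = 6)
  marks_all <- names(lvl_for)
  layout <- list()
  for (m in marks_all) {
    bs <- integer(0); gene_of <- integer(0)
    for (g in seq_len(ng)) {
      r <- region_for(m, g)
      if (is.null(r)) next
      b <- seq(r[1], r[2], by = bw)
      bs <- c(bs, b)
      gene_of <- c(gene_of, rep(g, length(b)))
    }
    layout[[m]] <- list(start = bs, gene = gene_of)
  }

  out <- list()
  for (ct in params@cell_types) {
    ret_ids <- st$intron_id[st$cell_type == ct & st$retained]
    depl_introns <- introns[introns$intron_id %in% intersect(ret_ids, dyn)]
    marks <- list()
    for (m in marks_all) {
      lay <- layout[[m]]
      nb <- length(lay$start)
      if (!nb) {
        marks[[m]] <- list(pileup = GenomicRanges::GRanges(),
                           peaks = GenomicRanges::GRanges())
        next
      }
      sc <- rgamma(nb, shape = 8, rate = 8 / lvl_for[[m]])
      gr <- GenomicRanges::GRanges("chrS",
              IRanges::IRanges(lay$start, lay$start + bw - 1L), score = sc)
      if (m == "H3K36me3" && length(depl_introns) &&
          params@h3k36_depletion != 1) {
        hit <- IRanges::overlapsAny(gr, depl_introns)
        gr$score[hit] <- rgamma(sum(hit), shape = 8,
                                rate = 8 / (10 * params@h3k36_depletion))
      }
      # one peak per covered gene: interval spans its bins, summit = max bin
      pk <- do.call(rbind, lapply(split(seq_len(nb), lay$gene), function(ii) {
        j <- ii[which.max(gr$score[ii])]
        data.frame(start = min(lay$start[ii]),
                   end = max(lay$start[ii]) + bw - 1L,
                   gene = lay$gene[ii[1]],
                   sig = gr$score[j],
                   summit = lay$start[j] + bw %/% 2L - min(lay$start[ii]))
      }))
      peaks <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(pk$start, pk$end),
        name = sprintf("%s_%s_%s", ct, m, genes$gene_id[pk$gene]),
        score = round(10 * pk$sig), signalValue = pk$sig,
        pValue = runif(nrow(pk), 5, 20), qValue = runif(nrow(pk), 3, 15),
        peak = pk$summit)
      marks[[m]] <- list(pileup = gr, peaks = peaks)
    }
    out[[ct]] <- marks
  }
  out
}

#' Generate a complete linked synthetic multi-omics data set
#'
#' Runs [simulateAnnotation()], [simulateTranscriptome()],
#' [simulateMethylomes()] and [simulateChip()] with seeds derived from
#' `params@seed` and assembles the result into a [SyntheticIRData-class].
#' Identical parameters give identical output.
#'
#' @param params a [SimulationParams-class] (default [simulationParams()]).
#' @return a [SyntheticIRData-class].
#' @examples
#' sim <- simulateIRData(simulationParams(n_genes = 6, seed = 7))
#' sim
#' @export
simulateIRData <- function(params = simulationParams()) {
  annot <- simulateAnnotation(params)
  tx <- simulateTranscriptome(annot, params)
  meth <- simulateMethylomes(annot, params)
  chip <- simulateChip(annot, params)
  truth <- annot$truth
  truth$introns$expr_class <-
    tx$gene_classes$expr_class[match(truth$introns$gene_id,
                                     tx$gene_classes$gene_id)]
  new("SyntheticIRData",
      params = params,
      exons = annot$exons,
      introns = annot$introns,
      genome = annot$genome,
      truth = truth,
      coverage = tx$coverage,
      junctions = tx$junctions,
      expression = tx$expression,
      methylomes = meth,
      chip = chip)
}
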