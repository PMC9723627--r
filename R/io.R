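#' Write a synthetic data set to standard file formats
#'
#' Emits GTF (1-based inclusive) annotation, FASTA genome, per-cell-type
#' bedGraph coverage (0-based half-open), junction/expression TSVs,
#' Bismark-style cytosine reports and per-mark narrowPeak + pileup bedGraph
#' files. Identical input objects give byte-identical files.
#'
#' @param sim a [SyntheticIRData-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSyntheticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  gtf <- file.path(dir, "annotation.gtf")
  writeAnnotationGTF(sim@exons, gtf)
  paths["gtf"] <- gtf
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim@genome, fa)
  paths["fasta"] <- fa
  for (ct in names(sim@coverage)) {
    p <- file.path(dir, sprintf("coverage_%s.bedGraph", ct))
    gr <- GenomicRanges::GRanges(sim@coverage[[ct]])
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, p, format = "bedGraph")
    paths[paste0("coverage_", ct)] <- p
  }
  jp <- file.path(dir, "junctions.tsv")
  write.table(sim@junctions, jp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["junctions"] <- jp
  ep <- file.path(dir, "expression.tsv")
  write.table(sim@expression, ep, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["expression"] <- ep
  for (ct in names(sim@methylomes)) {
    p <- file.path(dir, sprintf("methylome_%s.cytosine.txt", ct))
    m <- sim@methylomes[[ct]]
    write.table(data.frame(m$chrom, m$pos, m$strand, m$count_methylated,
                           m$count_unmethylated, m$context, m$context),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths[paste0("methylome_", ct)] <- p
  }
  for (ct in names(sim@chip)) {
    for (mk in names(sim@chip[[ct]])) {
      marks <- sim@chip[[ct]][[mk]]
      pb <- file.path(dir, sprintf("chip_%s_%s.pileup.bedGraph", ct, mk))
      rtracklayer::export(marks$pileup, pb, format = "bedGraph")
      pn <- file.path(dir, sprintf("chip_%s_%s.narrowPeak", ct, mk))
      writeNarrowPeak(marks$peaks, pn)
      paths[paste0("chip_", ct, "_", mk)] <- c(pb)
    }
  }
  invisible(paths)
}

#' Write exon annotation as GTF
#'
#' Gene, transcript and exon rows, 1-based inclusive coordinates, with
#' `gene_id` / `transcript_id` / `exon_number` attributes.
#'
#' @param exons annotation `GRanges` (metadata `gene_id`, `transcript_id`,
#'   `exon_rank`).
#' @param path output path.
#' @export
writeAnnotationGTF <- function(exons, path) {
  md <- S4Vectors::mcols(exons)
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                      md$gene_id, md$transcript_id, md$exon_rank)
  lines <- sprintf("%s\tdynamIR\texon\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(exons)),
                   GenomicRanges::start(exons), GenomicRanges::end(exons),
                   as.character(GenomicRanges::strand(exons)), attr_str)
  writeLines(lines, path)
}

#' Read exon annotation from GTF
#'
#' @param path GTF file (1-based inclusive).
#' @return exon `GRanges` with `gene_id`, `transcript_id`, `exon_rank`.
#' @export
readAnnotationGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  rank <- if (!is.null(gr$exon_number)) as.integer(gr$exon_number)
          else NA_integer_
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    exon_id = paste0(gr$gene_id, "_e", rank), exon_rank = rank)
  out
}

#' Derive introns from exon annotation
#'
#' Introns are the gaps between consecutive exons of each transcript, with
#' transcription-ordered flanking-exon ids and ranks.
#'
#' @param exons exon `GRanges` (from [readAnnotationGTF()]).
#' @return intron `GRanges` with `intron_id`, `gene_id`, `intron_rank`,
#'   `flank5_id`, `flank3_id`, `first_intron` (deduplicated across
#'   transcripts sharing an intron).
#' @export
extractIntrons <- function(exons) {
  md <- S4Vectors::mcols(exons)
  rows <- list()
  for (tx in unique(md$transcript_id)) {
    ex <- exons[md$transcript_id == tx]
    if (length(ex) < 2L) next
    o <- order(GenomicRanges::start(ex))
    ex <- ex[o]
    minus <- as.character(GenomicRanges::strand(ex))[1] == "-"
    n <- length(ex)
    for (i in seq_len(n - 1L)) {
      # transcription rank of the intron between genomic exons i and i+1
      rank <- if (minus) n - i else i
      f5 <- if (minus) ex$exon_id[i + 1L] else ex$exon_id[i]
      f3 <- if (minus) ex$exon_id[i] else ex$exon_id[i + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(ex))[1],
        start = GenomicRanges::end(ex)[i] + 1L,
        end = GenomicRanges::start(ex)[i + 1L] - 1L,
        strand = as.character(GenomicRanges::strand(ex))[1],
        gene_id = ex$gene_id[1], intron_rank = rank,
        flank5_id = f5, flank3_id = f3)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[, c("chrom", "start", "end", "strand")]), ,
           drop = FALSE]
  df <- df[order(df$gene_id, df$intron_rank), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    intron_id = sprintf("%s_i%d", df$gene_id, df$intron_rank),
    gene_id = df$gene_id, intron_rank = df$intron_rank,
    flank5_id = df$flank5_id, flank3_id = df$flank3_id,
    first_intron = df$intron_rank == 1L)
  gr
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @return an `RleList` of per-base coverage.
#' @export
readCoverageBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

#' Read a Bismark-style cytosine report
#'
#' Columns: chrom, 1-based position, strand, methylated count, unmethylated
#' count, context, trinucleotide.
#'
#' @param path report path.
#' @return data.frame with the package's cytosine-call columns.
#' @export
readCytosineReport <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- df[, 1:6]
  names(out) <- c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context")
  out
}

#' Read a junction-count table
#'
#' @param path TSV with header chrom, start, end, strand, count, sample
#'   (start/end = first/last intronic base, 1-based).
#' @return data.frame.
#' @export
readJunctionTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a gene-expression table
#'
#' @param path TSV with header gene_id, sample, fpkm.
#' @return data.frame.
#' @export
readExpressionTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write narrowPeak (BED6+4) peak calls
#'
#' @param peaks `GRanges` with `name`, `score`, `signalValue`, `pValue`,
#'   `qValue`, `peak` metadata.
#' @param path output path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,  # BED 0-based half-open
    end = GenomicRanges::end(peaks),
    name = peaks$name, score = peaks$score,
    strand = ".",
    signalValue = peaks$signalValue, pValue = peaks$pValue,
    qValue = peaks$qValue, peak = peaks$peak)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read narrowPeak (BED6+4) peak calls
#'
#' @param path narrowPeak file.
#' @return `GRanges` with narrowPeak metadata (1-based inclusive).
#' @export
readNarrowPeak <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand",
                 "signalValue", "pValue", "qValue", "peak")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         name = df$name, score = df$score,
                         signalValue = df$signalValue, pValue = df$pValue,
                         qValue = df$qValue, peak = df$peak)
}
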