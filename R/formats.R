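#' Read a proteome FASTA file
#'
#' Parses a protein FASTA file into a named [Biostrings::AAStringSet].
#' The header token before the first whitespace becomes the protein id;
#' wrapped sequence lines are concatenated. Sequences are restricted to
#' the 20 standard amino acids plus X.
#'
#' @param path Path to a FASTA file.
#' @param genomeId Optional genome identifier attached to every record
#'   (stored in `mcols(x)$genome_id`).
#' @return A named `AAStringSet`; `mcols()` carries `genome_id`.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 desc", "ACDE", ">p2", "WW", "W"), tf)
#' prot <- readProteome(tf, genomeId = "g1")
#' width(prot)  # 4 3
#' @export
readProteome <- function(path, genomeId = NA_character_) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty FASTA file: %s", path)
  headers <- grepl("^>", lines)
  if (!headers[1]) stopf("not a FASTA file (first line is not a header): %s", path)
  idx <- cumsum(headers)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[headers]))
  seqs <- vapply(split(lines[!headers], idx[!headers]),
                 function(x) paste(toupper(x), collapse = ""), character(1))
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stopf("FASTA record with empty sequence in %s", path)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1], path)
  for (i in seq_along(seqs)) {
    bad <- firstIllegalChar(seqs[i])
    if (bad > 0)
      stopf("illegal character '%s' at position %d of record '%s'",
            substr(seqs[i], bad, bad), bad, ids[i])
  }
  out <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(out)$genome_id <- genomeId
  out
}

#' Write proteins to a FASTA file
#'
#' @param proteins A named `AAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
writeProteome <- function(proteins, path, width = 60) {
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(proteins, path, width = width)
  invisible(path)
}

#' Read a gene-feature table
#'
#' Reads a tab-separated table with header columns `genome_id`, `gene_id`,
#' `contig`, `start`, `end`, `strand` (1-based inclusive nucleotide
#' coordinates) into a [GenomicRanges::GRanges], sorted by
#' (genome, contig, start). Gene ids share a namespace with protein ids so
#' proteomes and feature tables join by id.
#'
#' @param path Path to the TSV file.
#' @return A `GRanges` with metadata columns `gene_id` and `genome_id`,
#'   sorted by (genome_id, seqnames, start).
#' @export
readGeneFeatures <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genome_id", "gene_id", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature table missing columns: %s", paste(miss, collapse = ", "))
  asGeneFeatures(df)
}

#' Build a sorted gene-feature GRanges from a data frame
#'
#' @param df Data frame with columns `genome_id`, `gene_id`, `contig`,
#'   `start`, `end`, `strand`.
#' @return A sorted `GRanges`; see [readGeneFeatures()].
#' @export
asGeneFeatures <- function(df) {
  if (any(df$start > df$end))
    stopf("feature with start > end: %s", df$gene_id[df$start > df$end][1])
  if (!all(df$strand %in% c("+", "-")))
    stopf("unknown strand symbol '%s' for gene %s",
          df$strand[!(df$strand %in% c("+", "-"))][1],
          df$gene_id[!(df$strand %in% c("+", "-"))][1])
  ord <- order(df$genome_id, df$contig, df$start)
  df <- df[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$genome_id <- df$genome_id
  gr
}

#' Read a barcode count table
#'
#' Tab-separated table with columns `barcode`, `gene_id` (empty or NA for
#' intergenic insertions), `pos_fraction` (insertion position as a fraction
#' of gene length), then one non-negative integer count column per sample.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the columns above.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stopf("count table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("barcode", "gene_id", "pos_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("count table missing columns: %s", paste(miss, collapse = ", "))
  countCols <- setdiff(names(df), need)
  if (!length(countCols)) stopf("count table has no sample columns")
  for (cc in countCols) {
    if (any(df[[cc]] < 0, na.rm = TRUE)) stopf("negative counts in column %s", cc)
  }
  if (anyDuplicated(df$barcode))
    stopf("duplicate barcode '%s'", df$barcode[duplicated(df$barcode)][1])
  df
}

#' Write a barcode count table
#'
#' @param df Count table as returned by [readCountTable()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCountTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
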