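#' Families tracked in a genome repertoire
#'
#' @return Character vector of tracked family names.
#' @export
repertoireFamilies <- function() {
  c("MesA", "MesB", "MesC", "MesD", "MesX", "MetE", "MetH",
    "SplitMetE", "MetF", "AcsB", "AcsC", "AcsD")
}

#' Synthase families counted for sole-synthase analysis
#'
#' MesD is treated as a synthase only together with MesX by default
#' (`mesdRequiresMesX`), since the two form an obligate unit.
#'
#' @return Character vector.
#' @export
synthaseFamilies <- function() {
  c("MesA", "MesB", "MesC", "MesD", "MetE", "MetH", "SplitMetE")
}

#' Build the per-genome family repertoire matrix
#'
#' One row per genome, one count column per tracked family. Calls flagged
#' `non_enzymatic` are excluded from the counts; a split MetE system is
#' counted once per genome when present.
#'
#' @param calls Data.frame from [classifyProteins()] (columns `genome_id`,
#'   `family`, `non_enzymatic`).
#' @param splitCalls Optional data.frame from [detectSplitMetE()] rows
#'   (columns `genome_id`, `present`).
#' @param genomes Character vector of all genome ids (so genomes without
#'   calls get all-zero rows).
#' @return A data.frame with `genome_id` plus one integer column per
#'   family in [repertoireFamilies()].
#' @export
buildRepertoire <- function(calls, splitCalls = NULL, genomes = NULL) {
  fams <- repertoireFamilies()
  if (is.null(genomes))
    genomes <- sort(unique(c(calls$genome_id,
                             if (!is.null(splitCalls)) splitCalls$genome_id)))
  if (anyDuplicated(genomes)) stopf("duplicate genome ids in genome list")
  mat <- matrix(0L, length(genomes), length(fams),
                dimnames = list(genomes, fams))
  if (nrow(calls)) {
    use <- !is.na(calls$family) & !calls$non_enzymatic &
      calls$family %in% fams
    if (any(use)) {
      tab <- table(calls$genome_id[use], calls$family[use])
      mat[rownames(tab), colnames(tab)] <-
        mat[rownames(tab), colnames(tab)] + as.matrix(tab)
    }
  }
  if (!is.null(splitCalls) && nrow(splitCalls)) {
    if (anyDuplicated(splitCalls$genome_id))
      stopf("duplicate genome rows in split MetE calls")
    pres <- splitCalls$genome_id[splitCalls$present]
    pres <- intersect(pres, genomes)
    mat[pres, "SplitMetE"] <- 1L
  }
  out <- data.frame(genome_id = genomes, mat, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Co-occurrence of a family with a condition
#'
#' Among genomes containing `family`, the fraction also satisfying the
#' condition over `conditionFamilies` (`mode = "all"`: every condition
#' family present; `"any"`: at least one). Exact counts are reported
#' alongside the fraction; an empty denominator is flagged undefined
#' rather than raising an error.
#'
#' @param repertoire Data.frame from [buildRepertoire()].
#' @param family Family whose genomes form the denominator.
#' @param conditionFamilies Families forming the condition.
#' @param mode `"all"` or `"any"`.
#' @return A list with `numerator`, `denominator`, `fraction` (NA when
#'   undefined) and `undefined`.
#' @export
cooccurrence <- function(repertoire, family, conditionFamilies,
                         mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (!nrow(repertoire)) stopf("empty repertoire matrix")
  has <- repertoire[[family]] > 0
  condMat <- sapply(conditionFamilies,
                    function(f) repertoire[[f]] > 0)
  condMat <- matrix(condMat, nrow = nrow(repertoire))
  cond <- if (mode == "all") rowSums(condMat) == length(conditionFamilies)
          else rowSums(condMat) > 0
  den <- sum(has)
  num <- sum(has & cond)
  list(numerator = num, denominator = den,
       fraction = if (den > 0) num / den else NA_real_,
       undefined = den == 0)
}

#' Genomes with exactly one (or no) methionine synthase
#'
#' Counts the synthase families present per genome and returns, for each
#' genome, whether it has a sole synthase and which. Genomes with no
#' synthase at all are listed with `sole = "none"` — the observation that
#' motivates searching such genomes for novel synthase families. MesD
#' counts as a synthase only when MesX is also present (configurable).
#'
#' @param repertoire Data.frame from [buildRepertoire()].
#' @param mesdRequiresMesX Treat MesD as a synthase only with MesX?
#' @return A data.frame `genome_id`, `n_synthases`, `sole` (family name,
#'   "none", or NA when several are present).
#' @export
soleSynthase <- function(repertoire, mesdRequiresMesX = TRUE) {
  fams <- synthaseFamilies()
  presence <- sapply(fams, function(f) repertoire[[f]] > 0)
  presence <- matrix(presence, nrow = nrow(repertoire),
                     dimnames = list(NULL, fams))
  if (mesdRequiresMesX)
    presence[, "MesD"] <- presence[, "MesD"] & repertoire[["MesX"]] > 0
  n <- rowSums(presence)
  sole <- rep(NA_character_, nrow(repertoire))
  sole[n == 0] <- "none"
  one <- which(n == 1)
  if (length(one))
    sole[one] <- fams[apply(presence[one, , drop = FALSE], 1, which)]
  data.frame(genome_id = repertoire$genome_id, n_synthases = n,
             sole = sole, stringsAsFactors = FALSE)
}

#' Find operon-like adjacent gene pairs
#'
#' Reports a pair when a gene from `setA` and a gene from `setB` are
#' consecutive on the same contig, on the same strand (if required), with
#' an intergenic distance of at most `maxIntergenicBp`. "Adjacent" as
#' consecutive same-strand genes with a small gap is the standard operon
#' heuristic. Pairs are symmetric in (a, b).
#'
#' @param features A sorted `GRanges` from [readGeneFeatures()].
#' @param setA,setB Character vectors of gene ids.
#' @param maxIntergenicBp Maximum intergenic gap in bp (default 300).
#' @param requireSameStrand Require both genes on the same strand?
#' @return A data.frame: `genome_id`, `gene_a`, `gene_b`, `gap_bp`,
#'   `strand_a`, `strand_b`.
#' @export
findOperonPairs <- function(features, setA, setB, maxIntergenicBp = 300,
                            requireSameStrand = TRUE) {
  ids <- S4Vectors::mcols(features)$gene_id
  unknown <- setdiff(c(setA, setB), ids)
  if (length(unknown))
    stopf("unknown gene ids: %s", paste(unknown, collapse = ", "))
  genomeIds <- S4Vectors::mcols(features)$genome_id
  contigs <- as.character(GenomicRanges::seqnames(features))
  strands <- as.character(GenomicRanges::strand(features))
  starts <- GenomicRanges::start(features)
  ends <- GenomicRanges::end(features)
  key <- paste(genomeIds, contigs)
  ord <- order(key, starts)
  out <- list()
  for (grp in split(ord, key[ord])) {
    if (length(grp) < 2) next
    for (k in seq_len(length(grp) - 1)) {
      i <- grp[k]; j <- grp[k + 1]
      a <- ids[i]; b <- ids[j]
      inAB <- (a %in% setA && b %in% setB) || (a %in% setB && b %in% setA)
      if (!inAB) next
      if (requireSameStrand && strands[i] != strands[j]) next
      gap <- starts[j] - ends[i] - 1L
      if (gap > maxIntergenicBp) next
      out[[length(out) + 1]] <- data.frame(
        genome_id = genomeIds[i], gene_a = a, gene_b = b,
        gap_bp = gap, strand_a = strands[i], strand_b = strands[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(genome_id = character(0), gene_a = character(0),
                      gene_b = character(0), gap_bp = integer(0),
                      strand_a = character(0), strand_b = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
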