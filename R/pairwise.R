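#' Default BLOSUM62 scoring scheme
#'
#' BLOSUM62 with gap open 11 / extend 1 and the standard gapped-BLASTp
#' Karlin-Altschul constants (lambda = 0.267, K = 0.041), so that bit
#' scores are comparable with the thresholds used for family assignment.
#' A gap of length L costs `11 + L`. X scores 0 against all residues.
#'
#' All family thresholds in this package are configuration, not constants:
#' the bit scale of a Smith-Waterman search differs slightly from that of
#' profile searches, so [calibrateThreshold()] can rescale thresholds
#' against packaged true/decoy sets.
#'
#' @param gapOpen,gapExtend Affine gap penalties (positive, matrix units).
#' @param lambda,K Karlin-Altschul constants.
#' @return A [ScoringScheme-class] object.
#' @examples
#' sch <- blosum62Scheme()
#' sch@matrix["A", "A"]  # 4
#' @export
blosum62Scheme <- function(gapOpen = 11, gapExtend = 1,
                           lambda = 0.267, K = 0.041) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  m <- cbind(m, X = 0)
  m <- rbind(m, X = 0)
  scoringScheme("BLOSUM62", m, gapOpen, gapExtend, lambda, K)
}

#' Construct a scoring scheme
#'
#' @param name Matrix name.
#' @param matrix Symmetric substitution matrix covering the 20 standard
#'   residues plus X.
#' @param gapOpen,gapExtend Positive affine gap penalties.
#' @param lambda,K Karlin-Altschul constants for bit conversion.
#' @return A [ScoringScheme-class] object.
#' @export
scoringScheme <- function(name, matrix, gapOpen, gapExtend, lambda, K) {
  new("ScoringScheme", name = name, matrix = matrix,
      gapOpen = gapOpen, gapExtend = gapExtend, lambda = lambda, K = K)
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path Path to an NCBI-style matrix file (comment lines start
#'   with `#`; first non-comment row lists the column residues).
#' @return A numeric matrix restricted to the 20 standard residues plus X
#'   (X rescored to 0 against everything).
#' @export
readScoringMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, "", 1), cols))
  for (i in seq_along(rows)) m[i, ] <- as.numeric(rows[[i]][-1])
  keep <- intersect(AA_ALPHABET21, rownames(m))
  m <- m[keep, keep]
  if ("X" %in% rownames(m)) { m["X", ] <- 0; m[, "X"] <- 0 }
  m
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw Raw score in matrix units.
#' @param scheme A [ScoringScheme-class].
#' @return Bit score(s).
#' @examples
#' toBits(24, blosum62Scheme())  # ~13.85
#' @export
toBits <- function(raw, scheme) {
  (scheme@lambda * raw - log(scheme@K)) / log(2)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps under the given scoring
#' scheme. When no residue pair scores positively, an empty zero-score
#' alignment is returned.
#'
#' @param query,subject Sequences: character strings, `AAString`s, or
#'   named length-1 `AAStringSet`s.
#' @param scheme A [ScoringScheme-class]; default [blosum62Scheme()].
#' @param queryId,subjectId Identifiers (defaults taken from names).
#' @return A [LocalAlignment-class] object.
#' @examples
#' aln <- alignLocal("ACDE", "ACDE")
#' rawScore(aln)  # 24
#' @export
alignLocal <- function(query, subject, scheme = blosum62Scheme(),
                       queryId = "query", subjectId = "subject") {
  qs <- asSingleSequence(query, queryId)
  ss <- asSingleSequence(subject, subjectId)
  if (!nchar(qs$seq) || !nchar(ss$seq)) stopf("empty sequence in alignLocal")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qs$seq), Biostrings::AAString(ss$seq),
    type = "local", substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
  raw <- Biostrings::score(pa)
  alignedQ <- as.character(Biostrings::alignedPattern(pa))
  alignedS <- as.character(Biostrings::alignedSubject(pa))
  if (raw <= 0 || !nchar(alignedQ)) {
    return(new("LocalAlignment", queryId = qs$id, subjectId = ss$id,
               rawScore = 0, bits = toBits(0, scheme),
               identities = 0L, alignedColumns = 0L,
               queryStart = 0L, queryEnd = 0L, subjectStart = 0L,
               subjectEnd = 0L,
               columnMap = matrix(integer(0), 0, 2,
                                  dimnames = list(NULL, c("query", "subject")))))
  }
  qc <- strsplit(alignedQ, "")[[1]]
  sc <- strsplit(alignedS, "")[[1]]
  qStart <- Biostrings::start(Biostrings::pattern(pa))
  sStart <- Biostrings::start(Biostrings::subject(pa))
  qpos <- ifelse(qc == "-", NA_integer_, qStart - 1L + cumsum(qc != "-"))
  spos <- ifelse(sc == "-", NA_integer_, sStart - 1L + cumsum(sc != "-"))
  cm <- cbind(query = as.integer(qpos), subject = as.integer(spos))
  new("LocalAlignment", queryId = qs$id, subjectId = ss$id,
      rawScore = raw, bits = toBits(raw, scheme),
      identities = sum(qc == sc & qc != "-"),
      alignedColumns = length(qc),
      queryStart = as.integer(qStart),
      queryEnd = as.integer(Biostrings::end(Biostrings::pattern(pa))),
      subjectStart = as.integer(sStart),
      subjectEnd = as.integer(Biostrings::end(Biostrings::subject(pa))),
      columnMap = cm)
}

asSingleSequence <- function(x, fallbackId) {
  if (is(x, "AAStringSet")) {
    if (length(x) != 1) stopf("expected a single sequence")
    list(seq = as.character(x[[1]]),
         id = if (!is.null(names(x))) names(x)[1] else fallbackId)
  } else if (is(x, "AAString")) {
    list(seq = as.character(x), id = fallbackId)
  } else {
    nm <- names(x)
    list(seq = as.character(x)[1],
         id = if (!is.null(nm) && nzchar(nm[1])) nm[1] else fallbackId)
  }
}

#' Percent identity of a local alignment
#'
#' Identities over aligned columns including gap columns (the BLAST
#' `pident` convention); reported values are rounded to the nearest
#' integer percent, the unrounded value is available with
#' `rounded = FALSE`.
#'
#' @param aln A [LocalAlignment-class].
#' @param rounded Round to the nearest integer percent?
#' @return Percent identity in \[0, 100\].
#' @export
percentIdentity <- function(aln, rounded = TRUE) {
  if (aln@alignedColumns == 0) stopf("empty alignment has no percent identity")
  p <- 100 * aln@identities / aln@alignedColumns
  if (rounded) round(p) else p
}

#' Global (full-length) percent identity of two sequences
#'
#' Needleman-Wunsch global alignment identity over all columns including
#' gaps. Local-alignment identity measures the best-matching region and
#' therefore overstates the relatedness of full-length proteins; family
#' separation statements ("under 30% pairwise identity") use the global
#' convention.
#'
#' @param a,b Sequences (see [alignLocal()]).
#' @param scheme A [ScoringScheme-class].
#' @return Percent identity in \[0, 100\] (unrounded).
#' @export
globalPercentIdentity <- function(a, b, scheme = blosum62Scheme()) {
  as <- asSingleSequence(a, "a"); bs <- asSingleSequence(b, "b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as$seq), Biostrings::AAString(bs$seq),
    type = "global", substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
  Biostrings::pid(pa, type = "PID1")
}

#' Query coverage of a local alignment
#'
#' Fraction of the query spanned by the aligned region.
#'
#' @param aln A [LocalAlignment-class].
#' @param queryLength Length of the query sequence in residues.
#' @return Coverage in \[0, 1\].
#' @export
queryCoverage <- function(aln, queryLength) {
  if (aln@alignedColumns == 0) return(0)
  (aln@queryEnd - aln@queryStart + 1) / queryLength
}

#' Score one query against many proteins
#'
#' Fast score-only Smith-Waterman of a single query against a proteome,
#' returning raw and bit scores per protein. Full alignments (identity,
#' coverage, column map) can be computed afterwards with [alignLocal()]
#' for the proteins of interest.
#'
#' @param query A single sequence (see [alignLocal()]).
#' @param proteins A named `AAStringSet`.
#' @param scheme A [ScoringScheme-class].
#' @return A data.frame with columns `protein_id`, `raw`, `bits`.
#' @export
searchProteome <- function(query, proteins, scheme = blosum62Scheme()) {
  qs <- asSingleSequence(query, "query")
  S4Vectors::mcols(proteins) <- NULL  # the aligner warns on (and drops) mcols
  raw <- Biostrings::pairwiseAlignment(
    proteins, Biostrings::AAString(qs$seq),
    type = "local", substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend,
    scoreOnly = TRUE)
  raw <- pmax(raw, 0)
  data.frame(protein_id = names(proteins), raw = raw,
             bits = toBits(raw, scheme), stringsAsFactors = FALSE)
}
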