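#' Scoring scheme for local protein alignment
#'
#' Bundles a substitution matrix with affine gap penalties and the
#' Karlin-Altschul constants used to convert raw alignment scores to bits.
#' A gap of length L costs `gapOpen + L * gapExtend` matrix units.
#'
#' @slot name Name of the substitution matrix (e.g. "BLOSUM62").
#' @slot matrix Symmetric integer substitution matrix over the 20 standard
#'   residues plus X; X scores 0 against everything.
#' @slot gapOpen Positive gap-opening penalty (matrix units).
#' @slot gapExtend Positive per-residue gap-extension penalty.
#' @slot lambda Karlin-Altschul scale (nats per raw-score unit), > 0.
#' @slot K Karlin-Altschul constant, in (0, 1).
#' @export
setClass("ScoringScheme",
  representation(name = "character", matrix = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", K = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@matrix
  if (!isTRUE(all.equal(m, t(m)))) return("substitution matrix must be symmetric")
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    return("gap penalties must be positive")
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@K <= 0 || object@K >= 1) return("K must be in (0, 1)")
  TRUE
})

#' Result of a pairwise local alignment
#'
#' Holds the optimal Smith-Waterman score under affine gaps, its bit-score
#' conversion, identity counts and the residue-level column map between the
#' two sequences. Coordinates are 1-based; an empty (zero-score) alignment
#' has `alignedColumns == 0`.
#'
#' @slot queryId,subjectId Sequence identifiers.
#' @slot rawScore Optimal local score in matrix units (>= 0).
#' @slot bits Bit score, `(lambda * raw - ln K) / ln 2`.
#' @slot identities Number of identical aligned residue pairs.
#' @slot alignedColumns Alignment length including gap columns.
#' @slot queryStart,queryEnd,subjectStart,subjectEnd Aligned spans.
#' @slot columnMap Integer matrix with columns `query`, `subject`; NA marks
#'   a gap in that sequence.
#' @export
setClass("LocalAlignment",
  representation(queryId = "character", subjectId = "character",
                 rawScore = "numeric", bits = "numeric",
                 identities = "integer", alignedColumns = "integer",
                 queryStart = "integer", queryEnd = "integer",
                 subjectStart = "integer", subjectEnd = "integer",
                 columnMap = "matrix"))

setValidity("LocalAlignment", function(object) {
  if (object@identities > object@alignedColumns)
    return("identities cannot exceed aligned columns")
  cm <- object@columnMap
  if (nrow(cm) > 0) {
    for (col in 1:2) {
      v <- cm[, col][!is.na(cm[, col])]
      if (length(v) > 1 && any(diff(v) <= 0))
        return("column map positions must be strictly increasing")
    }
  }
  TRUE
})

#' Position-specific scoring model for a protein domain
#'
#' A gap-free position-specific score matrix (in bits) built from a family
#' alignment, with a trusted bit-score cutoff recorded at build time from
#' the training members.
#'
#' @slot name Model name.
#' @slot scores Numeric matrix, one row per model column, one column per
#'   residue (the 20 standard amino acids plus X).
#' @slot cutoff Trusted bit-score cutoff.
#' @export
setClass("ProfileModel",
  representation(name = "character", scores = "matrix", cutoff = "numeric"))

setValidity("ProfileModel", function(object) {
  if (nrow(object@scores) < 1) return("profile must have at least one column")
  if (!is.finite(object@cutoff)) return("cutoff must be finite")
  TRUE
})

#' Functional-residue positions on a reference protein
#'
#' Records the zinc-coordinating and substrate-binding positions of a
#' reference methionine synthase (E. coli MetE numbering by convention:
#' zinc H641/C643/E665/C726, substrate S433/E484/D599).
#'
#' @slot referenceId Identifier of the reference protein.
#' @slot zincPos Four strictly increasing zinc-site positions.
#' @slot substratePos Three strictly increasing substrate-site positions.
#' @slot zincRes,substrateRes Expected residues at those positions.
#' @export
setClass("ReferenceSites",
  representation(referenceId = "character", zincPos = "integer",
                 substratePos = "integer", zincRes = "character",
                 substrateRes = "character"))

setValidity("ReferenceSites", function(object) {
  if (any(diff(object@zincPos) <= 0) || any(diff(object@substratePos) <= 0))
    return("site positions must be strictly increasing")
  if (length(object@zincPos) != length(object@zincRes) ||
      length(object@substratePos) != length(object@substrateRes))
    return("positions and residues must have equal length")
  TRUE
})

#' Family reference used for homology-based classification
#'
#' A family is called when a protein scores at or above `threshold` bits
#' against the family's query sequence. Optionally a maximum protein length
#' is enforced, and a site policy demotes calls whose zinc site is broken
#' to non-enzymatic homologs.
#'
#' @slot family Family name (e.g. "MesA").
#' @slot query Named [Biostrings::AAStringSet] of length 1.
#' @slot threshold Positive bit-score threshold.
#' @slot maxLength Maximum candidate length in residues (NA = none).
#' @slot enforceSites Whether a broken zinc verdict demotes the call.
#' @slot zincPositions Zinc-site positions on the query (length 4), or
#'   empty when the family has no zinc site.
#' @export
setClass("FamilyReference",
  representation(family = "character", query = "AAStringSet",
                 threshold = "numeric", maxLength = "numeric",
                 enforceSites = "logical", zincPositions = "integer"))

setValidity("FamilyReference", function(object) {
  if (object@threshold <= 0) return("threshold must be positive")
  if (length(object@query) != 1) return("query must contain one sequence")
  if (length(object@zincPositions) %in% c(0L, 4L) == FALSE)
    return("zincPositions must have length 0 or 4")
  TRUE
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: %s, gap open %g / extend %g, lambda %.3f, K %.3f\n",
              object@name, object@gapOpen, object@gapExtend,
              object@lambda, object@K))
})

setMethod("show", "LocalAlignment", function(object) {
  cat(sprintf(
    "LocalAlignment %s vs %s: raw %g (%.1f bits), %d/%d identities, q %d-%d, s %d-%d\n",
    object@queryId, object@subjectId, object@rawScore, object@bits,
    object@identities, object@alignedColumns,
    object@queryStart, object@queryEnd, object@subjectStart, object@subjectEnd))
})

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel %s: %d columns, trusted cutoff %.2f bits\n",
              object@name, nrow(object@scores), object@cutoff))
})

setMethod("show", "FamilyReference", function(object) {
  cat(sprintf("FamilyReference %s: query %s (%d aa), threshold %g bits%s%s\n",
              object@family, names(object@query)[1],
              Biostrings::width(object@query)[1], object@threshold,
              if (is.na(object@maxLength)) "" else sprintf(", max length %g", object@maxLength),
              if (object@enforceSites) ", site policy on" else ""))
})

setMethod("show", "ReferenceSites", function(object) {
  cat(sprintf("ReferenceSites on %s: zinc %s (%s); substrate %s (%s)\n",
              object@referenceId,
              paste(object@zincPos, collapse = ","),
              paste(object@zincRes, collapse = ""),
              paste(object@substratePos, collapse = ","),
              paste(object@substrateRes, collapse = "")))
})

#' @rdname ScoringScheme-class
#' @param x A `ScoringScheme`.
#' @export
gapOpen <- function(x) x@gapOpen

#' @rdname ScoringScheme-class
#' @export
gapExtend <- function(x) x@gapExtend

#' @rdname LocalAlignment-class
#' @param x A `LocalAlignment`.
#' @export
rawScore <- function(x) x@rawScore

#' @rdname LocalAlignment-class
#' @export
bitScore <- function(x) x@bits

#' @rdname LocalAlignment-class
#' @export
columnMap <- function(x) x@columnMap

#' @rdname ProfileModel-class
#' @param x A `ProfileModel`.
#' @export
trustedCutoff <- function(x) x@cutoff

#' @rdname FamilyReference-class
#' @param x A `FamilyReference`.
#' @export
familyName <- function(x) x@family

#' @rdname FamilyReference-class
#' @export
familyThreshold <- function(x) x@threshold
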