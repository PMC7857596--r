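#' Progressive multiple sequence alignment
#'
#' A deliberately simple progressive aligner: a guide tree is built by
#' UPGMA on k-mer (k = 3) distances, then profiles are aligned
#' profile-to-profile up the tree with the pairwise scoring scheme's
#' substitution matrix and affine gap penalties. This is not MUSCLE:
#' there is no iterative refinement. The result is deterministic and
#' independent of input order because sequences are ordered
#' lexicographically by id before the guide tree is computed.
#'
#' @param seqs A named `AAStringSet` (or named character vector) of at
#'   least 2 sequences.
#' @param scheme A [ScoringScheme-class] supplying the substitution matrix
#'   and gap penalties.
#' @param k k-mer size for guide-tree distances.
#' @return A named equal-width `AAStringSet` in the input's id order;
#'   removing gaps from any row reproduces its input sequence.
#' @examples
#' aln <- progressiveAlign(c(a = "ACDE", b = "ACE"))
#' as.character(aln)
#' @export
progressiveAlign <- function(seqs, scheme = blosum62Scheme(), k = 3) {
  if (is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (length(seqs) < 2) stopf("progressive alignment needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("sequences must have unique names")
  inputOrder <- names(seqs)
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)

  if (n == 2) {
    aln <- mergeAlignments(msaToMatrix(seqs[1]), msaToMatrix(seqs[2]), scheme)
  } else {
    d <- kmerDistance(seqs, k)
    hc <- hclust(as.dist(d), method = "average")
    nodes <- vector("list", n - 1)
    leafAln <- function(i) {
      m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1)
      rownames(m) <- names(seqs)[i]
      m
    }
    for (step in seq_len(n - 1)) {
      pick <- function(x) if (x < 0) leafAln(-x) else nodes[[x]]
      nodes[[step]] <- mergeAlignments(pick(hc$merge[step, 1]),
                                       pick(hc$merge[step, 2]), scheme)
    }
    aln <- nodes[[n - 1]]
  }
  rows <- apply(aln, 1, paste, collapse = "")
  out <- Biostrings::AAStringSet(rows[inputOrder])
  out
}

# k-mer distance: 1 - shared k-mers / min(k-mer count), the usual quick
# guide-tree distance. Sequences shorter than k fall back to length 1 mers.
kmerDistance <- function(seqs, k = 3) {
  kmers <- lapply(seqs, function(s) {
    kk <- min(k, nchar(s))
    unique(substring(s, seq_len(nchar(s) - kk + 1),
                     seq_len(nchar(s) - kk + 1) + kk - 1))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(kmers[[i]], kmers[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(kmers[[i]]), length(kmers[[j]]))
  }
  d
}

# Align two sub-alignments (character matrices) profile-to-profile and
# return the merged character matrix.
mergeAlignments <- function(A, B, scheme) {
  FA <- profileFreq(A)
  FB <- profileFreq(B)
  M <- scheme@matrix[AA_ALPHABET21, AA_ALPHABET21]
  S <- t(FA) %*% M %*% FB
  path <- cpp_profile_nw(S, scheme@gapOpen, scheme@gapExtend)
  ncols <- length(path$a)
  out <- matrix("-", nrow(A) + nrow(B), ncols,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- path$a > 0
  ib <- path$b > 0
  out[seq_len(nrow(A)), which(ia)] <- A[, path$a[ia], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), which(ib)] <- B[, path$b[ib], drop = FALSE]
  out
}

# Column frequency profile over the 21-letter alphabet; gaps contribute
# nothing (columns with gaps get reduced total mass).
profileFreq <- function(A) {
  F <- matrix(0, length(AA_ALPHABET21), ncol(A),
              dimnames = list(AA_ALPHABET21, NULL))
  for (j in seq_len(ncol(A))) {
    col <- A[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tab <- table(factor(col, levels = AA_ALPHABET21))
      F[, j] <- as.numeric(tab) / nrow(A)
    }
  }
  F
}

#' Trim an alignment to confident blocks
#'
#' Keeps columns whose gap fraction is at most `maxGapFraction`, then
#' keeps only maximal runs of kept columns of length at least `minBlock`
#' (a simplified block trimmer honoring exactly those two parameters).
#' Column provenance is recorded: the returned object carries the original
#' column indices in `metadata(x)$kept_columns` and a per-column report in
#' `metadata(x)$trim_report`.
#'
#' @param msa A named equal-width `AAStringSet` (or character vector).
#' @param maxGapFraction Maximum tolerated per-column gap fraction.
#' @param minBlock Minimum run length of kept columns.
#' @return A trimmed `AAStringSet` with trim metadata.
#' @export
trimBlocks <- function(msa, maxGapFraction = 0.5, minBlock = 2) {
  m <- msaToMatrix(msa)
  gapFrac <- colMeans(m == "-")
  passGap <- gapFrac <= maxGapFraction
  keep <- passGap
  r <- rle(passGap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] < minBlock)
      keep[starts[i]:ends[i]] <- FALSE
  }
  if (!any(keep))
    stopf("no alignment columns survive trimming; input may be unalignable")
  reason <- ifelse(keep, "kept",
                   ifelse(!passGap, "gap_fraction", "short_block"))
  out <- Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1,
                                       paste, collapse = ""))
  S4Vectors::metadata(out)$kept_columns <- which(keep)
  S4Vectors::metadata(out)$trim_report <-
    data.frame(column = seq_along(keep), kept = keep, reason = reason,
               gap_fraction = gapFrac)
  out
}

#' Remove gaps from an aligned row
#'
#' @param x A character string with `-` gap characters.
#' @return The ungapped sequence.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
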