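#' Pairwise distance matrix from a trimmed alignment
#'
#' For each pair of rows, `p` is the mismatch fraction over mutually
#' ungapped columns; the Kimura-style protein correction
#' `d = -ln(1 - p - p^2/5)` is applied. `p` is capped just below the
#' correction's singularity (p ~ 0.8541) and capped pairs are flagged in
#' `attr(x, "capped")`.
#'
#' @param msa Named equal-width `AAStringSet` or character vector
#'   (>= 3 rows).
#' @param correction `"kimura"` or `"none"` (raw p-distance).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(msa, correction = c("kimura", "none")) {
  correction <- match.arg(correction)
  m <- msaToMatrix(msa)
  if (nrow(m) < 3) stopf("distance matrix needs at least 3 rows")
  if (ncol(m) < 1) stopf("alignment has no columns")
  n <- nrow(m)
  ids <- rownames(m)
  pCap <- 0.85
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  capped <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stopf("no comparable (mutually ungapped) columns between %s and %s",
            ids[i], ids[j])
    p <- mean(m[i, ok] != m[j, ok])
    if (correction == "kimura") {
      if (p > pCap) { p <- pCap; capped[i, j] <- capped[j, i] <- TRUE }
      d <- -log(1 - p - p^2 / 5)
    } else d <- p
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "capped") <- capped
  D
}

#' Neighbor-joining tree with Newick output
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix. Negative
#' branch lengths are clamped to zero with the deficit moved to the
#' adjacent branch (the usual NJ post-processing), so path lengths
#' between leaves are preserved. On additive matrices the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param dist Symmetric numeric matrix with row/col names (>= 3 taxa).
#' @return A Newick string terminated by `;`. The underlying `phylo`
#'   object is attached as `attr(x, "tree")`.
#' @export
neighborJoining <- function(dist) {
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stopf("distance matrix must be symmetric")
  if (nrow(dist) < 3) stopf("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(as.dist(dist))
  tree <- clampNegativeBranches(tree)
  nwk <- ape::write.tree(tree)
  attr(nwk, "tree") <- tree
  nwk
}

# Move negative branch lengths onto the adjacent branch: the edge is set
# to zero and its (negative) length added to the sibling edge sharing the
# same parent node, preserving leaf-to-leaf path sums along that split.
clampNegativeBranches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs))
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    else break  # root edge with no sibling: just clamp
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Leaf-to-leaf path lengths on a tree
#'
#' @param newick A Newick string (or result of [neighborJoining()]).
#' @return Symmetric matrix of patristic distances between leaves.
#' @export
treePathLengths <- function(newick) {
  tree <- attr(newick, "tree")
  if (is.null(tree)) tree <- ape::read.tree(text = as.character(newick))
  ape::cophenetic.phylo(tree)
}

#' Write a PHYLIP-like square distance matrix
#'
#' @param dist Symmetric matrix with names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeDistanceMatrix <- function(dist, path) {
  df <- data.frame(taxon = rownames(dist), as.data.frame(dist),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
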