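# Independent oracles and shared fixtures for the test suite.
# The alignment oracles here are written independently of the package's
# alignment backend so they can serve as a second route to the same
# quantities.

# Plain-R Smith-Waterman affine-gap DP, score only. Gap of length L costs
# open + L * ext. Alignments start and end in match columns.
swOracleScore <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  M <- matrix(-Inf, la + 1, lb + 1)
  X <- matrix(-Inf, la + 1, lb + 1)   # gap in b (consumes a)
  Y <- matrix(-Inf, la + 1, lb + 1)   # gap in a (consumes b)
  best <- 0
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- s + max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                     X[i, j - 1] - open - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# True exhaustive enumeration of local alignments for tiny sequences:
# every alignment is a series of match columns separated by single gap
# runs (adjacent opposing gap runs are never optimal under these
# penalties). Exponential; use only for lengths <= 4.
swEnumScore <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0
  recurse <- function(i, j, sc) {
    best <<- max(best, sc)
    if (i < la && j < lb)
      recurse(i + 1, j + 1, sc + mat[av[i + 1], bv[j + 1]])
    if (j < lb && i + 1 < la) for (g in seq_len(la - i - 1))
      recurse(i + g + 1, j + 1,
              sc - open - g * ext + mat[av[i + g + 1], bv[j + 1]])
    if (i < la && j + 1 < lb) for (g in seq_len(lb - j - 1))
      recurse(i + 1, j + g + 1,
              sc - open - g * ext + mat[av[i + 1], bv[j + g + 1]])
  }
  for (i in seq_len(la)) for (j in seq_len(lb))
    recurse(i, j, mat[av[i], bv[j]])
  best
}

randomSeq <- function(n) {
  paste(sample(MesFinder:::AA20, n, replace = TRUE), collapse = "")
}

# Memoized expensive fixtures shared across test files.
.fixtures <- new.env()
fixtureSeeds <- function() {
  if (is.null(.fixtures$seeds)) .fixtures$seeds <- familySeeds()
  .fixtures$seeds
}
fixtureRefs <- function() {
  if (is.null(.fixtures$refs))
    .fixtures$refs <- makeFamilyReferences(fixtureSeeds(), seed = 99)
  .fixtures$refs
}
fixtureProfiles <- function() {
  if (is.null(.fixtures$profiles))
    .fixtures$profiles <- buildDomainProfiles(fixtureSeeds(), seed = 7)
  .fixtures$profiles
}
fixtureScheme <- function() {
  if (is.null(.fixtures$scheme)) .fixtures$scheme <- blosum62Scheme()
  .fixtures$scheme
}
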