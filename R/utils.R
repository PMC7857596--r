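#' @importFrom methods new is validObject slot
#' @importFrom stats median hclust as.dist rpois runif setNames weighted.mean
#' @importFrom utils read.delim write.table packageVersion
NULL

# The 20 standard amino acids, in Biostrings' BLOSUM row order plus X.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")
AA_ALPHABET21 <- c(AA20, "X")

# Approximate background amino-acid frequencies (Robinson & Robinson style),
# used by the profile module and the synthetic generator.
AA_BACKGROUND <- c(
  A = 0.0787, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0168,
  Q = 0.0397, E = 0.0632, G = 0.0726, H = 0.0220, I = 0.0580,
  L = 0.0943, K = 0.0580, M = 0.0226, F = 0.0397, P = 0.0484,
  S = 0.0687, T = 0.0564, V = 0.0661, W = 0.0109, Y = 0.0299
)

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global random-number state so seeded generator
#' calls do not perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  force(seed)  # draws in the caller's stream must happen before the save
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Validate that a sequence uses only the 20 standard residues plus X.
# Returns the 1-based position of the first illegal character, or 0L.
firstIllegalChar <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET21))
  if (length(bad)) bad[1] else 0L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Write a TSV report with a provenance footer (version + config hash).
writeReport <- function(df, path, configHash = NULL) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  footer <- sprintf("# MesFinder %s%s",
                    as.character(packageVersion("MesFinder")),
                    if (is.null(configHash)) "" else paste0(" config:", configHash))
  cat(footer, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
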