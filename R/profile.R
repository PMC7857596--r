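#' Build a position-specific scoring model from a family alignment
#'
#' Per-column scores are log-odds in bits:
#' `log2(((count_r + pseudocount * background_r) / (n_eff + pseudocount)) / background_r)`
#' where `n_eff` is the number of non-gap residues in the column. Columns
#' with more than 50% gaps are dropped. With pseudocount 0, zero counts
#' are floored rather than scored minus infinity.
#'
#' The trusted cutoff is set at build time to the minimum [scoreProfile()]
#' score of the training sequences themselves (the original rows, gaps
#' removed), emulating a curated model's trusted cutoff.
#'
#' @param msa A named equal-width `AAStringSet` (>= 2 rows), or character
#'   vector of aligned rows with `-` gaps.
#' @param pseudocount Pseudocount mass (default 1) spread over residues in
#'   proportion to background frequencies.
#' @param name Model name.
#' @param background Named background frequencies over the 20 residues.
#' @param maxGapFraction Columns with a gap fraction above this are dropped.
#' @param floor Score floor replacing minus infinity (bits).
#' @return A [ProfileModel-class].
#' @export
buildProfile <- function(msa, pseudocount = 1, name = "profile",
                         background = AA_BACKGROUND,
                         maxGapFraction = 0.5, floor = -10) {
  m <- msaToMatrix(msa)
  if (nrow(m) < 2) stopf("a profile needs at least 2 aligned sequences")
  gapFrac <- colMeans(m == "-")
  keep <- which(gapFrac <= maxGapFraction)
  if (!length(keep)) stopf("all columns exceed the gap fraction limit")
  bg <- background[AA20] / sum(background[AA20])
  scores <- matrix(floor, length(keep), length(AA_ALPHABET21),
                   dimnames = list(NULL, AA_ALPHABET21))
  for (j in seq_along(keep)) {
    col <- m[, keep[j]]
    col <- col[col != "-"]
    col[col == "X"] <- NA  # X carries no residue information
    counts <- table(factor(col[!is.na(col)], levels = AA20))
    nEff <- sum(counts)
    p <- (as.numeric(counts) + pseudocount * bg) / (nEff + pseudocount)
    s <- log2(p / bg)
    s[!is.finite(s)] <- floor
    scores[j, AA20] <- pmax(s, floor)
    scores[j, "X"] <- 0
  }
  model <- new("ProfileModel", name = name, scores = scores, cutoff = 0)
  training <- vapply(seq_len(nrow(m)),
                     function(i) paste(m[i, ][m[i, ] != "-"], collapse = ""),
                     character(1))
  model@cutoff <- min(vapply(training, function(s) scoreProfile(model, s),
                             numeric(1)))
  model
}

#' Score a sequence against a profile model
#'
#' Returns the best ungapped local window score in bits: the maximal-sum
#' contiguous run of column scores over all alignments of the profile
#' against the sequence without gaps. Deterministic; flanking residues
#' outside the best window never change the score.
#'
#' @param model A [ProfileModel-class].
#' @param seq A sequence (character, `AAString`, or length-1 set).
#' @return Best window score in bits (0 if no positive window).
#' @export
scoreProfile <- function(model, seq) {
  s <- asSingleSequence(seq, "seq")$seq
  if (!nchar(s)) stopf("empty sequence")
  chars <- strsplit(s, "")[[1]]
  chars[!(chars %in% AA_ALPHABET21)] <- "X"
  L <- length(chars)
  P <- nrow(model@scores)
  # per-position score of residue i against profile column j, scanned by
  # diagonal (offset of sequence relative to profile) with Kadane's rule
  best <- 0
  resIdx <- match(chars, colnames(model@scores))
  for (off in (-(P - 1)):(L - 1)) {
    j <- seq_len(P)
    i <- j + off
    ok <- i >= 1 & i <= L
    if (!any(ok)) next
    v <- model@scores[cbind(j[ok], resIdx[i[ok]])]
    run <- 0
    for (x in v) {
      run <- max(0, run + x)
      if (run > best) best <- run
    }
  }
  best
}

#' Write a profile model to TSV
#'
#' One row per model column, one column per residue, with the model name
#' and trusted cutoff recorded in a header comment.
#'
#' @param model A [ProfileModel-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfile <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# profile\t%s\tcutoff\t%.6g\n", model@name, model@cutoff),
      file = con)
  df <- as.data.frame(model@scores)
  df <- cbind(column = seq_len(nrow(df)), df)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile model from TSV
#'
#' @param path Path written by [writeProfile()].
#' @return A [ProfileModel-class].
#' @export
readProfile <- function(path) {
  header <- readLines(path, n = 1)
  parts <- strsplit(sub("^# ", "", header), "\t")[[1]]
  df <- read.delim(path, comment.char = "#")
  scores <- as.matrix(df[, setdiff(names(df), "column")])
  colnames(scores) <- sub("^X$", "X", colnames(scores))
  new("ProfileModel", name = parts[2], scores = scores,
      cutoff = as.numeric(parts[4]))
}

# Convert an aligned set (AAStringSet / character vector) to a character
# matrix, rows = sequences, cols = alignment columns.
msaToMatrix <- function(msa) {
  if (is(msa, "AAStringSet")) msa <- as.character(msa)
  if (is.matrix(msa)) return(msa)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1) stopf("aligned rows must have equal width")
  m <- do.call(rbind, strsplit(msa, ""))
  rownames(m) <- names(msa)
  m
}
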