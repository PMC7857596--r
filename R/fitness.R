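#' Strain fitness from barcode counts
#'
#' The (un-normalized) fitness of a strain is the log2 ratio of its
#' relative abundance after growth versus before:
#' `log2(((after + pc) / depth_after) / ((before + pc) / depth_before))`.
#' The pseudocount (default 1) keeps zero counts finite.
#'
#' @param countBefore,countAfter Non-negative counts (vectorized).
#' @param depthBefore,depthAfter Positive total sample depths.
#' @param pseudocount Pseudocount added to both counts.
#' @return Strain fitness in log2 units.
#' @examples
#' strainFitness(100, 400, 1e5, 1e5)  # ~1.99
#' @export
strainFitness <- function(countBefore, countAfter, depthBefore, depthAfter,
                          pseudocount = 1) {
  if (any(countBefore < 0) || any(countAfter < 0))
    stopf("counts must be non-negative")
  if (depthBefore <= 0 || depthAfter <= 0) stopf("depths must be positive")
  log2(((countAfter + pseudocount) / depthAfter) /
       ((countBefore + pseudocount) / depthBefore))
}

#' Gene fitness as a weighted average of strain fitness
#'
#' Strains qualify when their insertion lies in the central part of the
#' gene (position fraction within `window`, default 10-90%). The gene
#' fitness is the weighted mean of qualifying strain fitness values with
#' weight `1 / (1/(1 + count_before) + 1/(1 + count_after))` — the
#' inverse of the approximate variance of a log ratio of counts, so
#' well-sampled strains dominate.
#'
#' @param strainFit Strain fitness values.
#' @param countBefore,countAfter Counts per strain.
#' @param posFraction Insertion position as a fraction of gene length.
#' @param window Central insertion window, `c(low, high)`.
#' @return A list: `fitness` (NA when no strain qualifies), `n_strains`,
#'   `measurable`, `total_before`, `total_after`.
#' @export
geneFitness <- function(strainFit, countBefore, countAfter, posFraction,
                        window = c(0.1, 0.9)) {
  ok <- posFraction >= window[1] & posFraction <= window[2]
  if (!any(ok)) {
    return(list(fitness = NA_real_, n_strains = 0L, measurable = FALSE,
                total_before = sum(countBefore), total_after = sum(countAfter)))
  }
  w <- 1 / (1 / (1 + countBefore[ok]) + 1 / (1 + countAfter[ok]))
  list(fitness = sum(strainFit[ok] * w) / sum(w),
       n_strains = sum(ok), measurable = TRUE,
       total_before = sum(countBefore[ok]), total_after = sum(countAfter[ok]))
}

#' Normalize gene fitness values within a sample
#'
#' Subtracts the per-sample median, so that most values sit near zero
#' (in a typical experiment most genes are neutral). Idempotent and
#' shift-invariant.
#'
#' @param x Gene fitness values for one sample.
#' @return Centered values.
#' @export
normalizeSample <- function(x) {
  if (!length(x)) stopf("no fitness values to normalize")
  x - median(x, na.rm = TRUE)
}

#' Gene-by-sample fitness matrix from a count table
#'
#' Runs the full fitness computation for every sample column of a count
#' table (see [readCountTable()]): strain fitness against the `before`
#' column, inverse-variance weighted gene averages over central
#' insertions, then per-sample median normalization.
#'
#' @param counts Count table with columns `barcode`, `gene_id`,
#'   `pos_fraction`, a `before` column and one or more after-sample
#'   columns.
#' @param beforeColumn Name of the before-growth count column.
#' @param pseudocount Pseudocount for [strainFitness()].
#' @param window Central insertion window for [geneFitness()].
#' @param normalize Apply per-sample median centering?
#' @return A data.frame: `gene_id`, then one fitness column per sample,
#'   plus `n_strains`. Genes with no qualifying strain get NA.
#' @export
fitnessMatrix <- function(counts, beforeColumn = "before", pseudocount = 1,
                          window = c(0.1, 0.9), normalize = TRUE) {
  sampleCols <- setdiff(names(counts),
                        c("barcode", "gene_id", "pos_fraction", beforeColumn))
  if (!length(sampleCols)) stopf("no after-sample columns found")
  inGene <- !is.na(counts$gene_id) & nzchar(counts$gene_id)
  genes <- sort(unique(counts$gene_id[inGene]))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  depthBefore <- sum(counts[[beforeColumn]])
  strainIdx <- split(which(inGene), counts$gene_id[inGene])
  nStrains <- integer(length(genes))
  for (sc in sampleCols) {
    depthAfter <- sum(counts[[sc]])
    sf <- strainFitness(counts[[beforeColumn]], counts[[sc]],
                        depthBefore, depthAfter, pseudocount)
    vals <- vapply(seq_along(genes), function(g) {
      idx <- strainIdx[[genes[g]]]
      gf <- geneFitness(sf[idx], counts[[beforeColumn]][idx],
                        counts[[sc]][idx], counts$pos_fraction[idx], window)
      nStrains[g] <<- gf$n_strains
      gf$fitness
    }, numeric(1))
    if (normalize) vals <- normalizeSample(vals)
    out[[sc]] <- vals
  }
  out$n_strains <- nStrains
  out
}
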