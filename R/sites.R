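#' Canonical MetE functional-residue positions
#'
#' The zinc-coordinating residues of E. coli MetE are His641, Cys643,
#' Glu665 and Cys726; the substrate (homocysteine/methionine) binding
#' residues are Ser433, Glu484 and Asp599. These positions, in E. coli
#' MetE numbering, anchor residue mapping onto candidate synthases.
#'
#' @param referenceId Identifier of the reference protein.
#' @param zincPos,substratePos Site positions on the reference.
#' @param zincRes,substrateRes Expected residues.
#' @return A [ReferenceSites-class].
#' @export
referenceSites <- function(referenceId = "MetE",
                           zincPos = c(641L, 643L, 665L, 726L),
                           substratePos = c(433L, 484L, 599L),
                           zincRes = c("H", "C", "E", "C"),
                           substrateRes = c("S", "E", "D")) {
  new("ReferenceSites", referenceId = referenceId,
      zincPos = as.integer(zincPos), substratePos = as.integer(substratePos),
      zincRes = zincRes, substrateRes = substrateRes)
}

#' Map reference functional residues onto a candidate
#'
#' Aligns the candidate to the reference (pairwise local alignment by
#' default) and maps each reference site position through the alignment's
#' column map. Positions falling outside the aligned region, or opposite
#' a gap, are flagged unaligned.
#'
#' @param reference Reference sequence (named, see [alignLocal()]).
#' @param sites A [ReferenceSites-class]; positions must lie within the
#'   reference.
#' @param candidate Candidate sequence.
#' @param scheme A [ScoringScheme-class].
#' @return A data.frame with one row per site: `site` ("zinc"/"substrate"),
#'   `ref_pos`, `ref_res`, `cand_pos` (NA if unaligned), `observed`.
#' @export
mapReferenceSites <- function(reference, sites, candidate,
                              scheme = blosum62Scheme()) {
  ref <- asSingleSequence(reference, "reference")
  cand <- asSingleSequence(candidate, "candidate")
  allPos <- c(sites@zincPos, sites@substratePos)
  if (any(allPos > nchar(ref$seq)))
    stopf("reference site position %d beyond reference length %d",
          max(allPos), nchar(ref$seq))
  aln <- alignLocal(ref$seq, cand$seq, scheme,
                    queryId = ref$id, subjectId = cand$id)
  cm <- aln@columnMap
  mapOne <- function(p) {
    row <- which(!is.na(cm[, "query"]) & cm[, "query"] == p)
    if (length(row) != 1 || is.na(cm[row, "subject"])) NA_integer_
    else cm[row, "subject"]
  }
  candPos <- vapply(allPos, mapOne, integer(1))
  observed <- ifelse(is.na(candPos), NA_character_,
                     substring(cand$seq, candPos, candPos))
  data.frame(
    site = c(rep("zinc", length(sites@zincPos)),
             rep("substrate", length(sites@substratePos))),
    ref_pos = allPos,
    ref_res = c(sites@zincRes, sites@substrateRes),
    cand_pos = candPos,
    observed = observed,
    stringsAsFactors = FALSE)
}

#' Zinc-site compatibility rules
#'
#' The per-position rule table for the four zinc-coordinating positions
#' (E. coli MetE numbering). The table encodes exactly the substitutions
#' known or suspected to be compatible with zinc binding: His641 admits
#' no substitute; Cys643 may be His (most MesC) or Tyr (possibly
#' compatible); Glu665 may be Asp (as in the characterized MesB) but not
#' Gly; Cys726 may be Asn. Any other residue is incompatible. The table
#' is configuration: pass a modified copy to [classifyZincSite()].
#'
#' @return A list keyed by position with `conserved` and `compatible`
#'   residue vectors.
#' @export
zincRules <- function() {
  list(
    `641` = list(conserved = "H", compatible = character(0)),
    `643` = list(conserved = "C", compatible = c("H", "Y")),
    `665` = list(conserved = "E", compatible = "D"),
    `726` = list(conserved = "C", compatible = "N"))
}

#' Classify a candidate's zinc site
#'
#' Applies the compatibility rules to the four observed residues (or NA
#' for unaligned positions). The overall verdict is `intact` iff all four
#' sites are conserved, `broken` if any site is incompatible or unaligned,
#' and `compatible` otherwise. Unknown symbols are incompatible.
#'
#' @param observed Character vector of four residues; NA marks an
#'   unaligned position.
#' @param rules Rule table from [zincRules()].
#' @return A list with `status` (per-site, in conserved/compatible/
#'   incompatible/unaligned) and `overall` (intact/compatible/broken).
#' @examples
#' classifyZincSite(c("H", "C", "E", "C"))$overall  # intact
#' classifyZincSite(c("H", "C", "D", "C"))$overall  # compatible
#' classifyZincSite(c("F", "S", "H", "G"))$overall  # broken
#' @export
classifyZincSite <- function(observed, rules = zincRules()) {
  if (length(observed) != length(rules))
    stopf("expected %d observed residues", length(rules))
  status <- character(length(rules))
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    status[i] <- if (is.na(observed[i])) "unaligned"
      else if (observed[i] %in% r$conserved) "conserved"
      else if (observed[i] %in% r$compatible) "compatible"
      else "incompatible"
  }
  overall <- if (all(status == "conserved")) "intact"
    else if (any(status %in% c("incompatible", "unaligned"))) "broken"
    else "compatible"
  list(status = setNames(status, names(rules)), overall = overall)
}

#' Information content of an alignment column
#'
#' Sequence-logo stack height in bits: `log2(20) - H`, where `H` is the
#' Shannon entropy of the residue frequencies in the column. Gaps are
#' excluded from the counts; no small-sample correction is applied.
#'
#' @param column Character vector of residues (may contain `-` gaps).
#' @return Information content in bits, in \[0, log2(20)\].
#' @examples
#' columnInformation(rep("C", 10))            # log2(20) ~ 4.32
#' columnInformation(c("A", "A", "C", "C"))   # log2(20) - 1
#' @export
columnInformation <- function(column) {
  col <- column[column != "-" & !is.na(column)]
  if (!length(col)) stopf("all-gap column has no information content")
  p <- table(col)
  p <- as.numeric(p) / sum(p)
  H <- -sum(p * log2(p))
  log2(20) - H
}

#' Per-column logo data for a family alignment
#'
#' @param msa A named equal-width `AAStringSet` or character vector.
#' @return A data.frame with `column`, `information` (bits) and one
#'   height column per observed residue (frequency times information,
#'   the usual logo letter height).
#' @export
logoData <- function(msa) {
  m <- msaToMatrix(msa)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col)) {
      return(data.frame(column = j, information = NA_real_))
    }
    ic <- columnInformation(col)
    freq <- table(factor(col, levels = AA20)) / length(col)
    heights <- as.numeric(freq) * ic
    out <- data.frame(column = j, information = ic)
    out[paste0("h_", AA20)] <- as.list(heights)
    out
  })
  do.call(rbind, rows)
}

#' Site report across candidates
#'
#' Maps the reference functional residues onto each candidate, classifies
#' the zinc site, and tabulates one row per candidate. For MesB the
#' substrate position corresponding to Glu484 is hard to align (a highly
#' variable region), so an unaligned substrate position never breaks a
#' verdict; only zinc positions determine the verdict.
#'
#' @param reference Reference sequence.
#' @param sites A [ReferenceSites-class].
#' @param candidates Named `AAStringSet`.
#' @param scheme A [ScoringScheme-class].
#' @param rules Zinc rule table.
#' @return A data.frame, one row per candidate, with mapped positions,
#'   observed residues and the zinc verdict.
#' @export
siteReport <- function(reference, sites, candidates,
                       scheme = blosum62Scheme(), rules = zincRules()) {
  rows <- lapply(names(candidates), function(id) {
    sm <- mapReferenceSites(reference, sites, candidates[id], scheme)
    zinc <- sm[sm$site == "zinc", ]
    verdict <- classifyZincSite(zinc$observed, rules)
    data.frame(candidate = id,
               zinc_pos = paste(zinc$cand_pos, collapse = ","),
               zinc_obs = paste(ifelse(is.na(zinc$observed), "-",
                                       zinc$observed), collapse = ""),
               substrate_obs = paste(ifelse(is.na(sm$observed[sm$site == "substrate"]),
                                            "-", sm$observed[sm$site == "substrate"]),
                                     collapse = ""),
               verdict = verdict$overall,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
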