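#' Construct a family reference
#'
#' @param family Family name.
#' @param query Named length-1 `AAStringSet` (or named character) with
#'   the family's reference/query sequence.
#' @param threshold Bit-score threshold for membership.
#' @param maxLength Optional maximum candidate length (residues).
#' @param enforceSites If TRUE, candidates whose zinc site is broken are
#'   demoted to non-enzymatic homologs rather than synthase calls.
#' @param zincPositions Positions of the four zinc-coordinating residues
#'   on the query (empty if not applicable).
#' @return A [FamilyReference-class].
#' @export
familyReference <- function(family, query, threshold,
                            maxLength = NA_real_, enforceSites = FALSE,
                            zincPositions = integer(0)) {
  if (is.character(query)) query <- Biostrings::AAStringSet(query)
  new("FamilyReference", family = family, query = query,
      threshold = threshold, maxLength = as.numeric(maxLength),
      enforceSites = enforceSites, zincPositions = as.integer(zincPositions))
}

#' Bit-score thresholds printed for the published family definitions
#'
#' The thresholds used with the original profile searches: 174 bits to
#' METE_METTM for MesA, 173 bits to DET0516 for MesB, 38 bits to Q8TUL3
#' for MesC, 560 bits to ACIAD3523 for MesD, and 200 bits to the
#' METE_PYRFU-like query for the catalytic component of split MetE.
#' MesD has two published operational definitions; both are exposed as
#' presets (`mesd_preset`): 560 bits (~72% identity, reference-proteome
#' screen) or 390 BLASTp bits (~55% identity, genome-neighborhood based).
#' Which preset fits a given input is the caller's choice.
#'
#' Because this package scores with Smith-Waterman rather than a profile
#' HMM, these values are defaults for comparability, not constants;
#' [calibrateThreshold()] rescales a threshold so that packaged
#' true/decoy sets separate.
#'
#' @param mesd_preset `"uniprot"` (560 bits) or `"microbesonline"`
#'   (390 bits).
#' @return Named numeric vector of thresholds.
#' @export
paperThresholds <- function(mesd_preset = c("uniprot", "microbesonline")) {
  mesd_preset <- match.arg(mesd_preset)
  c(MesA = 174, MesB = 173, MesC = 38,
    MesD = if (mesd_preset == "uniprot") 560 else 390,
    SplitMetE_cat = 200)
}

#' Calibrate a family threshold on true and decoy sets
#'
#' Sets the threshold to the midpoint between the lowest-scoring true
#' member and the highest-scoring decoy, in bits. Errors if the sets do
#' not separate.
#'
#' @param reference A [FamilyReference-class].
#' @param truePositives Named `AAStringSet` of known members.
#' @param decoys Named `AAStringSet` of non-members.
#' @param scheme A [ScoringScheme-class].
#' @return The reference with an updated threshold.
#' @export
calibrateThreshold <- function(reference, truePositives, decoys,
                               scheme = blosum62Scheme()) {
  tp <- searchProteome(reference@query, truePositives, scheme)$bits
  dc <- searchProteome(reference@query, decoys, scheme)$bits
  if (min(tp) <= max(dc))
    stopf("family %s: true members (min %.1f bits) do not separate from decoys (max %.1f bits)",
          reference@family, min(tp), max(dc))
  reference@threshold <- (min(tp) + max(dc)) / 2
  reference
}

#' Assign a family to one protein
#'
#' Scores the protein against every family reference. Among families
#' whose bit threshold is met, the protein is assigned to the family with
#' the highest percent identity to its query (the disambiguation rule:
#' a protein hitting two families is assigned to the more similar one
#' and the other hit is disregarded). If the winning family enforces the
#' site policy and the protein's zinc verdict is broken, the call is
#' flagged `non_enzymatic` — a family-like homolog, excluded from
#' synthase counts.
#'
#' @param protein A single named sequence.
#' @param references List of [FamilyReference-class] objects.
#' @param scheme A [ScoringScheme-class].
#' @param rules Zinc rule table from [zincRules()].
#' @return A one-row data.frame: `protein_id`, `family` (NA if no
#'   threshold met), `bits`, `identity_pct`, `non_enzymatic`,
#'   `disambiguated`, `length_violation`.
#' @export
assignFamily <- function(protein, references, scheme = blosum62Scheme(),
                         rules = zincRules()) {
  if (!length(references)) stopf("no family references supplied")
  p <- asSingleSequence(protein, "protein")
  pLen <- nchar(p$seq)
  pSet <- Biostrings::AAStringSet(setNames(p$seq, p$id))
  # score-only screen first; full alignments only where a threshold is met
  hits <- lapply(references, function(ref) {
    bits <- searchProteome(ref@query, pSet, scheme)$bits
    lengthViolation <- !is.na(ref@maxLength) && pLen > ref@maxLength
    list(ref = ref, bits = bits,
         pass = bits >= ref@threshold && !lengthViolation,
         lengthViolation = lengthViolation)
  })
  passing <- lapply(Filter(function(h) h$pass, hits), function(h) {
    h$aln <- alignLocal(h$ref@query, p$seq, scheme, subjectId = p$id)
    h
  })
  if (!length(passing)) {
    anyLen <- any(vapply(hits, function(h)
      h$lengthViolation && h$bits >= h$ref@threshold, logical(1)))
    return(data.frame(protein_id = p$id, family = NA_character_,
                      bits = NA_real_, identity_pct = NA_real_,
                      non_enzymatic = FALSE, disambiguated = FALSE,
                      length_violation = anyLen, stringsAsFactors = FALSE))
  }
  ids <- vapply(passing, function(h) percentIdentity(h$aln, rounded = FALSE),
                numeric(1))
  win <- passing[[which.max(ids)]]
  nonEnz <- FALSE
  if (win$ref@enforceSites && length(win$ref@zincPositions) == 4) {
    qSeq <- as.character(win$ref@query[[1]])
    sites <- referenceSites(
      referenceId = win$ref@family,
      zincPos = win$ref@zincPositions,
      substratePos = integer(0),
      zincRes = vapply(win$ref@zincPositions,
                       function(i) substring(qSeq, i, i), character(1)),
      substrateRes = character(0))
    sm <- mapReferenceSites(win$ref@query, sites, p$seq, scheme)
    verdict <- classifyZincSite(sm$observed[sm$site == "zinc"], rules)
    nonEnz <- verdict$overall == "broken"
  }
  data.frame(protein_id = p$id, family = win$ref@family,
             bits = win$aln@bits,
             identity_pct = percentIdentity(win$aln, rounded = FALSE),
             non_enzymatic = nonEnz,
             disambiguated = length(passing) > 1,
             length_violation = FALSE, stringsAsFactors = FALSE)
}

#' Classify every protein of a proteome set
#'
#' Vectorized screening: each family query is scored against all proteins
#' (score-only Smith-Waterman), and full alignments are computed only for
#' proteins that reach at least one family threshold; those are then
#' disambiguated with [assignFamily()].
#'
#' @param proteins Named `AAStringSet`; `mcols(proteins)$genome_id` (if
#'   present) is carried into the output.
#' @param references List of [FamilyReference-class] objects.
#' @param scheme A [ScoringScheme-class].
#' @param rules Zinc rule table.
#' @return A data.frame with one row per protein that met at least one
#'   threshold (columns as in [assignFamily()], plus `genome_id`).
#' @export
classifyProteins <- function(proteins, references,
                             scheme = blosum62Scheme(), rules = zincRules()) {
  if (!length(references)) stopf("no family references supplied")
  anyPass <- rep(FALSE, length(proteins))
  for (ref in references) {
    sc <- searchProteome(ref@query, proteins, scheme)
    anyPass <- anyPass | (sc$bits >= ref@threshold)
  }
  genomeIds <- S4Vectors::mcols(proteins)$genome_id
  if (is.null(genomeIds)) genomeIds <- rep(NA_character_, length(proteins))
  rows <- lapply(which(anyPass), function(i) {
    row <- assignFamily(proteins[i], references, scheme, rules)
    row$genome_id <- genomeIds[i]
    row
  })
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), family = character(0),
                      bits = numeric(0), identity_pct = numeric(0),
                      non_enzymatic = logical(0), disambiguated = logical(0),
                      length_violation = logical(0), genome_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Split-MetE candidate rules
#'
#' The two per-protein decision rules of split-MetE detection, exposed as
#' vectorized pure functions. A catalytic-component candidate must reach
#' the bit threshold (default 200, which excludes all representatives of
#' the MesA-D families and MetE) against the catalytic query and be at
#' most `maxLength` (400) residues. A folate-binding-component candidate
#' must reach the N-domain profile cutoff and the length limit, and when
#' the protein also matches the catalytic-domain profile at its cutoff,
#' the N-domain score must be strictly higher.
#'
#' @param bits Bit score against the catalytic-component query.
#' @param length Protein length in residues.
#' @param threshold Catalytic bit threshold.
#' @param nScore,catScore Profile scores (bits) against the N-domain and
#'   catalytic-domain models.
#' @param nCutoff,catCutoff The two profile cutoffs.
#' @param maxLength Maximum candidate length.
#' @return Logical vector.
#' @export
splitCatCandidate <- function(bits, length, threshold = 200,
                              maxLength = 400) {
  bits >= threshold & length <= maxLength
}

#' @rdname splitCatCandidate
#' @export
splitFolateCandidate <- function(nScore, catScore, length, nCutoff,
                                 catCutoff, maxLength = 400) {
  nScore >= nCutoff & length <= maxLength &
    !(catScore >= catCutoff & nScore <= catScore)
}

#' Detect a split MetE system in one genome
#'
#' Catalytic candidates must score at least `catRef@threshold` bits
#' (default 200) against the catalytic-component query and be at most
#' 400 residues long; only the highest-scoring candidate per genome is
#' kept (ties broken by lexicographic protein id). Folate-binding
#' candidates must match the N-domain profile at its trusted cutoff and
#' be at most 400 residues; a protein that also matches the
#' catalytic-domain profile is kept only if its N-domain score is
#' strictly higher. The system is present iff both components are found.
#' The two components are not required to be adjacent, but adjacency is
#' reported when gene features are supplied.
#'
#' @param proteins Named `AAStringSet` for one genome.
#' @param catRef [FamilyReference-class] for the catalytic component
#'   (threshold in bits, `maxLength` defaulting to 400).
#' @param nDomainProfile,catDomainProfile [ProfileModel-class] objects
#'   for the folate-binding (N-terminal) and catalytic domains.
#' @param features Optional `GRanges` of gene features for adjacency.
#' @param maxIntergenicBp Adjacency gap limit (bp).
#' @param scheme A [ScoringScheme-class].
#' @param maxLength Candidate length limit for both components.
#' @return A one-row data.frame: `genome_id`, `catalytic_id`,
#'   `catalytic_bits`, `folate_id`, `folate_bits`, `present`, `adjacent`.
#' @export
detectSplitMetE <- function(proteins, catRef, nDomainProfile,
                            catDomainProfile, features = NULL,
                            maxIntergenicBp = 300,
                            scheme = blosum62Scheme(), maxLength = 400) {
  genomeId <- unique(S4Vectors::mcols(proteins)$genome_id)
  if (!length(genomeId)) genomeId <- NA_character_
  lens <- Biostrings::width(proteins)

  sc <- searchProteome(catRef@query, proteins, scheme)
  catLimit <- if (!is.na(catRef@maxLength)) catRef@maxLength else maxLength
  catOk <- splitCatCandidate(sc$bits, lens, catRef@threshold, catLimit)
  catId <- NA_character_; catBits <- NA_real_
  if (any(catOk)) {
    cand <- sc[catOk, ]
    cand <- cand[order(-cand$bits, cand$protein_id), ]
    catId <- cand$protein_id[1]
    catBits <- cand$bits[1]
  }

  folId <- NA_character_; folBits <- NA_real_
  shortEnough <- which(lens <= maxLength)
  if (length(shortEnough)) {
    nScores <- vapply(shortEnough, function(i)
      scoreProfile(nDomainProfile, proteins[i]), numeric(1))
    # catalytic-domain scores needed only where the N profile matches
    cScores <- rep(-Inf, length(shortEnough))
    for (k in which(nScores >= nDomainProfile@cutoff))
      cScores[k] <- scoreProfile(catDomainProfile, proteins[shortEnough[k]])
    keep <- splitFolateCandidate(nScores, cScores, lens[shortEnough],
                                 nDomainProfile@cutoff,
                                 catDomainProfile@cutoff, maxLength)
    if (any(keep)) {
      ord <- order(-nScores[keep], names(proteins)[shortEnough[keep]])
      pick <- which(keep)[ord[1]]
      folId <- names(proteins)[shortEnough[pick]]
      folBits <- nScores[pick]
    }
  }

  present <- !is.na(catId) && !is.na(folId)
  adjacent <- NA
  if (present && !is.null(features)) {
    pairs <- findOperonPairs(features, catId, folId,
                             maxIntergenicBp = maxIntergenicBp,
                             requireSameStrand = FALSE)
    adjacent <- nrow(pairs) > 0
  }
  data.frame(genome_id = genomeId, catalytic_id = catId,
             catalytic_bits = catBits, folate_id = folId,
             folate_bits = folBits, present = present, adjacent = adjacent,
             stringsAsFactors = FALSE)
}

#' Call MetH from a distant reference
#'
#' A protein is called MetH if it matches the curated-model profile at
#' its trusted cutoff, or if it aligns to the distant characterized
#' reference with at least `bitFloor` bits and at least 80% coverage of
#' the query (the coverage rule excludes single-domain matches to a
#' multi-domain query).
#'
#' @param protein A single named sequence.
#' @param reference [FamilyReference-class] whose query is the
#'   characterized MetH; `threshold` is the bit floor standing in for the
#'   published E-value cutoff.
#' @param profile Optional [ProfileModel-class] for the curated model.
#' @param minCoverage Minimum query coverage (default 0.8).
#' @param scheme A [ScoringScheme-class].
#' @return Logical.
#' @export
callMetH <- function(protein, reference, profile = NULL,
                     minCoverage = 0.8, scheme = blosum62Scheme()) {
  p <- asSingleSequence(protein, "protein")
  if (!is.null(profile) && scoreProfile(profile, p$seq) >= profile@cutoff)
    return(TRUE)
  aln <- alignLocal(reference@query, p$seq, scheme, subjectId = p$id)
  qLen <- Biostrings::width(reference@query)[1]
  aln@bits >= reference@threshold && queryCoverage(aln, qLen) >= minCoverage
}
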