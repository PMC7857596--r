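#' Synthetic family seed sequences
#'
#' Deterministically constructs a miniature set of synthetic reference
#' sequences, one per family tracked by the pipeline. These are synthetic
#' stand-ins, not database sequences: a full-length MetE-like scaffold
#' (753 residues) carries the canonical functional residues (zinc
#' H641/C643/E665/C726, substrate S433/E484/D599, E. coli MetE
#' numbering), and each core-synthase seed is derived from the scaffold's
#' catalytic region through an explicit segment map, so that the zinc and
#' substrate sites fall at the positions reported for the characterized
#' family representatives: MesA 216/218/240/301 and 8/59/174, MesB
#' 214/216/235/311 and 15/69/177, MesC 204/206/225/314 and 11/59/166.
#' Core-synthase seeds are at most 386 residues. Inter-family seed
#' identities are kept below 30% by independent heavy mutation outside
#' short conserved windows around the functional sites. Non-synthase
#' families (MesX, MetF, AcsB/C/D, MetH) are independent random sequences
#' of realistic lengths.
#'
#' @param seed Integer seed fixing the construction (default 20210203;
#'   the same seed always yields byte-identical seeds).
#' @return A list: `seeds` (named `AAStringSet`), `sites` (per-family
#'   list with `zinc` and `substrate` positions), `lengths`.
#' @export
familySeeds <- function(seed = 20210203) {
  withSeed(seed, {
    metE <- randomProteinChars(753)
    metE <- implantSites(metE, c(641, 643, 665, 726), c("H", "C", "E", "C"))
    metE <- implantSites(metE, c(433, 484, 599), c("S", "E", "D"))

    canonical <- list(zinc = c(641L, 643L, 665L, 726L),
                      substrate = c(433L, 484L, 599L))
    mk <- function(zinc, substrate, len, keepProb = 0.28) {
      anchors <- cbind(ref = c(canonical$substrate, canonical$zinc),
                       cand = c(substrate, zinc))
      anchors <- anchors[order(anchors[, "ref"]), , drop = FALSE]
      deriveSeed(metE, anchors, len, keepProb)
    }
    seeds <- list(
      MetE = paste(metE, collapse = ""),
      MesA = mk(c(216, 218, 240, 301), c(8, 59, 174), 328),
      MesB = mk(c(214, 216, 235, 311), c(15, 69, 177), 338),
      MesC = mk(c(204, 206, 225, 314), c(11, 59, 166), 340),
      MesD = mk(c(268, 270, 292, 353), c(60, 111, 226), 380),
      SplitMetE_cat = mk(c(231, 233, 255, 316), c(23, 74, 189), 343,
                         keepProb = 0.45),
      SplitMetE_N = paste(mutateChars(metE[11:370], keepProb = 0.5),
                          collapse = ""),
      MesX = paste(randomProteinChars(300), collapse = ""),
      MetH = paste(randomProteinChars(810), collapse = ""),
      MetF = paste(randomProteinChars(290), collapse = ""),
      AcsB = paste(randomProteinChars(720), collapse = ""),
      AcsC = paste(randomProteinChars(470), collapse = ""),
      AcsD = paste(randomProteinChars(420), collapse = ""))
    sites <- list(
      MetE = canonical,
      MesA = list(zinc = c(216L, 218L, 240L, 301L), substrate = c(8L, 59L, 174L)),
      MesB = list(zinc = c(214L, 216L, 235L, 311L), substrate = c(15L, 69L, 177L)),
      MesC = list(zinc = c(204L, 206L, 225L, 314L), substrate = c(11L, 59L, 166L)),
      MesD = list(zinc = c(268L, 270L, 292L, 353L), substrate = c(60L, 111L, 226L)),
      SplitMetE_cat = list(zinc = c(231L, 233L, 255L, 316L),
                           substrate = c(23L, 74L, 189L)))
    ss <- Biostrings::AAStringSet(unlist(seeds))
    list(seeds = ss, sites = sites,
         lengths = setNames(Biostrings::width(ss), names(ss)))
  })
}

randomProteinChars <- function(n) {
  sample(names(AA_BACKGROUND), n, replace = TRUE, prob = AA_BACKGROUND)
}

implantSites <- function(chars, positions, residues) {
  chars[positions] <- residues
  chars
}

# Mutate a character vector: keep each residue with probability keepProb,
# otherwise replace by a different uniformly drawn residue. Uniform (not
# similarity-weighted) replacement keeps independently derived seeds from
# converging on the same substitutions, which would inflate inter-family
# identity.
mutateChars <- function(chars, keepProb) {
  mut <- runif(length(chars)) > keepProb
  if (any(mut))
    chars[mut] <- vapply(chars[mut], uniformSubstitute, character(1))
  chars
}

uniformSubstitute <- function(r) sample(setdiff(AA20, r), 1)

# Derive a family seed from the scaffold via an anchor map. Between
# consecutive anchors (and at the termini) the candidate copies scaffold
# residues in two half-runs so any indel sits mid-interval; copied
# positions within windowHalf of an anchor are conserved exactly, other
# copied positions are kept with probability keepProb, and unmatched
# candidate positions (insertions) are random residues.
deriveSeed <- function(refChars, anchors, candLen, keepProb,
                       windowHalf = 3) {
  src <- rep(NA_integer_, candLen)  # scaffold position feeding each candidate position
  aRef <- anchors[, "ref"]; aCand <- anchors[, "cand"]
  K <- nrow(anchors)
  src[aCand] <- aRef
  lead <- aCand[1] - 1
  if (lead > 0) src[seq_len(lead)] <- aRef[1] - lead:1
  for (k in seq_len(K - 1)) {
    cA <- aCand[k]; cB <- aCand[k + 1]; rA <- aRef[k]; rB <- aRef[k + 1]
    spanC <- cB - cA - 1; spanR <- rB - rA - 1
    matched <- min(spanC, spanR)
    if (matched > 0) {
      h1 <- matched %/% 2; h2 <- matched - h1
      if (h1 > 0) src[cA + seq_len(h1)] <- rA + seq_len(h1)
      if (h2 > 0) src[cB - h2:1] <- rB - h2:1
    }
  }
  tail <- candLen - aCand[K]
  if (tail > 0) {
    if (aRef[K] + tail > length(refChars))
      stopf("candidate tail extends beyond the scaffold")
    src[aCand[K] + seq_len(tail)] <- aRef[K] + seq_len(tail)
  }
  nearAnchor <- rep(FALSE, candLen)
  for (a in aCand)
    nearAnchor[max(1, a - windowHalf):min(candLen, a + windowHalf)] <- TRUE
  out <- character(candLen)
  for (i in seq_len(candLen)) {
    if (is.na(src[i])) {
      out[i] <- randomProteinChars(1)
    } else {
      r <- refChars[src[i]]
      out[i] <- if (nearAnchor[i] || runif(1) < keepProb) r
                else uniformSubstitute(r)
    }
  }
  paste(out, collapse = "")
}

# Draw a replacement residue, weighted towards BLOSUM62-positive
# exchanges; falls back to uniform when no exchange is positive.
substituteResidue <- function(r) {
  m <- blosumCache()
  w <- pmax(m[r, AA20], 0)
  w[r] <- 0
  if (sum(w) == 0) w[] <- 1 * (AA20 != r)
  sample(AA20, 1, prob = w)
}

blosumEnv <- new.env()
blosumCache <- function() {
  if (is.null(blosumEnv$m)) blosumEnv$m <- blosum62Scheme()@matrix
  blosumEnv$m
}

#' Generate a synthetic family member at a controlled identity
#'
#' Substitutes residues of the seed at randomly chosen non-site
#' positions (substitutions weighted towards BLOSUM62-positive
#' exchanges) until the expected identity to the seed equals the target;
#' the functional-site residues are then set according to `siteStatus`:
#' `"intact"` writes the canonical zinc residues H,C,E,C, `"broken"`
#' writes one of the observed non-enzymatic patterns FSHG, YCDQ or YREQ,
#' `"none"` leaves all positions eligible for substitution.
#'
#' @param seedSeq Seed sequence (named character or length-1 set).
#' @param targetIdentity Target identity in \[0.25, 1\].
#' @param siteStatus `"intact"`, `"broken"`, or `"none"`.
#' @param sites List with `zinc` (and optionally `substrate`) positions
#'   on the seed; required unless `siteStatus = "none"`.
#' @param seed Integer RNG seed.
#' @return A character string (the member sequence).
#' @export
generateFamilyMember <- function(seedSeq, targetIdentity,
                                 siteStatus = c("intact", "broken", "none"),
                                 sites = NULL, seed = 1) {
  siteStatus <- match.arg(siteStatus)
  s <- asSingleSequence(seedSeq, "seed")$seq
  if (targetIdentity < 0.25 || targetIdentity > 1)
    stopf("target identity must be in [0.25, 1]")
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  sitePos <- integer(0)
  if (siteStatus != "none") {
    if (is.null(sites)) stopf("site positions required for siteStatus '%s'", siteStatus)
    sitePos <- sort(unique(unlist(sites)))
  }
  withSeed(seed, {
    nSub <- round((1 - targetIdentity) * L)
    eligible <- setdiff(seq_len(L), sitePos)
    if (nSub > length(eligible))
      stopf("target identity %.2f unreachable while preserving %d site positions",
            targetIdentity, length(sitePos))
    if (nSub > 0) {
      at <- sample(eligible, nSub)
      chars[at] <- vapply(chars[at], substituteResidue, character(1))
    }
    if (siteStatus == "intact") {
      chars[sites$zinc] <- c("H", "C", "E", "C")
    } else if (siteStatus == "broken") {
      pattern <- sample(c("FSHG", "YCDQ", "YREQ"), 1)
      chars[sites$zinc] <- strsplit(pattern, "")[[1]]
    }
    paste(chars, collapse = "")
  })
}

#' Generate one synthetic genome
#'
#' Places family members, operon partners and shuffled-composition decoys
#' on a single contig with configurable intergenic gaps. Families named
#' together in an `operons` entry are placed consecutively on the same
#' strand with a small gap (so adjacency detection can recover them, as
#' in the conserved mesB-acsC-acsD and mesD-mesX arrangements); all other
#' genes are separated by `looseGapBp`.
#'
#' @param genomeId Genome identifier.
#' @param members Data.frame with columns `family`, `identity`,
#'   `site_status` — or a named integer vector of family counts, in
#'   which case identities are drawn uniformly from `identityRange` and
#'   zinc-bearing families are intact.
#' @param operons List of character vectors of family names to place
#'   adjacently (each named family must occur among the members).
#' @param decoys Number of shuffled-composition decoy proteins.
#' @param seed Integer RNG seed; the same seed gives byte-identical output.
#' @param identityRange Identity range for members when `members` is a
#'   count vector.
#' @param operonGapBp,looseGapBp Intergenic gaps within operons and
#'   elsewhere.
#' @param seedSet Result of [familySeeds()].
#' @return A list: `proteins` (named `AAStringSet` with genome ids),
#'   `features` (`GRanges`), `truth` (data.frame manifest).
#' @export
generateGenome <- function(genomeId, members = c(), operons = list(),
                           decoys = 0, seed = 1,
                           identityRange = c(0.4, 0.9),
                           operonGapBp = 50, looseGapBp = 500,
                           seedSet = familySeeds()) {
  if (!is.data.frame(members)) {
    fams <- if (length(members)) rep(names(members), as.integer(members))
            else character(0)
    members <- data.frame(
      family = fams,
      identity = rep(NA_real_, length(fams)),
      site_status = ifelse(fams %in% names(seedSet$sites), "intact", "none"),
      stringsAsFactors = FALSE)
  }
  unknownFam <- setdiff(members$family, names(seedSet$seeds))
  if (length(unknownFam))
    stopf("unknown family name: %s", paste(unknownFam, collapse = ", "))
  for (op in operons) {
    missing <- setdiff(op, members$family)
    if (length(missing))
      stopf("operon names families absent from the genome: %s",
            paste(missing, collapse = ", "))
  }
  withSeed(seed, {
    n <- nrow(members)
    if (n > 0 && any(is.na(members$identity)))
      members$identity[is.na(members$identity)] <-
        runif(sum(is.na(members$identity)), identityRange[1], identityRange[2])
    seqs <- character(0); truth <- list(); famOf <- character(0)
    for (i in seq_len(if (n > 0) n else 0)) {
      fam <- members$family[i]
      pid <- sprintf("%s_p%02d", genomeId, i)
      seqs[pid] <- generateFamilyMember(
        seedSet$seeds[fam], members$identity[i],
        siteStatus = members$site_status[i],
        sites = seedSet$sites[[fam]],
        seed = sample.int(2^30, 1))
      famOf[pid] <- fam
      truth[[pid]] <- data.frame(
        protein_id = pid, genome_id = genomeId, family = fam,
        target_identity = members$identity[i],
        site_status = members$site_status[i],
        operon = "", stringsAsFactors = FALSE)
    }
    for (d in seq_len(decoys)) {
      pid <- sprintf("%s_d%02d", genomeId, d)
      template <- seedSet$seeds[[sample.int(length(seedSet$seeds), 1)]]
      seqs[pid] <- paste(sample(strsplit(as.character(template), "")[[1]]),
                         collapse = "")
      famOf[pid] <- "decoy"
      truth[[pid]] <- data.frame(
        protein_id = pid, genome_id = genomeId, family = "none",
        target_identity = NA_real_, site_status = "none", operon = "",
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(protein_id = character(0), genome_id = character(0),
                             family = character(0), target_identity = numeric(0),
                             site_status = character(0), operon = character(0))
    # gene order: operon blocks first (members in stated order), then the rest
    ids <- names(seqs)
    placed <- character(0); blocks <- list()
    for (oi in seq_along(operons)) {
      block <- vapply(operons[[oi]], function(fam) {
        cand <- setdiff(ids[famOf == fam], placed)
        cand[1]
      }, character(1))
      placed <- c(placed, block)
      truth$operon[truth$protein_id %in% block] <- sprintf("op%d", oi)
      blocks[[oi]] <- block
    }
    rest <- setdiff(ids, placed)
    if (length(rest)) rest <- sample(rest)
    cur <- 1L; rows <- list()
    addGene <- function(pid, strand, gapAfter) {
      len <- 3L * nchar(seqs[[pid]]) + 3L
      row <- data.frame(genome_id = genomeId, gene_id = pid,
                        contig = paste0(genomeId, "_c1"),
                        start = cur, end = cur + len - 1L, strand = strand,
                        stringsAsFactors = FALSE)
      cur <<- cur + len + gapAfter
      row
    }
    for (block in blocks) {
      strand <- sample(c("+", "-"), 1)
      for (k in seq_along(block))
        rows[[length(rows) + 1]] <- addGene(
          block[k], strand,
          if (k < length(block)) operonGapBp else looseGapBp)
    }
    for (pid in rest)
      rows[[length(rows) + 1]] <- addGene(pid, sample(c("+", "-"), 1),
                                          looseGapBp)
    featDf <- if (length(rows)) do.call(rbind, rows)
      else data.frame(genome_id = character(0), gene_id = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
    proteins <- Biostrings::AAStringSet(seqs)
    S4Vectors::mcols(proteins)$genome_id <- rep(genomeId, length(proteins))
    list(proteins = proteins,
         features = if (nrow(featDf)) asGeneFeatures(featDf) else
           GenomicRanges::GRanges(),
         truth = truth)
  })
}

#' Generate a multi-genome synthetic screen
#'
#' Emulates, in miniature, a reference-proteome screen: each genome draws
#' a repertoire of synthase families with members at controlled identity
#' (default 40-90% to the family seed), accessory families follow their
#' biological associations (MesB genomes carry AcsB/AcsC/AcsD with the
#' mesB-acsC-acsD operon; MesD genomes carry MesX adjacently), a
#' configurable fraction of zinc-bearing members carries a broken site,
#' and every genome receives shuffled decoys.
#'
#' @param nGenomes Number of genomes.
#' @param seed Integer RNG seed.
#' @param decoysPerGenome Decoys per genome.
#' @param brokenFraction Fraction of core-synthase members generated with
#'   a broken zinc site.
#' @param identityRange Member identity range.
#' @param seedSet Result of [familySeeds()].
#' @return A list: `proteins`, `features`, `truth` (as in
#'   [generateGenome()], concatenated), `genomes`.
#' @export
generateScreen <- function(nGenomes = 50, seed = 1, decoysPerGenome = 10,
                           brokenFraction = 0, identityRange = c(0.4, 0.9),
                           seedSet = familySeeds()) {
  core <- c("MesA", "MesB", "MesC", "MesD")
  withSeed(seed, {
    plans <- lapply(seq_len(nGenomes), function(g) {
      fams <- sample(core, sample(1:2, 1))
      members <- data.frame(family = fams,
                            identity = runif(length(fams), identityRange[1],
                                             identityRange[2]),
                            site_status = ifelse(
                              runif(length(fams)) < brokenFraction,
                              "broken", "intact"),
                            stringsAsFactors = FALSE)
      operons <- list()
      if ("MesB" %in% fams) {
        members <- rbind(members, data.frame(
          family = c("AcsB", "AcsC", "AcsD"), identity = runif(3, 0.6, 0.95),
          site_status = "none"))
        operons <- c(operons, list(c("MesB", "AcsC", "AcsD")))
      }
      if ("MesD" %in% fams) {
        members <- rbind(members, data.frame(
          family = "MesX", identity = runif(1, 0.6, 0.95),
          site_status = "none"))
        operons <- c(operons, list(c("MesD", "MesX")))
      }
      list(members = members, operons = operons,
           seed = sample.int(2^30, 1))
    })
    out <- lapply(seq_along(plans), function(g)
      generateGenome(sprintf("g%03d", g), plans[[g]]$members,
                     plans[[g]]$operons, decoys = decoysPerGenome,
                     seed = plans[[g]]$seed, seedSet = seedSet))
    proteins <- do.call(c, lapply(out, `[[`, "proteins"))
    featList <- lapply(out, `[[`, "features")
    features <- suppressWarnings(do.call(c, featList))
    truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    list(proteins = proteins, features = features, truth = truth,
         genomes = sprintf("g%03d", seq_len(nGenomes)))
  })
}

#' Generate synthetic BarSeq counts from known gene fitness
#'
#' Each gene receives `nStrainsPerGene` barcoded strains with uniform
#' insertion positions; strain abundances after growth are proportional
#' to `before * 2^fitness(gene)`, and counts are Poisson draws at the
#' given sequencing depth. A neutral experiment (all fitness 0) has
#' equal expected counts before and after.
#'
#' @param trueFitness Named numeric vector of per-gene log2 fitness.
#' @param nStrainsPerGene Strains per gene.
#' @param depth Total counts per sample.
#' @param seed Integer RNG seed.
#' @param intergenicFraction Fraction of additional strains with no gene
#'   assignment.
#' @return A list: `counts` (data.frame with `barcode`, `gene_id`,
#'   `pos_fraction`, `before`, `after`), `truth` (the input fitness).
#' @export
generateBarseq <- function(trueFitness, nStrainsPerGene = 10, depth = 5e5,
                           seed = 1, intergenicFraction = 0) {
  if (depth <= 0) stopf("depth must be positive")
  genes <- names(trueFitness)
  withSeed(seed, {
    geneOf <- rep(genes, each = nStrainsPerGene)
    nExtra <- round(length(geneOf) * intergenicFraction)
    geneOf <- c(geneOf, rep("", nExtra))
    n <- length(geneOf)
    f <- ifelse(geneOf == "", 0, trueFitness[geneOf])
    pos <- runif(n)
    beforeRel <- rgamma(n, shape = 2)
    afterRel <- beforeRel * 2^f
    before <- rpois(n, depth * beforeRel / sum(beforeRel))
    after <- rpois(n, depth * afterRel / sum(afterRel))
    counts <- data.frame(
      barcode = sprintf("bc%06d", seq_len(n)),
      gene_id = geneOf, pos_fraction = pos,
      before = before, after = after, stringsAsFactors = FALSE)
    list(counts = counts, truth = trueFitness)
  })
}

#' @importFrom stats rgamma
NULL
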