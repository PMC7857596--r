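makeCalls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(protein_id = r[[1]], genome_id = r[[2]], family = r[[3]],
               bits = 200, identity_pct = 50,
               non_enzymatic = isTRUE(r$nonenz), disambiguated = FALSE,
               length_violation = FALSE, stringsAsFactors = FALSE)))
}

test_that("repertoire rows count calls, excluding non-enzymatic homologs", {
  calls <- makeCalls(list("p1", "g1", "MesB"), list("p2", "g1", "MesB"),
                     list("p3", "g2", "MesB", nonenz = TRUE),
                     list("p4", "g2", "AcsC"))
  rep <- buildRepertoire(calls, genomes = c("g1", "g2", "g3"))
  expect_equal(rep$MesB[rep$genome_id == "g1"], 2L)  # paralogs are counted
  expect_equal(rep$MesB[rep$genome_id == "g2"], 0L)  # non-enzymatic excluded
  expect_equal(rep$AcsC[rep$genome_id == "g2"], 1L)
  expect_true(all(unlist(rep[rep$genome_id == "g3", -1]) == 0))
  # column sums equal the non-flagged call counts
  expect_equal(sum(rep$MesB), 2L)
})

test_that("split MetE is counted once per genome and duplicates rejected", {
  calls <- makeCalls(list("p1", "g1", "MesA"))
  split <- data.frame(genome_id = c("g1", "g2"), present = c(TRUE, FALSE))
  rep <- buildRepertoire(calls, split, genomes = c("g1", "g2"))
  expect_equal(rep$SplitMetE, c(1L, 0L))
  splitDup <- data.frame(genome_id = c("g1", "g1"), present = TRUE)
  expect_error(buildRepertoire(calls, splitDup, genomes = "g1"),
               "duplicate")
})

test_that("co-occurrence fractions and counts follow the definition", {
  rep <- data.frame(genome_id = paste0("g", 1:5),
                    MesB = c(1, 2, 1, 1, 0), AcsC = c(1, 1, 1, 0, 1),
                    AcsD = c(1, 1, 0, 0, 1))
  both <- cooccurrence(rep, "MesB", c("AcsC", "AcsD"))
  expect_equal(both$numerator, 2)
  expect_equal(both$denominator, 4)
  expect_equal(both$fraction, 0.5)
  either <- cooccurrence(rep, "MesB", c("AcsC", "AcsD"), mode = "any")
  expect_equal(either$fraction, 0.75)
  none <- data.frame(genome_id = "g1", MesB = 0, AcsC = 1, AcsD = 1)
  res <- cooccurrence(none, "MesB", "AcsC")
  expect_true(res$undefined)
  expect_true(is.na(res$fraction))
})

test_that("sole-synthase detection handles the MesD/MesX unit and none", {
  rep <- data.frame(genome_id = paste0("g", 1:4),
                    MesA = c(0, 0, 0, 0), MesB = c(1, 0, 0, 0),
                    MesC = 0, MesD = c(0, 1, 1, 0), MesX = c(0, 1, 0, 0),
                    MetE = 0, MetH = c(0, 0, 1, 0), SplitMetE = 0,
                    MetF = 0, AcsB = 0, AcsC = 0, AcsD = 0)
  ss <- soleSynthase(rep)
  expect_equal(ss$sole, c("MesB", "MesD", "MetH", "none"))
  # with the switch off, MesD alone counts even without MesX
  ss2 <- soleSynthase(rep, mesdRequiresMesX = FALSE)
  expect_true(is.na(ss2$sole[3]))  # MesD + MetH: two synthases
})

test_that("operon pairs require consecutiveness, strand and gap", {
  df <- data.frame(
    genome_id = "g1", contig = "c1",
    gene_id = c("a1", "b1", "x1", "b2", "a2"),
    start = c(1000L, 2100L, 3100L, 4200L, 8000L),
    end = c(2000L, 3000L, 4100L, 5000L, 8900L),
    strand = c("+", "+", "+", "-", "-"))
  feats <- asGeneFeatures(df)
  # a1-b1 consecutive, same strand, gap 99 <= 300
  pairs <- findOperonPairs(feats, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gene_a, "a1")
  expect_equal(pairs$gap_bp, 99L)
  # strand requirement: b2(-) then a2(-) are consecutive but gap too large
  pairs2 <- findOperonPairs(feats, c("a1", "a2"), c("b1", "b2"),
                            maxIntergenicBp = 5000)
  expect_equal(nrow(pairs2), 2L)  # symmetric: (a,b) or (b,a) order
  # intervening gene blocks the pair: a1..x1..b2 is not consecutive
  pairs3 <- findOperonPairs(feats, "a1", "b2", maxIntergenicBp = 5000,
                            requireSameStrand = FALSE)
  expect_equal(nrow(pairs3), 0L)
  expect_error(findOperonPairs(feats, "missing", "b1"), "unknown gene ids")
})

test_that("operon pairs are symmetric in the two gene sets", {
  df <- data.frame(genome_id = "g1", contig = "c1",
                   gene_id = c("m", "n"), start = c(1L, 1201L),
                   end = c(1100L, 2300L), strand = "+")
  feats <- asGeneFeatures(df)
  p1 <- findOperonPairs(feats, "m", "n")
  p2 <- findOperonPairs(feats, "n", "m")
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$gap_bp, p2$gap_bp)
})
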