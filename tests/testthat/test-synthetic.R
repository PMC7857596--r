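test_that("family seeds are deterministic with documented site geometry", {
  fs <- fixtureSeeds()
  fs2 <- familySeeds()
  expect_identical(as.character(fs$seeds), as.character(fs2$seeds))
  # core synthase seeds respect the 386-residue bound; MetE is full length
  core <- c("MesA", "MesB", "MesC", "MesD")
  expect_true(all(fs$lengths[core] <= 386))
  expect_gte(fs$lengths[["MetE"]], 676)
  # canonical residues at the recorded positions
  for (fam in c("MetE", core)) {
    s <- as.character(fs$seeds[[fam]])
    z <- fs$sites[[fam]]$zinc
    expect_equal(paste(substring(s, z, z), collapse = ""), "HCEC")
  }
})

test_that("inter-family seed identities stay below 30% (global)", {
  fs <- fixtureSeeds()
  core <- c("MesA", "MesB", "MesC", "MesD")
  for (pair in combn(core, 2, simplify = FALSE)) {
    pid <- globalPercentIdentity(fs$seeds[pair[1]], fs$seeds[pair[2]])
    expect_lt(pid, 30)
  }
})

test_that("member generation hits its identity target within 3 points", {
  fs <- fixtureSeeds()
  pids <- vapply(1:50, function(i)
    percentIdentity(alignLocal(
      generateFamilyMember(fs$seeds["MesB"], 0.4, "intact",
                           fs$sites$MesB, seed = 7000 + i),
      fs$seeds["MesB"]), rounded = FALSE), numeric(1))
  expect_true(all(abs(pids - 40) <= 3))
  # target 1.0, intact: seed returned unchanged
  expect_equal(generateFamilyMember(fs$seeds["MesB"], 1.0, "intact",
                                    fs$sites$MesB, seed = 1),
               as.character(fs$seeds[["MesB"]]))
})

test_that("broken members classify broken; unreachable identities error", {
  fs <- fixtureSeeds()
  for (i in 1:5) {
    m <- generateFamilyMember(fs$seeds["MesC"], 0.6, "broken",
                              fs$sites$MesC, seed = i)
    z <- fs$sites$MesC$zinc
    obs <- substring(m, z, z)
    expect_equal(classifyZincSite(obs)$overall, "broken")
  }
  expect_error(
    generateFamilyMember("HECA", 0.25, "intact",
                         list(zinc = c(1L, 2L, 3L, 4L)), seed = 1),
    "unreachable")
})

test_that("generated genomes are reproducible and internally consistent", {
  fs <- fixtureSeeds()
  g1 <- generateGenome("gg", c(MesB = 1, AcsC = 1, AcsD = 1),
                       operons = list(c("MesB", "AcsC", "AcsD")),
                       decoys = 3, seed = 77, seedSet = fs)
  g2 <- generateGenome("gg", c(MesB = 1, AcsC = 1, AcsD = 1),
                       operons = list(c("MesB", "AcsC", "AcsD")),
                       decoys = 3, seed = 77, seedSet = fs)
  expect_identical(as.character(g1$proteins), as.character(g2$proteins))
  expect_identical(g1$truth, g2$truth)
  # ids consistent between proteome, features, and truth
  expect_setequal(names(g1$proteins),
                  S4Vectors::mcols(g1$features)$gene_id)
  expect_setequal(names(g1$proteins), g1$truth$protein_id)
  expect_equal(anyDuplicated(names(g1$proteins)), 0L)
})

test_that("constructed operons are recovered by adjacency detection", {
  fs <- fixtureSeeds()
  g <- generateGenome("go", c(MesB = 1, AcsC = 1, AcsD = 1),
                      operons = list(c("MesB", "AcsC", "AcsD")),
                      seed = 78, seedSet = fs)
  mesb <- g$truth$protein_id[g$truth$family == "MesB"]
  acs <- g$truth$protein_id[g$truth$family %in% c("AcsC", "AcsD")]
  pairs <- findOperonPairs(g$features, mesb, acs)
  expect_gte(nrow(pairs), 1L)
  expect_true(mesb %in% c(pairs$gene_a, pairs$gene_b))
})

test_that("empty genome specs yield empty outputs", {
  fs <- fixtureSeeds()
  g <- generateGenome("gz", c(), seed = 79, seedSet = fs)
  expect_equal(length(g$proteins), 0L)
  expect_equal(nrow(g$truth), 0L)
})

test_that("decoy-only genomes yield no synthase calls at published
          thresholds", {
  fs <- fixtureSeeds()
  sch <- fixtureScheme()
  paper <- paperThresholds()
  refs <- list(
    MesA = familyReference("MesA", fs$seeds["MesA"], paper[["MesA"]]),
    MesB = familyReference("MesB", fs$seeds["MesB"], paper[["MesB"]]),
    MesC = familyReference("MesC", fs$seeds["MesC"], paper[["MesC"]]),
    MesD = familyReference("MesD", fs$seeds["MesD"], paper[["MesD"]]))
  clean <- vapply(1:20, function(i) {
    g <- generateGenome(sprintf("gd%02d", i), c(), decoys = 20,
                        seed = 900 + i, seedSet = fs)
    calls <- classifyProteins(g$proteins, refs, sch)
    nrow(calls) == 0 || all(is.na(calls$family))
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("barseq generation is seeded and neutral in expectation", {
  truth <- setNames(rep(0, 10), paste0("n", 1:10))
  b1 <- generateBarseq(truth, 10, 1e5, seed = 5)
  b2 <- generateBarseq(truth, 10, 1e5, seed = 5)
  expect_identical(b1$counts, b2$counts)
  # neutral: total after within a few percent of total before
  expect_lt(abs(sum(b1$counts$after) - sum(b1$counts$before)) /
              sum(b1$counts$before), 0.05)
  # strongly deleterious genes collapse
  b3 <- generateBarseq(setNames(c(0, -5), c("a", "b")), 20, 1e5, seed = 6)
  byGene <- tapply(b3$counts$after, b3$counts$gene_id, sum)
  expect_lt(byGene[["b"]], byGene[["a"]] / 10)
})
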