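test_that("a protein above one family threshold is assigned that family", {
  fs <- fixtureSeeds()
  refs <- fixtureRefs()
  m <- generateFamilyMember(fs$seeds["MesA"], 0.7, "intact",
                            fs$sites$MesA, seed = 3)
  call <- assignFamily(Biostrings::AAStringSet(c(p1 = m)), refs)
  expect_equal(call$family, "MesA")
  expect_false(call$non_enzymatic)
  expect_gte(call$bits, familyThreshold(refs$MesA))
})

test_that("multi-family hits are disambiguated by identity to the query", {
  fs <- fixtureSeeds()
  # two references over the same two seeds, thresholds low enough that a
  # MesA-like protein hits both; identity must decide
  refs <- list(
    MesA = familyReference("MesA", fs$seeds["MesA"], threshold = 30),
    MesC = familyReference("MesC", fs$seeds["MesC"], threshold = 30))
  m <- generateFamilyMember(fs$seeds["MesA"], 0.55, "intact",
                            fs$sites$MesA, seed = 4)
  call <- assignFamily(Biostrings::AAStringSet(c(p1 = m)), refs)
  expect_equal(call$family, "MesA")
  expect_true(call$disambiguated)
})

test_that("broken zinc sites demote calls to non-enzymatic homologs", {
  fs <- fixtureSeeds()
  refs <- fixtureRefs()
  m <- generateFamilyMember(fs$seeds["MesB"], 0.7, "broken",
                            fs$sites$MesB, seed = 5)
  call <- assignFamily(Biostrings::AAStringSet(c(p1 = m)), refs)
  expect_equal(call$family, "MesB")
  expect_true(call$non_enzymatic)
})

test_that("raising a threshold never adds calls (monotone)", {
  fs <- fixtureSeeds()
  sch <- fixtureScheme()
  set.seed(51)
  prots <- Biostrings::AAStringSet(setNames(
    c(vapply(1:4, function(i)
        generateFamilyMember(fs$seeds["MesB"], runif(1, 0.4, 0.9), "intact",
                             fs$sites$MesB, seed = 100 + i), character(1)),
      vapply(1:4, function(i) randomSeq(300), character(1))),
    paste0("p", 1:8)))
  ref <- fixtureRefs()$MesB
  nCalls <- function(th) {
    r <- ref; r@threshold <- th
    sum(!is.na(classifyProteins(prots, list(MesB = r), sch)$family))
  }
  counts <- vapply(c(50, 150, 250, 350, 500), nCalls, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("split-MetE candidate rules match an exhaustive rule-table oracle", {
  set.seed(52)
  n <- 1000
  bits <- runif(n, 0, 400)
  len <- sample(100:800, n, replace = TRUE)
  nScore <- runif(n, 0, 300)
  cScore <- runif(n, 0, 300)
  nCut <- 120; cCut <- 110
  # independent restatement of the published rules, case by case
  oracleCat <- logical(n); oracleFol <- logical(n)
  for (i in seq_len(n)) {
    oracleCat[i] <- (bits[i] >= 200) && (len[i] <= 400)
    folOk <- (nScore[i] >= nCut) && (len[i] <= 400)
    if (folOk && cScore[i] >= cCut) {
      # matches the catalytic domain too: N-domain must score strictly higher
      folOk <- nScore[i] > cScore[i]
    }
    oracleFol[i] <- folOk
  }
  expect_equal(splitCatCandidate(bits, len), oracleCat)
  expect_equal(splitFolateCandidate(nScore, cScore, len, nCut, cCut),
               oracleFol)
})

test_that("split-MetE detection finds both components and adjacency", {
  fs <- fixtureSeeds()
  refs <- fixtureRefs()
  profs <- fixtureProfiles()
  g <- generateGenome("gs", c(SplitMetE_cat = 1, SplitMetE_N = 1, MesB = 1),
                      operons = list(c("SplitMetE_cat", "SplitMetE_N")),
                      decoys = 4, seed = 13, seedSet = fs)
  sp <- detectSplitMetE(g$proteins, refs$SplitMetE_cat, profs$SplitMetE_N,
                        profs$SplitMetE_cat, features = g$features)
  expect_true(sp$present)
  expect_true(sp$adjacent)
  expect_equal(sp$catalytic_id,
               g$truth$protein_id[g$truth$family == "SplitMetE_cat"])
  expect_equal(sp$folate_id,
               g$truth$protein_id[g$truth$family == "SplitMetE_N"])
})

test_that("split-MetE absence is reported, not an error", {
  fs <- fixtureSeeds()
  refs <- fixtureRefs()
  profs <- fixtureProfiles()
  g <- generateGenome("ge", c(MesA = 1), decoys = 3, seed = 14, seedSet = fs)
  sp <- detectSplitMetE(g$proteins, refs$SplitMetE_cat, profs$SplitMetE_N,
                        profs$SplitMetE_cat)
  expect_false(sp$present)
  expect_true(is.na(sp$folate_id))
})

test_that("an over-length catalytic candidate is rejected", {
  fs <- fixtureSeeds()
  refs <- fixtureRefs()
  profs <- fixtureProfiles()
  # the full MetE scaffold scores well against the catalytic query but is
  # 753 aa, far over the 400-residue limit
  prots <- fs$seeds["MetE"]
  S4Vectors::mcols(prots)$genome_id <- "gl"
  sp <- detectSplitMetE(prots, refs$SplitMetE_cat, profs$SplitMetE_N,
                        profs$SplitMetE_cat)
  expect_true(is.na(sp$catalytic_id))
})

test_that("MetH calls require high query coverage", {
  fs <- fixtureSeeds()
  sch <- fixtureScheme()
  ref <- familyReference("MetH", fs$seeds["MetH"], threshold = 50)
  # identical protein: coverage 100%
  expect_true(callMetH(fs$seeds["MetH"], ref, scheme = sch))
  # strong hit covering only half the query: rejected
  half <- substr(as.character(fs$seeds[["MetH"]]), 1, 400)
  expect_false(callMetH(half, ref, scheme = sch))
})

test_that("partial-domain MetF homologs are reported as MetF-like", {
  fs <- fixtureSeeds()
  sch <- fixtureScheme()
  ref <- familyReference("MetF", fs$seeds["MetF"], threshold = 50)
  expect_equal(callMetF(fs$seeds["MetF"], ref, scheme = sch), "MetF")
  cTerm <- substr(as.character(fs$seeds[["MetF"]]), 130, 290)
  expect_equal(callMetF(cTerm, ref, scheme = sch), "MetF-like_partial")
  expect_equal(callMetF(randomSeq(250), ref, scheme = sch), "none")
})
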