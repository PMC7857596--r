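test_that("identity mapping when candidate equals the reference", {
  set.seed(41)
  ref <- randomSeq(200)
  chars <- strsplit(ref, "")[[1]]
  chars[c(100, 102, 140, 180)] <- c("H", "C", "E", "C")
  chars[c(20, 50, 80)] <- c("S", "E", "D")
  ref <- paste(chars, collapse = "")
  sites <- referenceSites("ref", zincPos = c(100, 102, 140, 180),
                          substratePos = c(20, 50, 80))
  sm <- mapReferenceSites(ref, sites, ref)
  expect_equal(sm$cand_pos, sm$ref_pos)
  expect_equal(sm$observed, sm$ref_res)
})

test_that("an N-terminal extension shifts every mapped position", {
  set.seed(42)
  chars <- strsplit(randomSeq(150), "")[[1]]
  chars[c(60, 62, 90, 120)] <- c("H", "C", "E", "C")
  chars[c(10, 25, 40)] <- c("S", "E", "D")
  ref <- paste(chars, collapse = "")
  sites <- referenceSites("ref", zincPos = c(60, 62, 90, 120),
                          substratePos = c(10, 25, 40))
  cand <- paste0(randomSeq(10), ref)
  sm <- mapReferenceSites(ref, sites, cand)
  expect_equal(sm$cand_pos, sm$ref_pos + 10L)
})

test_that("site positions beyond the reference are rejected", {
  expect_error(
    mapReferenceSites("ACDE", referenceSites("r", zincPos = c(1, 2, 3, 10),
                                             substratePos = c(1, 2, 3)),
                      "ACDE"),
    "beyond")
})

test_that("zinc verdicts encode the known compatibility rules", {
  expect_equal(classifyZincSite(c("H", "C", "E", "C"))$overall, "intact")
  # aspartate for Glu665, as in the characterized MesB
  expect_equal(classifyZincSite(c("H", "C", "D", "C"))$overall, "compatible")
  # histidine or tyrosine for Cys643 (MesC), asparagine for Cys726 (MesB)
  expect_equal(classifyZincSite(c("H", "H", "E", "C"))$overall, "compatible")
  expect_equal(classifyZincSite(c("H", "Y", "E", "C"))$overall, "compatible")
  expect_equal(classifyZincSite(c("H", "C", "E", "N"))$overall, "compatible")
  # the non-enzymatic Chloroflexales patterns
  for (pat in c("FSHG", "YCDQ", "YREQ"))
    expect_equal(classifyZincSite(strsplit(pat, "")[[1]])$overall, "broken")
  # glycine aligning to Glu665 is not compatible
  expect_equal(classifyZincSite(c("H", "C", "G", "C"))$overall, "broken")
  # unaligned position breaks the verdict
  expect_equal(classifyZincSite(c("H", "C", NA, "C"))$overall, "broken")
})

test_that("verdicts are monotone: breaking a site never improves them", {
  rank <- c(intact = 3, compatible = 2, broken = 1)
  good <- c("H", "C", "E", "C")
  for (i in 1:4) {
    worse <- good; worse[i] <- "W"
    expect_lt(rank[classifyZincSite(worse)$overall],
              rank[classifyZincSite(good)$overall])
  }
})

test_that("column information matches entropy closed forms", {
  expect_equal(columnInformation(rep("C", 8)), log2(20), tolerance = 1e-12)
  expect_equal(columnInformation(MesFinder:::AA20), 0, tolerance = 1e-12)
  expect_equal(columnInformation(c("A", "A", "C", "C")), log2(20) - 1,
               tolerance = 1e-12)
  # gaps are excluded from the counts
  expect_equal(columnInformation(c("C", "C", "-", "-")), log2(20),
               tolerance = 1e-12)
  expect_error(columnInformation(c("-", "-")), "all-gap")
})

test_that("information content is bounded for random columns", {
  set.seed(43)
  for (i in 1:30) {
    col <- sample(MesFinder:::AA20, sample(2:30, 1), replace = TRUE)
    ic <- columnInformation(col)
    expect_gte(ic, 0)
    expect_lte(ic, log2(20))
  }
})

test_that("logo data reports per-residue heights summing to the column IC", {
  msa <- c(a = "AC", b = "AC", c = "AG")
  ld <- logoData(msa)
  expect_equal(ld$information[1], log2(20), tolerance = 1e-12)
  hcols <- grep("^h_", names(ld))
  expect_equal(sum(ld[2, hcols]), ld$information[2], tolerance = 1e-12)
})

test_that("site mapping recovers positions on synthetic family members", {
  fs <- fixtureSeeds()
  sm <- mapReferenceSites(fs$seeds["MetE"], referenceSites(), fs$seeds["MesB"])
  expect_equal(sm$cand_pos[sm$site == "zinc"], c(214L, 216L, 235L, 311L))
  m <- generateFamilyMember(fs$seeds["MesB"], 0.7, "intact",
                            fs$sites$MesB, seed = 9)
  sitesB <- referenceSites("MesB", zincPos = fs$sites$MesB$zinc,
                           substratePos = fs$sites$MesB$substrate)
  sm2 <- mapReferenceSites(fs$seeds["MesB"], sitesB, m)
  expect_equal(paste(sm2$observed[sm2$site == "zinc"], collapse = ""),
               "HCEC")
})
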