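test_that("profile columns score as log-odds with limit cases", {
  # all-C column, no pseudocount: C scores log2(1/bg_C) > 0, others floored
  msa <- c(a = "C", b = "C", c = "C")
  p <- buildProfile(msa, pseudocount = 0, name = "allC")
  bg <- MesFinder:::AA_BACKGROUND
  bgC <- bg[["C"]] / sum(bg)
  expect_equal(unname(p@scores[1, "C"]), unname(log2(1 / bgC)),
               tolerance = 1e-9)
  expect_true(all(p@scores[1, setdiff(MesFinder:::AA20, "C")] == -10))

  # uniform column over all 20 residues with uniform background: all zero
  msa20 <- setNames(MesFinder:::AA20, paste0("s", 1:20))
  pu <- buildProfile(msa20, pseudocount = 0, name = "uniform",
                     background = setNames(rep(1 / 20, 20),
                                           MesFinder:::AA20))
  expect_true(all(abs(pu@scores[1, MesFinder:::AA20]) < 1e-12))
})

test_that("mostly-gapped columns are dropped and tiny alignments error", {
  msa <- c(a = "AC", b = "A-", c = "A-")
  p <- buildProfile(msa, name = "gappy")
  expect_equal(nrow(p@scores), 1L)  # column 2 has 2/3 gaps
  expect_error(buildProfile(c(a = "ACDE")), "at least 2")
})

test_that("training sequences outscore shuffled versions", {
  set.seed(31)
  base <- randomSeq(60)
  train <- vapply(1:4, function(i)
    generateFamilyMember(base, 0.8, "none", seed = i), character(1))
  names(train) <- paste0("t", 1:4)
  aln <- progressiveAlign(train)
  p <- buildProfile(aln, name = "fam")
  own <- scoreProfile(p, train[1])
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(train[[1]], "")[[1]]), collapse = "")
    expect_gte(own, scoreProfile(p, shuf))
  }
})

test_that("profile scoring is local: flanks never change the best window", {
  set.seed(32)
  base <- randomSeq(40)
  train <- setNames(vapply(1:3, function(i)
    generateFamilyMember(base, 0.85, "none", seed = i), character(1)),
    paste0("t", 1:3))
  p <- buildProfile(progressiveAlign(train), name = "fam")
  sc <- scoreProfile(p, base)
  expect_equal(scoreProfile(p, paste0("WWWWW", base, "HHHHH")), sc)
  # length-1 sequence scores the best single-column score
  expect_equal(scoreProfile(p, "C"), max(0, max(p@scores[, "C"])))
})

test_that("all training members clear a min-score cutoff; matched-composition
          random sequences rarely do", {
  set.seed(33)
  base <- randomSeq(80)
  train <- setNames(vapply(1:5, function(i)
    generateFamilyMember(base, 0.7, "none", seed = i), character(1)),
    paste0("t", 1:5))
  p <- buildProfile(progressiveAlign(train), name = "fam")
  trainScores <- vapply(train, function(s) scoreProfile(p, s), numeric(1))
  cutoff <- min(trainScores)
  expect_true(all(trainScores >= cutoff))
  chars <- strsplit(base, "")[[1]]
  below <- vapply(1:200, function(i)
    scoreProfile(p, paste(sample(chars), collapse = "")) < cutoff,
    logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("profiles round-trip through the TSV serialization", {
  set.seed(34)
  base <- randomSeq(30)
  train <- setNames(vapply(1:3, function(i)
    generateFamilyMember(base, 0.8, "none", seed = i), character(1)),
    paste0("t", 1:3))
  p <- buildProfile(progressiveAlign(train), name = "roundtrip")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(p, tf)
  p2 <- readProfile(tf)
  expect_equal(p2@name, p@name)
  expect_equal(p2@cutoff, p@cutoff, tolerance = 1e-4)
  expect_equal(unname(p2@scores), unname(p@scores), tolerance = 1e-4)
  expect_equal(scoreProfile(p2, base), scoreProfile(p, base),
               tolerance = 1e-3)
})
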