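test_that("self-alignment scores the BLOSUM62 diagonal sum", {
  aln <- alignLocal("ACDE", "ACDE")
  expect_equal(rawScore(aln), 24)  # 4 + 9 + 6 + 5
  expect_equal(percentIdentity(aln), 100)
  expect_equal(aln@queryStart, 1L)
  expect_equal(aln@queryEnd, 4L)
})

test_that("no positive-scoring pair yields an empty zero-score alignment", {
  aln <- alignLocal("ACDE", "WWWW")
  expect_equal(rawScore(aln), 0)
  expect_equal(aln@alignedColumns, 0L)
  expect_error(percentIdentity(aln), "empty")
})

test_that("bit conversion follows the Karlin-Altschul formula", {
  sch <- blosum62Scheme()
  expect_equal(toBits(24, sch), (0.267 * 24 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(toBits(24, sch), 2), 13.85)
  # algebraic zero: lambda * raw = ln K
  raw0 <- log(sch@K) / sch@lambda
  expect_equal(toBits(raw0, sch), 0, tolerance = 1e-12)
  # monotone in raw score
  expect_true(all(diff(toBits(c(0, 10, 100, 500), sch)) > 0))
})

test_that("percent identity follows the pident convention", {
  expect_equal(percentIdentity(alignLocal("ACDE", "ACDD")), 75)
  expect_equal(percentIdentity(alignLocal("ACDE", "ACDD"), rounded = FALSE),
               75)
})

test_that("SW scores equal the independent DP oracle on random pairs", {
  sch <- fixtureScheme()
  set.seed(402)
  for (i in 1:200) {
    a <- randomSeq(sample(2:8, 1))
    b <- randomSeq(sample(2:8, 1))
    expect_equal(rawScore(alignLocal(a, b, sch)),
                 swOracleScore(a, b, sch@matrix),
                 info = paste(a, b))
  }
})

test_that("the DP oracle itself matches exhaustive enumeration on tiny pairs", {
  sch <- fixtureScheme()
  set.seed(403)
  for (i in 1:15) {
    a <- randomSeq(sample(2:4, 1))
    b <- randomSeq(sample(2:4, 1))
    expect_equal(swOracleScore(a, b, sch@matrix),
                 swEnumScore(a, b, sch@matrix), info = paste(a, b))
  }
})

test_that("alignment properties: symmetry, identity bound, column map", {
  sch <- fixtureScheme()
  set.seed(404)
  for (i in 1:25) {
    a <- randomSeq(sample(5:40, 1))
    b <- randomSeq(sample(5:40, 1))
    f <- alignLocal(a, b, sch)
    r <- alignLocal(b, a, sch)
    expect_equal(rawScore(f), rawScore(r))
    if (f@alignedColumns > 0) {
      expect_lte(percentIdentity(f), 100)
      cm <- columnMap(f)
      q <- cm[, "query"][!is.na(cm[, "query"])]
      s <- cm[, "subject"][!is.na(cm[, "subject"])]
      expect_true(all(diff(q) > 0))
      expect_true(all(diff(s) > 0))
      # column map reads back the aligned residues
      expect_equal(max(q), f@queryEnd)
      expect_equal(min(s), f@subjectStart)
    }
  }
})

test_that("appending a strongly matching residue never lowers the score", {
  sch <- fixtureScheme()
  set.seed(405)
  for (i in 1:20) {
    a <- randomSeq(10)
    b <- randomSeq(10)
    base <- rawScore(alignLocal(a, b, sch))
    expect_gte(rawScore(alignLocal(paste0(a, "W"), paste0(b, "W"), sch)),
               base)
  }
})

test_that("X scores zero against everything", {
  sch <- fixtureScheme()
  expect_true(all(sch@matrix["X", ] == 0))
  expect_true(all(sch@matrix[, "X"] == 0))
})

test_that("NCBI matrix files round-trip through the reader", {
  sch <- fixtureScheme()
  tf <- withr::local_tempfile(fileext = ".txt")
  m <- sch@matrix
  lines <- c("# test matrix", paste(" ", paste(colnames(m), collapse = " ")),
             vapply(rownames(m), function(r)
               paste(r, paste(m[r, ], collapse = " ")), character(1)))
  writeLines(lines, tf)
  m2 <- readScoringMatrix(tf)
  expect_equal(m2[rownames(m), colnames(m)], m)
})

test_that("searchProteome agrees with alignLocal scores", {
  sch <- fixtureScheme()
  set.seed(406)
  prots <- Biostrings::AAStringSet(setNames(
    vapply(1:5, function(i) randomSeq(30), character(1)), paste0("p", 1:5)))
  q <- randomSeq(25)
  res <- searchProteome(q, prots, sch)
  for (i in 1:5)
    expect_equal(res$raw[i], rawScore(alignLocal(q, prots[i], sch)))
})
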