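test_that("profile construction follows the match-column and pseudocount rules", {
  rows <- c(r1 = "ACDEF", r2 = "ACDEF", r3 = "ACDEF", r4 = "ACDEF")
  p <- buildProfile(SeedAlignment(rows))
  expect_equal(profileLength(p), 5L)

  # a column that is gap in 3 of 4 rows (75% >= 50%) becomes an insert column
  rows2 <- c(r1 = "AC-EF", r2 = "AC-EF", r3 = "ACDEF", r4 = "AC-EF")
  expect_equal(profileLength(buildProfile(SeedAlignment(rows2))), 4L)
  # exactly 50% gaps is also an insert column
  rows3 <- c(r1 = "A-F", r2 = "ACF", r3 = "A-F", r4 = "ACF")
  expect_equal(profileLength(buildProfile(SeedAlignment(rows3))), 2L)

  # emission smoothing: column of 4 x A
  q <- aaBackground()
  em <- matchEmissions(buildProfile(SeedAlignment(rows)))
  expect_equal(unname(em[1, "A"]), (4 + q[["A"]]) / 5)
  expect_true(all(em[1, "A"] > em[1, setdiff(colnames(em), "A")]))
  expect_equal(rowSums(em), rep(1, 5), tolerance = 1e-12)

  expect_error(buildProfile(SeedAlignment(c(r1 = "-", r2 = "-"))),
               "no match columns")
  expect_error(buildProfile(SeedAlignment(c(r1 = "ACD"))), ">= 2 rows")
})

test_that("a background-emission profile scores zero bits in glocal mode", {
  q <- aaBackground()
  em <- matrix(rep(q, each = 4), 4, 20)
  p <- makeProfileHMM(em, bg = q)  # no-indel chain
  set.seed(2)
  for (k in 1:5)
    expect_equal(forwardScore(p, randomAASeq(4), "glocal"), 0,
                 tolerance = 1e-12)
})

test_that("forward and Viterbi equal path enumeration on small models", {
  set.seed(17)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  for (k in 1:30) {
    p <- randomProfile(sample(1:3, 1))
    s <- paste(sample(aa, sample(1:4, 1), replace = TRUE), collapse = "")
    for (mode in c("glocal", "local")) {
      o <- oraclePHMM(p, s, mode)
      expect_equal(forwardScore(p, s, mode), o$forward, tolerance = 1e-9,
                   info = paste(mode, s))
      expect_equal(viterbiAlign(p, s, mode)$bits, o$viterbi,
                   tolerance = 1e-9, info = paste(mode, s))
    }
  }
})

test_that("forward dominates Viterbi and envelopes are well-formed", {
  set.seed(29)
  for (k in 1:20) {
    p <- randomProfile(sample(2:6, 1))
    s <- randomAASeq(sample(3:12, 1))
    f <- forwardScore(p, s)
    v <- viterbiAlign(p, s)
    expect_gte(f + 1e-9, v$bits)
    if (is.finite(v$bits)) {
      expect_lte(v$envStart, v$envEnd)
      expect_gte(v$envStart, 1L)
      expect_lte(v$envEnd, nchar(s))
    }
  }
})

test_that("a sharply peaked profile aligns its consensus as all-match", {
  rows <- rep(c(r1 = "MKWVFDE"), 4)
  names(rows) <- paste0("r", 1:4)
  p <- buildProfile(SeedAlignment(rows))
  v <- viterbiAlign(p, "MKWVFDE", "glocal")
  expect_true(all(v$path$state == "M"))
  expect_equal(v$envStart, 1L)
  expect_equal(v$envEnd, 7L)
})

test_that("calibration is deterministic and rejects degenerate nulls", {
  rows <- vapply(1:4, function(i) randomAASeq(30), "")
  names(rows) <- paste0("r", 1:4)
  p <- buildProfile(SeedAlignment(rows))
  c1 <- calibrateProfile(p, nNull = 200L, lenDist = 50:150, seed = 9L)
  c2 <- calibrateProfile(p, nNull = 200L, lenDist = 50:150, seed = 9L)
  expect_identical(c(c1@mu, c1@lambda), c(c2@mu, c2@lambda))
  expect_gt(c1@lambda, 0)
  expect_error(calibrateProfile(p, nNull = 50L), "nNull")

  # background-emission profile scores depend on length only -> with a single
  # null length the score distribution is degenerate
  q <- aaBackground()
  flat <- makeProfileHMM(matrix(rep(q, each = 3), 3, 20), bg = q)
  expect_error(calibrateProfile(flat, nNull = 150L, lenDist = 80L),
               "degenerate")
})

test_that("e-values are monotone in score and linear in database size", {
  cal <- methods::new("EvalueCalibration", profileId = "p", mu = 5,
                      lambda = 1.2, nNull = 1000L, seed = 1L)
  s <- seq(-10, 30, by = 0.5)
  ev <- hitEvalue(s, cal, 100L)
  expect_true(all(diff(ev) <= 0))            # weakly monotone everywhere
  sMid <- seq(3, 25, by = 0.5)               # strictly, away from saturation
  expect_true(all(diff(hitEvalue(sMid, cal, 100L)) < 0))
  expect_equal(hitEvalue(8, cal, 200L), 2 * hitEvalue(8, cal, 100L))
  expect_equal(hitEvalue(-1e6, cal, 50L), 50, tolerance = 1e-9)
  # p-value monotone decreasing in score
  expect_true(all(diff(gumbelPvalue(sMid, cal)) < 0))
})

test_that("proteome scanning finds a planted consensus and thresholds hits", {
  set.seed(41)
  rows <- rep(c(r1 = randomAASeq(40)), 4)
  rows[2:4] <- vapply(2:4, function(i) {
    v <- strsplit(rows[1], "")[[1]]
    mut <- sample(40, 6)
    v[mut] <- sample(names(aaBackground()), 6, replace = TRUE)
    paste(v, collapse = "")
  }, "")
  names(rows) <- paste0("r", 1:4)
  p <- buildProfile(SeedAlignment(rows))
  decoys <- vapply(1:100, function(i) randomAASeq(sample(60:150, 1)), "")
  names(decoys) <- sprintf("d%03d", 1:100)
  planted <- paste0(randomAASeq(20), rows[[1]], randomAASeq(25))
  prot <- Proteome("t", c(decoys, planted = planted))
  cal <- calibrateProfile(p, nNull = 500L, lenDist = 60:150, seed = 2L)
  hits <- scanProteome(p, prot, cal, threshold = 0.01)
  expect_equal(hits$id[1], "planted")
  expect_true(all(hits$evalue <= 0.01))
  expect_gte(hits$envStart[1], 15L)
  expect_lte(hits$envEnd[1], 65L)

  empty <- scanProteome(p, Proteome("e", character()), cal)
  expect_equal(nrow(empty), 0L)
})

test_that("domain annotation orders, repeats and resolves overlaps", {
  set.seed(55)
  mkProfile <- function(block) {
    rows <- vapply(1:4, function(i) {
      v <- strsplit(block, "")[[1]]
      mut <- sample(length(v), 3)
      v[mut] <- sample(names(aaBackground()), 3, replace = TRUE)
      paste(v, collapse = "")
    }, "")
    names(rows) <- paste0("r", 1:4)
    buildProfile(SeedAlignment(rows))
  }
  blockA <- randomAASeq(40); blockB <- randomAASeq(40)
  pA <- mkProfile(blockA); pA@id <- "A"
  pB <- mkProfile(blockB); pB@id <- "B"
  profs <- list(A = pA, B = pB)
  cals <- lapply(profs, calibrateProfile, nNull = 400L, lenDist = 100:250,
                 seed = 4L)

  seq1 <- paste0(randomAASeq(10), blockA, randomAASeq(15), blockB,
                 randomAASeq(20))
  arch <- annotateDomains(seq1, profs, cals)
  expect_equal(arch$domain, c("A", "B"))
  expect_true(all(diff(arch$start) > 0))

  # tandem repeat: two copies of A recovered despite single-hit scoring
  seq2 <- paste0(randomAASeq(8), blockA, randomAASeq(12), blockA,
                 randomAASeq(10))
  arch2 <- annotateDomains(seq2, profs, cals)
  expect_equal(arch2$domain, c("A", "A"))

  # nothing above threshold -> empty architecture
  arch3 <- annotateDomains(randomAASeq(120), profs, cals)
  expect_equal(nrow(arch3), 0L)

  # overlapping hits: the better e-value survives
  df <- data.frame(domain = c("A", "B"), start = c(10L, 30L),
                   end = c(60L, 80L), evalue = c(1e-8, 1e-3))
  # emulate via the exported resolution path: both profiles hit the same
  # region of a sequence built from blockA only
  arch4 <- annotateDomains(paste0(randomAASeq(10), blockA, randomAASeq(10)),
                           profs, cals)
  expect_equal(arch4$domain, "A")
})
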