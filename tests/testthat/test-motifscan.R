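test_that("built-in patterns carry the canonical expressions and policies", {
  reg <- motifRegistry()
  expect_equal(reg$AP2$pattern, "DP[WF]|F.D.F|WV.F|F.F.[FL]")
  expect_equal(reg$clathrin$pattern,
               "L[FILMV].[FILMV][DE]|L[FILMV].[DE][FILMV]")
  expect_equal(reg$EH$pattern, "NPF")
  expect_true(all(vapply(reg, function(p) p$policy, "") == "C_tail"))
  expect_error(motifPattern("bad", "(unclosed"), "compile")
})

test_that("tail extraction respects the region policy", {
  s <- randomAASeq(80)
  arch <- data.frame(domain = "D", start = 10L, end = 50L,
                     evalue = 1e-9)
  ct <- extractTail(s, arch, "C_tail")
  expect_equal(c(ct$start, ct$end), c(51L, 80L))
  expect_equal(ct$seq, substr(s, 51, 80))
  nt <- extractTail(s, arch, "N_tail")
  expect_equal(c(nt$start, nt$end), c(1L, 9L))
  none <- extractTail(s, arch[0, ], "C_tail")
  expect_equal(c(none$start, none$end), c(1L, 80L))
  # zero-length tail
  arch2 <- data.frame(domain = "D", start = 1L, end = 80L, evalue = 1e-9)
  expect_equal(extractTail(s, arch2, "C_tail")$seq, "")
  # tails and domains partition the sequence
  expect_true(ct$start > max(arch$end))
  expect_true(nt$end < min(arch$start))
})

test_that("motif scanning matches hand-evaluated cases", {
  reg <- motifRegistry()
  r1 <- scanMotif("GSDPWKL", reg$AP2)
  expect_equal(r1$count, 1L)
  expect_equal(r1$positions, 3L)
  r2 <- scanMotif("LIDLE", reg$clathrin)   # L[FILMV].[DE][FILMV] at 1
  expect_equal(r2$count, 1L)
  expect_equal(r2$positions, 1L)
  expect_equal(scanMotif("", reg$AP2)$count, 0L)
  # overlapping matches all counted; one position matching two alternatives
  # counts once
  r3 <- scanMotif("FADAFADAF", reg$AP2)    # F.D.F at 1 and 5
  expect_equal(r3$positions, c(1L, 5L))
  r4 <- scanMotif("NPFNPF", reg$EH)
  expect_equal(r4$count, 2L)
})

test_that("motif scanning equals the exhaustive per-position oracle", {
  set.seed(77)
  reg <- motifRegistry()
  for (pat in reg) {
    for (k in 1:150) {
      s <- randomAASeq(sample(10:60, 1))
      expect_equal(scanMotif(s, pat)$count,
                   oracleMotifCount(s, pat$pattern), info = s)
    }
  }
})

test_that("occurrence statistics follow the per-taxon formulas", {
  counts <- list(o1 = 1L, o2 = c(2L, 0L), o3 = 4L, o4 = 0L)
  st <- motifOccurrence(counts, c("o1", "o2", "o3", "o4"))
  expect_equal(st$occurrence, 0.75)
  expect_equal(st$medianCount, 2)        # median of {1, 2, 4}
  expect_equal(st$nTotal, 4L)

  # organisms lacking the family count in the denominator...
  st2 <- motifOccurrence(list(o1 = 1L), c("o1", "o2"))
  expect_equal(st2$occurrence, 0.5)
  # ...unless restricted to possessors
  st3 <- motifOccurrence(list(o1 = 1L), c("o1", "o2"),
                         possessorsOnly = TRUE)
  expect_equal(st3$occurrence, 1)

  st4 <- motifOccurrence(list(o1 = 0L), c("o1", "o2"))
  expect_equal(st4$occurrence, 0)
  expect_true(is.na(st4$medianCount))

  expect_error(motifOccurrence(counts, character()), "empty taxon group")
  # bounds hold on random inputs
  set.seed(3)
  for (k in 1:20) {
    cnt <- lapply(1:5, function(i) sample(0:4, sample(0:3, 1), replace = TRUE))
    names(cnt) <- paste0("x", 1:5)
    st <- motifOccurrence(cnt, paste0("x", 1:5))
    expect_gte(st$occurrence, 0); expect_lte(st$occurrence, 1)
    if (!is.na(st$medianCount)) expect_gte(st$medianCount, 1)
  }
})

test_that("activator-region search separates planted consensus from nulls", {
  fx <- miniFixture()
  set.seed(61)
  rows <- rep(c(r1 = randomAASeq(25)), 3)
  rows[2:3] <- vapply(2:3, function(i) {
    v <- strsplit(rows[1], "")[[1]]
    mut <- sample(25, 3)
    v[mut] <- sample(names(aaBackground()), 3, replace = TRUE)
    paste(v, collapse = "")
  }, "")
  names(rows) <- paste0("r", 1:3)
  apa <- buildProfile(SeedAlignment(rows, "APA"))
  cal <- calibrateProfile(apa, nNull = 1000L, lenDist = 100:200, seed = 8L)
  cons <- paste(colnames(matchEmissions(apa))[
    apply(matchEmissions(apa), 1, which.max)], collapse = "")
  planted <- paste0(randomAASeq(60), cons, randomAASeq(60))
  nulls <- vapply(1:50, function(i) randomAASeq(145), "")
  names(nulls) <- sprintf("n%02d", 1:50)
  rep <- apaSearch(c(planted = planted, nulls), apa, cal)
  expect_true(rep$pass[rep$id == "planted"])
  expect_lte(sum(rep$pass[rep$id != "planted"]), 3L)
  # dashed-line semantics: pass iff -log10(E) >= 2 at the 0.01 threshold
  expect_identical(rep$pass, rep$neglog10 >= 2)
})

test_that("family motif statistics agree with planted truth", {
  sv <- miniSurvey()
  fx <- miniFixture()
  ms <- sv$motifStats
  # FAMB carries a planted NPF in metazoans only
  npf <- ms[ms$family == "FAMB" & ms$pattern == "EH", ]
  metaRow <- npf[npf$group == "Metazoa", ]
  expect_gte(metaRow$occurrence, 0.5)
  outRow <- npf[npf$group == "Excavata", ]
  expect_equal(outRow$occurrence, 0)     # family absent there
})
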