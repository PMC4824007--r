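test_that("reference positions map through gapped rows", {
  aln <- SeedAlignment(c(ref = "ACDE", other = "AGDE"))
  expect_equal(mapReferencePositions(aln, "ref", 1:4), 1:4)

  aln2 <- SeedAlignment(c(ref = "A-CD", other = "AGCD"))
  expect_equal(mapReferencePositions(aln2, "ref", 2L), 3L)
  expect_equal(mapReferencePositions(aln2, "ref", c(1L, 3L)), c(1L, 4L))
  expect_error(mapReferencePositions(aln2, "ref", 0L), "out of reference")
  expect_error(mapReferencePositions(aln2, "ref", 4L), "out of reference")
  expect_error(mapReferencePositions(aln2, "nope", 1L), "not in alignment")
  # a mapped column is never a gap in the reference row
  ch <- strsplit("A-CD", "")[[1]]
  expect_true(all(ch[mapReferencePositions(aln2, "ref", 1:3)] != "-"))
})

test_that("information content matches closed forms", {
  inv <- SeedAlignment(stats::setNames(rep("W", 8), paste0("r", 1:8)))
  p <- conservationProfile(inv, 1L, correction = FALSE)
  expect_equal(p$stats$ic, log2(20), tolerance = 1e-9)
  expect_equal(p$stats$consensus, "W")

  uni <- SeedAlignment(stats::setNames(
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    paste0("r", 1:20)))
  p2 <- conservationProfile(uni, 1L, correction = FALSE)
  expect_equal(p2$stats$ic, 0, tolerance = 1e-9)

  half <- SeedAlignment(stats::setNames(rep(c("A", "C"), 4),
                                        paste0("r", 1:8)))
  p3 <- conservationProfile(half, 1L, correction = FALSE)
  expect_equal(p3$stats$ic, log2(20) - 1, tolerance = 1e-9)
  expect_equal(p3$stats$entropy, 1, tolerance = 1e-9)

  # the small-sample correction subtracts 19 / (2 ln2 n) and clips at 0
  p4 <- conservationProfile(inv, 1L, correction = TRUE)
  expect_equal(p4$stats$ic, log2(20) - 19 / (2 * log(2) * 8),
               tolerance = 1e-9)
  p5 <- conservationProfile(uni, 1L, correction = TRUE)
  expect_equal(p5$stats$ic, 0)   # clipped from below

  # gaps are excluded from the denominator
  gap <- SeedAlignment(c(r1 = "W", r2 = "-", r3 = "W", r4 = "-"))
  p6 <- conservationProfile(gap, 1L, correction = FALSE)
  expect_equal(p6$stats$n, 2L)
  expect_equal(p6$stats$ic, log2(20), tolerance = 1e-9)
  expect_error(conservationProfile(
    SeedAlignment(c(r1 = "-", r2 = "-")), 1L), "all-gap")
})

test_that("information content weakly decreases as columns flatten", {
  mk <- function(chars) conservationProfile(
    SeedAlignment(stats::setNames(chars, paste0("r", seq_along(chars)))),
    1L, correction = FALSE)$stats$ic
  ics <- c(mk(rep("A", 8)),
           mk(c(rep("A", 6), rep("C", 2))),
           mk(c(rep("A", 4), rep("C", 4))),
           mk(c("A", "A", "C", "C", "D", "D", "E", "E")),
           mk(c("A", "C", "D", "E", "F", "G", "H", "I")))
  expect_true(all(diff(ics) <= 1e-12))
})

test_that("contact distances equal the exhaustive atom-pair minimum", {
  set.seed(14)
  for (k in 1:25) {
    nA <- sample(1:6, 1); nB <- sample(1:6, 1)
    mkAtoms <- function(n, offset) lapply(seq_len(n), function(i)
      list(name = paste0("C", i), x = stats::rnorm(1) + offset,
           y = stats::rnorm(1), z = stats::rnorm(1)))
    res <- list(list(chain = "A", resno = 1L, resname = "ALA",
                     atoms = mkAtoms(nA, 0)),
                list(chain = "B", resno = 1L, resname = "LEU",
                     atoms = mkAtoms(nB, sample(2:8, 1))))
    f <- writeTempLines(pdbText(res), ".pdb")
    m <- readCoords(f)
    at <- atomTable(m)
    A <- at[at$chain == "A", ]; B <- at[at$chain == "B", ]
    brute <- Inf
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      brute <- min(brute, sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                               (A$z[i] - B$z[j])^2))
    q <- data.frame(chainA = "A", resnoA = 1L, chainB = "B", resnoB = 1L)
    r <- residueContacts(m, q)
    expect_equal(r$distance, brute, tolerance = 1e-3)  # PDB prints 3 decimals
    expect_equal(r$contact, brute <= 4.5)
    # symmetry under pair reversal
    q2 <- data.frame(chainA = "B", resnoA = 1L, chainB = "A", resnoB = 1L)
    expect_equal(residueContacts(m, q2)$distance, r$distance)
  }
})

test_that("contact detection thresholds and errors behave as stated", {
  res <- list(list(chain = "A", resno = 1L, resname = "GLY",
                   atoms = list(list(name = "CA", x = 0, y = 0, z = 0))),
              list(chain = "B", resno = 5L, resname = "GLY",
                   atoms = list(list(name = "CA", x = 3, y = 0, z = 0))))
  f <- writeTempLines(pdbText(res), ".pdb")
  m <- readCoords(f)
  q <- data.frame(chainA = "A", resnoA = 1L, chainB = "B", resnoB = 5L)
  expect_true(residueContacts(m, q, tau = 4.5)$contact)
  res[[2]]$atoms[[1]]$x <- 5
  m2 <- readCoords(writeTempLines(pdbText(res), ".pdb"))
  expect_false(residueContacts(m2, q, tau = 4.5)$contact)
  qBad <- data.frame(chainA = "A", resnoA = 9L, chainB = "B", resnoB = 5L)
  expect_error(residueContacts(m, qBad), "A/9")
})

test_that("contact classification follows the charge and hydrophobicity rules", {
  at <- function(name, x) data.frame(atom = name, x = x, y = 0, z = 0)
  K <- rbind(at("CA", 0), at("NZ", 1))
  E <- rbind(at("CA", 5), at("OE1", 1 + 3.2))
  expect_equal(classifyContact("LYS", "GLU", K, E), "electrostatic")

  V <- rbind(at("CA", 0), at("CB", 1), at("CG1", 1.5))
  L <- rbind(at("CA", 9), at("CD1", 5.5))
  expect_equal(classifyContact("VAL", "LEU", V, L), "hydrophobic")

  S <- rbind(at("CA", 0), at("OG", 1))
  A <- rbind(at("CA", 4.5), at("CB", 3.5))
  expect_equal(classifyContact("SER", "ALA", S, A), "other")

  # same-sign charges are not electrostatic
  K2 <- rbind(at("CA", 5), at("NZ", 1.5))
  expect_equal(classifyContact("LYS", "LYS", K, K2), "other")
  # one-letter names accepted
  expect_equal(classifyContact("K", "E", K, E), "electrostatic")
})
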