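test_that("generated taxonomies have the stated shape and are deterministic", {
  tax <- generateTaxonomy()
  expect_length(tax@tree$tip.label, 16L)      # 8 clades x 2 organisms
  expect_equal(focalPath(tax),
               c("LECA", "Obazoa", "Opisthokonta", "Holozoa", "Metazoa",
                 "Vertebrata"))
  expect_length(focalPath(tax), 6L)
  t2 <- generateTaxonomy()
  expect_identical(ape::write.tree(tax@tree), ape::write.tree(t2@tree))
  # every organism descends from the root clade
  expect_setequal(cladeLeaves(tax)$LECA, tax@tree$tip.label)
})

test_that("zero-rate evolution copies the root to every carrier", {
  spec <- familySpec("F0", data.frame(domain = "D0", length = 40L),
                     "LECA", rate = 0)
  ev <- evolveFamily(spec, miniTaxonomy(), seed = 4L)
  seqs <- unlist(lapply(ev$sequences, unname))
  expect_gt(length(seqs), 1L)
  expect_length(unique(seqs), 1L)
})

test_that("pairwise divergence follows the equal-rates closed form", {
  tax <- readTaxonomy(text = "(a:1,b:1)LECA;", focalClade = "LECA")
  spec <- familySpec("FD", data.frame(domain = "DD", length = 1000L),
                     "LECA", rate = 0.2, domainRateMult = 1,
                     nTail = 0L, cTail = 0L)
  diffs <- vapply(1:5, function(k) {
    ev <- evolveFamily(spec, tax, seed = 100L + k)
    a <- strsplit(ev$sequences$a[[1]], "")[[1]]
    b <- strsplit(ev$sequences$b[[1]], "")[[1]]
    mean(a != b)
  }, 0)
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * 0.4))  # t = 2 branches x 0.2
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("motif planting marks exactly the event clade's subtree", {
  tax <- miniTaxonomy()
  spec <- familySpec("FM", data.frame(domain = "DM", length = 40L),
                     "LECA", rate = 0,
                     events = list(list(type = "motif_plant",
                                        clade = "Metazoa", motif = "DPW",
                                        region = "C_tail")))
  ev <- evolveFamily(spec, tax, seed = 11L)
  metaz <- cladeLeaves(tax)$Metazoa
  for (o in names(ev$sequences)) {
    s <- ev$sequences[[o]]
    if (!length(s)) next
    has <- grepl("DPW", s[[1]], fixed = TRUE)
    if (o %in% metaz) expect_true(has, info = o) else
      expect_false(has, info = o)
  }
})

test_that("events referencing unknown clades fail loudly", {
  spec <- familySpec("FE", data.frame(domain = "D", length = 20L),
                     "LECA",
                     events = list(list(type = "motif_plant",
                                        clade = "Nowhere", motif = "NPF",
                                        region = "C_tail")))
  expect_error(evolveFamily(spec, miniTaxonomy(), seed = 1L),
               "unknown clade")
  spec2 <- familySpec("FE", data.frame(domain = "D", length = 20L),
                      "Atlantis")
  expect_error(evolveFamily(spec2, miniTaxonomy(), seed = 1L),
               "unknown clade")
})

test_that("fixtures are deterministic and internally consistent", {
  fx1 <- generateSurveyFixture(specs = miniSpecs(), tax = miniTaxonomy(),
                               nDecoys = 10L, seed = 19L)
  fx2 <- generateSurveyFixture(specs = miniSpecs(), tax = miniTaxonomy(),
                               nDecoys = 10L, seed = 19L)
  for (o in names(fx1$proteomes))
    expect_identical(as.character(sequences(fx1$proteomes[[o]])),
                     as.character(sequences(fx2$proteomes[[o]])))
  expect_identical(fx1$truth, fx2$truth)

  # truth-table consistency: homolog status iff positive paralog count
  tr <- fx1$truth
  expect_identical(tr$paralogs > 0L, tr$status == "homolog")
})

test_that("clade-specific duplication plants the stated paralog counts", {
  fx <- generateSurveyFixture(seed = 42L, nDecoys = 0L)
  tr <- fx$truth[fx$truth$family == "CALM", ]
  vert <- cladeLeaves(fx$taxonomy)$Vertebrata
  expect_true(all(tr$paralogs[tr$organism %in% vert] == 3L))
  expect_true(all(tr$paralogs[!tr$organism %in% vert] == 1L))
  # the DRP-style scenario: partial-architecture relatives outside Holozoa
  dnm <- fx$truth[fx$truth$family == "DNM", ]
  holo <- cladeLeaves(fx$taxonomy)$Holozoa
  expect_true(all(dnm$status[dnm$organism %in% holo] == "homolog"))
  expect_true(all(dnm$status[!dnm$organism %in% holo] == "analog_ancestor"))
})

test_that("homolog recall does not increase with the substitution rate", {
  tax <- miniTaxonomy()
  recalls <- vapply(c(0.1, 0.4, 1.6), function(r) {
    spec <- list(FAMR = familySpec(
      "FAMR", data.frame(domain = c("RA", "RB"), length = c(50L, 45L)),
      "LECA", rate = r, domainRateMult = 0.5))
    fx <- generateSurveyFixture(specs = spec, tax = tax, nDecoys = 15L,
                                decoyLenRange = c(60L, 180L), seed = 23L)
    sv <- runSurveyCore(fx$taxonomy, fx$proteomes, fx$families,
                        fx$seedAlignments, fx$domainAlignments,
                        fx$refOrganism, nNull = 250L, seed = 2L)
    got <- vapply(sv$calls, callStatus, "")
    tr <- fx$truth
    want <- tr$status[tr$status == "homolog"]
    mean(got[paste(tr$family, tr$organism,
                   sep = "|")][tr$status == "homolog"] == "homolog")
  }, 0)
  expect_true(all(diff(recalls) <= 1e-12))
  expect_equal(recalls[1], 1)
})
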