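test_that("architecture matching distinguishes full, partial and none", {
  expect_equal(matchArchitecture(c("EH", "EH", "CC"), c("EH", "EH", "CC"),
                                 collapseRepeats = FALSE), "full")
  expect_equal(matchArchitecture("SH3", c("EH", "EH", "CC", "SH3", "SH3")),
               "partial")
  expect_equal(matchArchitecture("PH", c("EH", "CC")), "none")

  # tandem-repeat tolerance: 5 SH3 copies match a 2-copy reference
  five <- c("EH", "EH", "CC", rep("SH3", 5))
  two <- c("EH", "EH", "CC", "SH3", "SH3")
  expect_equal(matchArchitecture(five, two, collapseRepeats = TRUE), "full")
  expect_equal(matchArchitecture(five, two, collapseRepeats = FALSE),
               "partial")
  # data.frame input as produced by annotateDomains
  df <- data.frame(domain = c("EH", "CC"), start = c(1, 50),
                   end = c(40, 90), evalue = c(1e-9, 1e-6))
  expect_equal(matchArchitecture(df, c("EH", "CC")), "full")
})

test_that("reciprocal best hit requires a designated member ranked first", {
  q <- randomAASeq(50)
  other <- randomAASeq(50)
  ref <- Proteome("h", c(target = q, bystander = other))
  expect_true(reciprocalCheck(q, ref, "target"))
  # a decoy engineered to outscore the designated member
  expect_false(reciprocalCheck(other, ref, "target"))
  # a designated member is always its own best hit
  expect_true(reciprocalCheck(q, ref, c("target", "bystander")))
  expect_error(reciprocalCheck(q, ref, "absent_id"), "absent")
})

test_that("homolog calling integrates search, architecture and reciprocity", {
  sv <- miniSurvey()
  fx <- miniFixture()
  tr <- fx$truth
  got <- vapply(sv$calls, callStatus, "")
  key <- paste(tr$family, tr$organism, sep = "|")
  expect_identical(unname(got[key]), tr$status)
  # evidence trail: accepted hits only under homolog status
  for (cl in sv$calls) {
    if (callStatus(cl) == "homolog")
      expect_gte(sum(callHits(cl)$accepted), 1L)
    else
      expect_equal(sum(callHits(cl)$accepted), 0L)
  }
})

test_that("relaxed reciprocity accepts full architecture alone", {
  fx <- miniFixture()
  sv <- miniSurvey()
  org <- "exca_1"  # distant organism, FAMA present
  fam <- fx$families$FAMA
  # designate an unrelated record so the reciprocal test must fail
  famBad <- queryFamily("FAMA", fam$refArchitecture,
                        paste0(fx$refOrganism, "_decoy_001"))
  callStrict <- callHomologs(famBad, fx$proteomes[[org]],
                             sv$profiles$FAMA, sv$cals$FAMA,
                             sv$domainProfiles, sv$domainCals,
                             fx$proteomes[[fx$refOrganism]])
  expect_equal(callStatus(callStrict), "absent")
  famRelax <- queryFamily("FAMA", fam$refArchitecture,
                          paste0(fx$refOrganism, "_decoy_001"),
                          relaxReciprocal = TRUE)
  callRelax <- callHomologs(famRelax, fx$proteomes[[org]],
                            sv$profiles$FAMA, sv$cals$FAMA,
                            sv$domainProfiles, sv$domainCals,
                            fx$proteomes[[fx$refOrganism]])
  expect_equal(callStatus(callRelax), "homolog")
})

test_that("emergence epoch is the smallest focal clade containing all hits", {
  tax <- generateTaxonomy()  # LECA..Vertebrata + Excavata/Archaeplastida
  expect_equal(emergenceEpoch(c("exca_1", "holo_1"), tax), "LECA")
  expect_equal(emergenceEpoch(c("holo_1", "holo_2", "meta_1"), tax),
               "Holozoa")
  expect_equal(emergenceEpoch(tax@tree$tip.label, tax), "LECA")
  expect_equal(emergenceEpoch(character(), tax), "not_found")
  expect_equal(emergenceEpoch("vert_2", tax), "Vertebrata")
  expect_error(emergenceEpoch("unknown_org", tax), "not in taxonomy")
})

test_that("adding organisms moves the epoch only toward the root", {
  tax <- generateTaxonomy()
  fp <- focalPath(tax)
  set.seed(12)
  orgs <- tax@tree$tip.label
  for (k in 1:30) {
    base <- sample(orgs, sample(1:6, 1))
    extra <- sample(setdiff(orgs, base), 1)
    e1 <- match(emergenceEpoch(base, tax), fp)
    e2 <- match(emergenceEpoch(c(base, extra), tax), fp)
    expect_lte(e2, e1)
  }
})

test_that("paralog counts and presence are mutually consistent", {
  sv <- miniSurvey()
  pt <- sv$paralogs
  pres <- presence(sv$emergence)
  expect_identical(dimnames(pt), dimnames(pres))
  expect_identical(pt > 0L, pres)
  expect_true(all(pt >= 0L))
})

test_that("the emergence matrix aggregates clades by OR over organisms", {
  sv <- miniSurvey()
  fx <- miniFixture()
  em <- sv$emergence
  cp <- cladePresence(em)
  pres <- presence(em)
  for (cl in colnames(cp)) {
    members <- intersect(cladeLeaves(fx$taxonomy)[[cl]], colnames(pres))
    expect_identical(cp[, cl],
                     rowSums(pres[, members, drop = FALSE]) >= 1L)
  }
  # planted epochs recovered on the mini fixture
  expect_identical(unname(epochs(em)[names(fx$truthEpochs)]),
                   unname(fx$truthEpochs))
})
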