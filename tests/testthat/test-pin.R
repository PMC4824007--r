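mkRecords <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(proteinA = r[1], proteinB = r[2], method = r[3],
               sourceDb = "db")))
  df$selfLoop <- df$proteinA == df$proteinB
  df
}

test_that("evidence filtering keeps the whitelist and drops the rest", {
  rec <- mkRecords(c("A", "B", "two-hybrid screening"),
                   c("A", "B", "affinity purification of complexes"),
                   c("B", "C", "colocalization"),
                   c("C", "D", "far western blotting"),
                   c("D", "E", "some exotic assay"))
  expect_message(out <- filterInteractions(rec), "unlisted")
  expect_equal(nrow(out), 2L)
  expect_true(all(grepl("affinity|far western", out$method)))
  # no blacklisted method ever survives
  expect_false(any(vapply(out$method, function(m)
    any(vapply(evidencePolicy()$blacklist, grepl, TRUE, x = tolower(m),
               fixed = TRUE)), TRUE)))
  expect_equal(nrow(filterInteractions(rec[0, ])), 0L)
  expect_error(evidencePolicy(whitelist = "x", blacklist = "x"), "disjoint")
})

test_that("network assembly collapses records and annotates nodes", {
  rec <- mkRecords(c("A", "B", "far western"), c("B", "A", "far western"),
                   c("B", "C", "far western"))
  g <- buildNetwork(rec, classMap = c(A = "hub", C = "CLASP"))
  ig <- interactionGraph(g)
  expect_equal(igraph::vcount(ig), 3L)
  expect_equal(igraph::ecount(ig), 2L)
  ab <- igraph::E(ig)[igraph::V(ig)["A"] %--% igraph::V(ig)["B"]]
  expect_equal(ab$nRecords, 2L)
  expect_equal(igraph::V(ig)$class[match("A", igraph::V(ig)$name)], "hub")
  expect_equal(igraph::V(ig)$class[match("B", igraph::V(ig)$name)],
               "unknown")

  # epoch annotation joins the emergence matrix
  sv <- miniSurvey()
  rec2 <- mkRecords(c("FAMA", "FAMB", "far western"))
  g2 <- buildNetwork(rec2, emergence = sv$emergence)
  ig2 <- interactionGraph(g2)
  expect_equal(igraph::V(ig2)$epoch[match("FAMA", igraph::V(ig2)$name)],
               unname(epochs(sv$emergence)["FAMA"]))
})

test_that("the edge set is independent of record order", {
  rec <- mkRecords(c("A", "B", "far western"), c("C", "B", "far western"),
                   c("D", "A", "far western"), c("A", "B", "far western"))
  g1 <- buildNetwork(rec)
  g2 <- buildNetwork(rec[c(4, 2, 1, 3), ])
  el1 <- igraph::as_edgelist(interactionGraph(g1))
  el2 <- igraph::as_edgelist(interactionGraph(g2))
  expect_identical(el1, el2)
  expect_identical(igraph::E(interactionGraph(g1))$records,
                   igraph::E(interactionGraph(g2))$records)
})

test_that("a designated hub dominates degree in a star fixture", {
  spokes <- paste0("S", 1:6)
  rec <- do.call(mkRecords, c(lapply(spokes, function(s)
    c("HUB", s, "far western")),
    list(c("S1", "S2", "far western"))))
  g <- interactionGraph(buildNetwork(rec))
  deg <- igraph::degree(g)
  expect_true(all(deg[["HUB"]] >= deg[names(deg) != "HUB"]))
})

test_that("network export round-trips GraphML and writes SIF", {
  rec <- mkRecords(c("A", "B", "far western"), c("B", "C", "far western"))
  g <- buildNetwork(rec, classMap = c(A = "hub"))
  f <- tempfile(fileext = ".graphml")
  exportNetwork(g, f, "graphml")
  g2 <- importNetworkGraphML(f)
  ig <- interactionGraph(g); ig2 <- interactionGraph(g2)
  expect_equal(sort(igraph::V(ig2)$name), sort(igraph::V(ig)$name))
  expect_identical(igraph::as_edgelist(ig2), igraph::as_edgelist(ig))
  expect_identical(igraph::E(ig2)$records, igraph::E(ig)$records)
  expect_identical(igraph::V(ig2)$class[match(igraph::V(ig)$name,
                                              igraph::V(ig2)$name)],
                   igraph::V(ig)$class)

  sif <- tempfile(fileext = ".sif")
  exportNetwork(g, sif, "sif")
  expect_length(readLines(sif), igraph::ecount(ig))

  # empty graph exports a valid (empty) document
  ge <- buildNetwork(rec[0, ])
  f2 <- tempfile(fileext = ".graphml")
  exportNetwork(ge, f2, "graphml")
  expect_equal(igraph::vcount(interactionGraph(importNetworkGraphML(f2))), 0L)
  sif2 <- tempfile(fileext = ".sif")
  exportNetwork(ge, sif2, "sif")
  expect_length(readLines(sif2), 0L)
})

test_that("synthetic interactions recover the truth graph exactly", {
  truth <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "D"))
  rec0 <- generateInteractions(truth, nNoise = 0L, seed = 2L)
  out0 <- filterInteractions(rec0)
  expect_equal(nrow(out0), 3L)

  # blacklist noise only -> empty after filtering
  recN <- generateInteractions(truth[0, ], nodes = c("A", "B"),
                               nNoise = 8L, seed = 2L)
  expect_equal(nrow(filterInteractions(recN)), 0L)

  # mixed: filtered edge set equals the truth set exactly
  rec <- generateInteractions(truth, nNoise = 15L, seed = 5L)
  out <- filterInteractions(rec)
  gotEdges <- sort(paste(pmin(out$proteinA, out$proteinB),
                         pmax(out$proteinA, out$proteinB)))
  wantEdges <- sort(paste(pmin(truth$a, truth$b), pmax(truth$a, truth$b)))
  expect_identical(gotEdges, wantEdges)

  # file round trip through the MI-TAB reader
  f <- tempfile(fileext = ".tsv")
  generateInteractions(truth, nNoise = 5L, seed = 9L, path = f)
  suppressMessages(rec2 <- readInteractions(f))
  expect_equal(nrow(rec2), 8L)
})
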