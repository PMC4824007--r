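#' Disjoint taxon groups for per-group statistics
#'
#' Splits the organisms into disjoint "phylum-like" groups: along the focal
#' path, each clade's exclusive leaves (members of that clade but not of the
#' next nested one), plus every maximal named clade off the focal path
#' (e.g. the outgroup clades).
#'
#' @param tax a [Taxonomy-class].
#' @return Named list, group -> organisms.
#' @export
taxonGroups <- function(tax) {
  cl <- tax@cladeLeaves
  fp <- tax@focalPath
  groups <- list()
  off <- setdiff(names(cl), fp)
  maximal <- off[vapply(off, function(a)
    !any(vapply(off, function(b)
      a != b && all(cl[[a]] %in% cl[[b]]), TRUE)), TRUE)]
  for (g in maximal) groups[[g]] <- cl[[g]]
  for (i in seq_along(fp)) {
    inner <- if (i < length(fp)) cl[[fp[i + 1L]]] else character()
    ex <- setdiff(setdiff(cl[[fp[i]]], inner),
                  unlist(cl[maximal], use.names = FALSE))
    if (length(ex)) groups[[fp[i]]] <- ex
  }
  groups
}

#' Run the homology survey core
#'
#' Executes the full detection pipeline on in-memory objects: builds and
#' calibrates the family and domain profiles (null lengths pooled over all
#' scanned proteomes so e-values are comparable across organisms), calls
#' homologs for every family in every proteome, assembles the emergence
#' matrix and paralog table, computes tail-motif statistics per taxon group,
#' runs the activator-region profile search over the configured family's
#' accepted proteins, and (when interaction records are supplied) builds the
#' evidence-filtered network annotated with emergence epochs.
#'
#' @param tax a [Taxonomy-class].
#' @param proteomes named list of [Proteome-class] objects.
#' @param families named list of [queryFamily()]s.
#' @param seedAlignments,domainAlignments named lists of
#'   [SeedAlignment-class] objects (families and domains).
#' @param refOrganism organism whose proteome anchors the reciprocal test.
#' @param seqThreshold,domThreshold e-value inclusion thresholds.
#' @param nNull null-set size per profile calibration.
#' @param seed master seed for all calibrations.
#' @param apaSeed optional [SeedAlignment-class] for the activator-region
#'   profile.
#' @param apaFamily family whose accepted proteins are scanned for the
#'   activator region.
#' @param motifPolicies optional named character vector, family -> region
#'   policy override (e.g. `c(STON = "N_tail")`).
#' @param interactions optional interaction record data.frame
#'   (pre-filtering).
#' @param policy [evidencePolicy()] for interaction filtering.
#' @param classMap optional node functional classes for the network.
#' @return List with `profiles`, `cals`, `domainProfiles`, `domainCals`,
#'   `calls` (list of [HomologCall-class]), `emergence`, `paralogs`,
#'   `motifStats`, `apaReport` (NULL without `apaSeed`), `network` (NULL
#'   without `interactions`).
#' @export
runSurveyCore <- function(tax, proteomes, families, seedAlignments,
                          domainAlignments, refOrganism,
                          seqThreshold = 0.01, domThreshold = 0.01,
                          nNull = 500L, seed = 1L,
                          apaSeed = NULL, apaFamily = "FCHO",
                          motifPolicies = NULL, interactions = NULL,
                          policy = evidencePolicy(), classMap = character()) {
  stopifnot(seqThreshold > 0, domThreshold > 0)
  if (!refOrganism %in% names(proteomes))
    stop("reference organism has no proteome: ", refOrganism)
  lenDist <- unlist(lapply(proteomes, function(p)
    Biostrings::width(sequences(p))), use.names = FALSE)

  profiles <- lapply(seedAlignments, buildProfile)
  cals <- lapply(profiles, function(p)
    calibrateProfile(p, nNull = nNull, lenDist = lenDist,
                     seed = deriveSeed(seed, paste0("cal_", p@id))))
  domainProfiles <- lapply(domainAlignments, buildProfile)
  domainCals <- lapply(domainProfiles, function(p)
    calibrateProfile(p, nNull = nNull, lenDist = lenDist,
                     seed = deriveSeed(seed, paste0("dom_", p@id))))

  refProteome <- proteomes[[refOrganism]]
  calls <- list()
  for (fn in names(families)) {
    for (o in names(proteomes)) {
      calls[[paste(fn, o, sep = "|")]] <-
        callHomologs(families[[fn]], proteomes[[o]], profiles[[fn]],
                     cals[[fn]], domainProfiles, domainCals, refProteome,
                     seqThreshold = seqThreshold,
                     domThreshold = domThreshold)
    }
  }

  emergence <- buildEmergenceMatrix(calls, tax)
  paralogs <- countParalogs(calls)

  groups <- taxonGroups(tax)
  motifStats <- do.call(rbind, lapply(names(families), function(fn) {
    fcalls <- calls[startsWith(names(calls), paste0(fn, "|"))]
    pol <- if (!is.null(motifPolicies) && fn %in% names(motifPolicies))
      motifPolicies[[fn]] else NULL
    st <- familyMotifStats(fcalls, proteomes, domainProfiles, domainCals,
                           groups = groups, policyOverride = pol,
                           domThreshold = domThreshold)
    cbind(family = fn, st)
  }))

  apaReport <- NULL
  if (!is.null(apaSeed) && apaFamily %in% names(families)) {
    apaProfile <- buildProfile(apaSeed)
    apaCal <- calibrateProfile(apaProfile, nNull = max(nNull, 1000L),
                               lenDist = lenDist,
                               seed = deriveSeed(seed, "apa"))
    rows <- list()
    for (o in names(proteomes)) {
      cl <- calls[[paste(apaFamily, o, sep = "|")]]
      acc <- cl@hits$id[cl@hits$accepted]
      if (!length(acc)) next
      seqs <- stats::setNames(
        as.character(sequences(proteomes[[o]])[acc]), acc)
      df <- apaSearch(seqs, apaProfile, apaCal)
      rows[[o]] <- cbind(organism = o, df)
    }
    apaReport <- if (length(rows)) do.call(rbind, rows) else
      data.frame(organism = character(), id = character(), bits = numeric(),
                 evalue = numeric(), neglog10 = numeric(), pass = logical())
    rownames(apaReport) <- NULL
  }

  network <- NULL
  if (!is.null(interactions)) {
    surv <- filterInteractions(interactions, policy)
    network <- buildNetwork(surv, emergence = emergence,
                            classMap = classMap)
  }

  list(profiles = profiles, cals = cals, domainProfiles = domainProfiles,
       domainCals = domainCals, calls = calls, emergence = emergence,
       paralogs = paralogs, motifStats = motifStats,
       apaReport = apaReport, network = network)
}

.writeAtomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Run a survey from a configuration and write a run directory
#'
#' Loads every input named in the configuration, executes
#' [runSurveyCore()] and writes `emergence_matrix.tsv`,
#' `paralog_table.tsv`, `motif_stats.tsv`, `apa_report.tsv`,
#' `network.graphml`, `calls.jsonl` and `run_log.txt` into `outDir`
#' (write-then-rename, so a failed run leaves no truncated outputs).
#' Re-running with identical inputs and seeds reproduces identical files.
#'
#' The configuration is a list (see [surveyConfigFromYaml()]) with entries:
#' `proteomesDir`, `seedsDir`, `domainsDir`, `taxonomyFile`, `focalClade`,
#' `refOrganism`, `families` (data.frame or list with `family`,
#' `architecture` as `+`-separated domain ids, `designated` as
#' `,`-separated ids, optional `relaxReciprocal`, `collapseRepeats`,
#' `motifPolicy`), and optional `interactionsFile`, `apaSeedFile`,
#' `apaFamily`, `seqThreshold`, `domThreshold`, `nNull`, `seed`.
#'
#' @param config configuration list.
#' @param outDir output directory (created).
#' @return Invisibly, the [runSurveyCore()] result list.
#' @export
runSurvey <- function(config, outDir) {
  need <- c("proteomesDir", "seedsDir", "domainsDir", "taxonomyFile",
            "focalClade", "refOrganism", "families")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))
  for (f in c("taxonomyFile", "interactionsFile", "apaSeedFile"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config file does not exist: ", config[[f]])

  tax <- readTaxonomy(config$taxonomyFile, focalClade = config$focalClade)
  protFiles <- sort(list.files(config$proteomesDir, "\\.(fa|fasta)$",
                               full.names = TRUE))
  proteomes <- lapply(protFiles, readProteome)
  names(proteomes) <- vapply(proteomes, organism, "")
  seedFiles <- sort(list.files(config$seedsDir, "\\.afa$",
                               full.names = TRUE))
  seeds <- lapply(seedFiles, readSeedAlignment)
  names(seeds) <- vapply(seeds, function(x) x@id, "")
  domFiles <- sort(list.files(config$domainsDir, "\\.afa$",
                              full.names = TRUE))
  doms <- lapply(domFiles, readSeedAlignment)
  names(doms) <- vapply(doms, function(x) x@id, "")

  famTab <- config$families
  if (is.data.frame(famTab))
    famTab <- lapply(seq_len(nrow(famTab)), function(i) as.list(famTab[i, ]))
  families <- list()
  motifPolicies <- character()
  for (fr in famTab) {
    families[[fr$family]] <- queryFamily(
      fr$family,
      strsplit(fr$architecture, "+", fixed = TRUE)[[1L]],
      strsplit(fr$designated, ",", fixed = TRUE)[[1L]],
      relaxReciprocal = isTRUE(fr$relaxReciprocal),
      collapseRepeats = !isFALSE(fr$collapseRepeats))
    if (!is.null(fr$motifPolicy))
      motifPolicies[fr$family] <- fr$motifPolicy
  }
  seeds <- seeds[names(seeds) %in% names(families) |
                   names(seeds) %in% "APA"]
  apaSeed <- if (!is.null(config$apaSeedFile))
    readSeedAlignment(config$apaSeedFile) else seeds[["APA"]]
  seeds <- seeds[setdiff(names(seeds), "APA")]
  interactions <- if (!is.null(config$interactionsFile))
    readInteractions(config$interactionsFile) else NULL

  res <- runSurveyCore(
    tax, proteomes, families, seeds, doms, config$refOrganism,
    seqThreshold = config$seqThreshold %||% 0.01,
    domThreshold = config$domThreshold %||% 0.01,
    nNull = config$nNull %||% 500L,
    seed = config$seed %||% 1L,
    apaSeed = apaSeed, apaFamily = config$apaFamily %||% "FCHO",
    motifPolicies = if (length(motifPolicies)) motifPolicies else NULL,
    interactions = interactions)

  writeSurveyOutputs(res, outDir, config)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the survey output files
#'
#' @param res result of [runSurveyCore()].
#' @param outDir output directory.
#' @param config the configuration used (hashed into the run log).
#' @return `outDir`, invisibly.
#' @export
writeSurveyOutputs <- function(res, outDir, config = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  em <- res$emergence
  emdf <- data.frame(family = rownames(presence(em)),
                     epoch = epochs(em)[rownames(presence(em))],
                     presence(em) * 1L, check.names = FALSE)
  writeTsvAtomic(emdf, file.path(outDir, "emergence_matrix.tsv"))
  pdf <- data.frame(family = rownames(res$paralogs), res$paralogs,
                    check.names = FALSE)
  writeTsvAtomic(pdf, file.path(outDir, "paralog_table.tsv"))
  writeTsvAtomic(res$motifStats, file.path(outDir, "motif_stats.tsv"))
  apa <- res$apaReport %||% data.frame(
    organism = character(), id = character(), bits = numeric(),
    evalue = numeric(), neglog10 = numeric(), pass = logical())
  writeTsvAtomic(apa, file.path(outDir, "apa_report.tsv"))
  if (!is.null(res$network)) {
    .writeAtomic(function(p) exportNetwork(res$network, p, "graphml"),
                 file.path(outDir, "network.graphml"))
  } else {
    .writeAtomic(function(p) exportNetwork(
      buildNetwork(data.frame(proteinA = character(),
                              proteinB = character(),
                              method = character(),
                              sourceDb = character())), p, "graphml"),
      file.path(outDir, "network.graphml"))
  }
  .writeAtomic(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    for (cl in res$calls)
      writeLines(jsonlite::toJSON(list(
        family = cl@family, organism = cl@organism, status = cl@status,
        hits = cl@hits), auto_unbox = TRUE, digits = NA, na = "null"), con)
  }, file.path(outDir, "calls.jsonl"))
  cfgTmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config[order(names(config))], cfgTmp,
                       auto_unbox = TRUE, force = TRUE)
  hash <- unname(tools::md5sum(cfgTmp))
  unlink(cfgTmp)
  .writeAtomic(function(p) writeLines(c(
    paste("package:", as.character(utils::packageVersion("CMETrace"))),
    paste("R:", R.version.string),
    paste("config_md5:", hash),
    paste("seed:", config$seed %||% 1L),
    paste("families:", length(res$profiles)),
    paste("organisms:", length(unique(vapply(res$calls,
                                             function(x) x@organism, ""))))),
    p), file.path(outDir, "run_log.txt"))
  invisible(outDir)
}

#' Load a survey configuration from YAML
#'
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return Configuration list for [runSurvey()].
#' @export
surveyConfigFromYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("proteomesDir", "seedsDir", "domainsDir", "taxonomyFile",
              "interactionsFile", "apaSeedFile"))
    if (!is.null(cfg[[f]]) && !grepl("^/", cfg[[f]]))
      cfg[[f]] <- file.path(base, cfg[[f]])
  cfg
}
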