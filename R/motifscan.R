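#' Built-in linear-motif patterns
#'
#' The three endocytic interaction-motif patterns scanned in protein tails,
#' as amino-acid regular expressions: AP2-binding
#' (`DP[WF]|F.D.F|WV.F|F.F.[FL]`), clathrin-box
#' (`L[FILMV].[FILMV][DE]|L[FILMV].[DE][FILMV]`) and the EH-domain-binding
#' tripeptide (`NPF`). All three default to the C-terminal tail; stonin-type
#' families override the region policy to the N-terminal tail.
#'
#' @return Named list of motif patterns, each a list with `name`, `pattern`
#'   and `policy` (one of `"C_tail"`, `"N_tail"`, `"full"`).
#' @export
motifRegistry <- function() {
  list(
    AP2      = motifPattern("AP2", "DP[WF]|F.D.F|WV.F|F.F.[FL]", "C_tail"),
    clathrin = motifPattern("clathrin",
                            "L[FILMV].[FILMV][DE]|L[FILMV].[DE][FILMV]",
                            "C_tail"),
    EH       = motifPattern("EH", "NPF", "C_tail"))
}

#' Define a motif pattern
#'
#' @param name pattern name.
#' @param pattern regular expression over the amino-acid alphabet.
#' @param policy which tail region is scanned: `"C_tail"`, `"N_tail"` or
#'   `"full"`.
#' @return Motif pattern list.
#' @export
motifPattern <- function(name, pattern,
                         policy = c("C_tail", "N_tail", "full")) {
  policy <- match.arg(policy)
  ok <- tryCatch({ suppressWarnings(grepl(pattern, "A", perl = TRUE)); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("pattern does not compile: ", pattern)
  list(name = name, pattern = pattern, policy = policy)
}

#' Extract the disordered tail of a protein
#'
#' The terminal region outside all resolved domain envelopes: for `C_tail`,
#' residues from one past the last envelope end to the sequence end; for
#' `N_tail`, residues 1 to one before the first envelope start; with an empty
#' architecture the whole sequence is the tail. A zero-length tail is valid.
#'
#' @param seq protein sequence (string).
#' @param arch resolved domain architecture ([annotateDomains()] data.frame).
#' @param policy `"C_tail"`, `"N_tail"` or `"full"`.
#' @return List with `seq`, 1-based inclusive `start`/`end` in the parent
#'   (`start > end` for an empty tail) and `policy`.
#' @export
extractTail <- function(seq, arch, policy = c("C_tail", "N_tail", "full")) {
  policy <- match.arg(policy)
  L <- nchar(seq)
  if (policy == "full" || nrow(arch) == 0L) {
    s <- 1L; e <- L
  } else if (policy == "C_tail") {
    s <- max(arch$end) + 1L; e <- L
  } else {
    s <- 1L; e <- min(arch$start) - 1L
  }
  list(seq = if (s <= e) substr(seq, s, e) else "",
       start = s, end = e, policy = policy)
}

#' Scan a region for a motif pattern
#'
#' Counts every start position whose suffix matches any alternative of the
#' pattern; overlapping matches are all counted, and a position matching two
#' alternatives counts once.
#'
#' @param region region string (a tail, or any sequence).
#' @param pat a [motifPattern()].
#' @return List with `count` and 1-based `positions` within the region.
#' @export
scanMotif <- function(region, pat) {
  if (is.list(region)) region <- region$seq
  if (!nchar(region)) return(list(count = 0L, positions = integer()))
  m <- gregexpr(paste0("(?=(", pat$pattern, "))"), region, perl = TRUE)[[1L]]
  pos <- as.integer(m[m > 0L])
  list(count = length(pos), positions = pos)
}

#' Per-taxon motif occurrence statistics
#'
#' Occurrence `O` = organisms in the group with the motif in at least one of
#' the family's proteins, divided by all organisms in the group (organisms
#' lacking a homolog stay in the denominator unless `possessorsOnly`);
#' `medianCount` = median motif count over the group's motif-containing
#' proteins (undefined when there are none).
#'
#' @param perProteinCounts named list, organism -> integer vector of motif
#'   counts for that organism's family proteins (empty vector when the family
#'   is absent there).
#' @param taxGroup non-empty character vector of organisms in the group.
#' @param possessorsOnly restrict the denominator to organisms that have the
#'   family (sensitivity analysis; off by default).
#' @return List with `occurrence`, `medianCount` (NA when undefined),
#'   `nWith`, `nTotal`.
#' @export
motifOccurrence <- function(perProteinCounts, taxGroup,
                            possessorsOnly = FALSE) {
  if (!length(taxGroup)) stop("empty taxon group")
  counts <- lapply(taxGroup, function(o) {
    v <- perProteinCounts[[o]]
    if (is.null(v)) integer() else v
  })
  names(counts) <- taxGroup
  hasFam <- vapply(counts, function(v) length(v) > 0L, TRUE)
  nTotal <- if (possessorsOnly) sum(hasFam) else length(taxGroup)
  hasMotif <- vapply(counts, function(v) any(v >= 1L), TRUE)
  nWith <- sum(hasMotif)
  allCounts <- unlist(counts, use.names = FALSE)
  withMotif <- allCounts[allCounts >= 1L]
  list(occurrence = if (nTotal > 0L) nWith / nTotal else NA_real_,
       medianCount = if (length(withMotif)) stats::median(withMotif)
                     else NA_real_,
       nWith = nWith, nTotal = nTotal)
}

#' Profile search for an AP2-activating (APA)-type region
#'
#' Scores each record with a calibrated profile built from a small seed of
#' activator-region sequences and reports, per record, the e-value, its
#' negative decadic logarithm (the bar height of an e-value diagram) and
#' whether it passes the threshold (pass iff `-log10(E) >= -log10(threshold)`,
#' i.e. `E <= threshold`).
#'
#' @param records named character vector of protein sequences.
#' @param apaProfile a [ProfileHMM-class].
#' @param cal its [EvalueCalibration-class].
#' @param threshold e-value threshold (default 0.01, the dashed line at
#'   `-log10(E) = 2`).
#' @param dbSize database size for the e-value (default 1 per record).
#' @return data.frame with columns `id`, `bits`, `evalue`, `neglog10`,
#'   `pass`.
#' @export
apaSearch <- function(records, apaProfile, cal, threshold = 0.01,
                      dbSize = 1L) {
  pp <- .phmmParams(apaProfile)
  ints <- lapply(records, aaToInt)
  bits <- .forwardBatchInt(pp, ints, TRUE)
  ev <- hitEvalue(bits, cal, dbSize)
  data.frame(id = names(records), bits = bits, evalue = ev,
             neglog10 = -log10(ev), pass = ev <= threshold)
}

#' Motif statistics across families, patterns and taxon groups
#'
#' For every accepted homolog protein the domain architecture is resolved,
#' the tail under the pattern's region policy is extracted and scanned, and
#' per-group occurrence/median statistics are computed with
#' [motifOccurrence()].
#'
#' @param calls list of [HomologCall-class] for one family.
#' @param proteomes named list of [Proteome-class] (by organism).
#' @param domainProfiles,domainCals as in [annotateDomains()].
#' @param patterns named list of [motifPattern()]s.
#' @param groups named list, group name -> organisms.
#' @param policyOverride optional region policy overriding every pattern's
#'   own (e.g. `"N_tail"` for stonin-type families).
#' @param domThreshold domain e-value threshold for tail resolution.
#' @return data.frame with one row per (pattern, group).
#' @export
familyMotifStats <- function(calls, proteomes, domainProfiles, domainCals,
                             patterns = motifRegistry(), groups,
                             policyOverride = NULL, domThreshold = 0.01) {
  # per organism: per accepted protein, its sequence and architecture
  perOrg <- list()
  for (cl in calls) {
    acc <- cl@hits$id[cl@hits$accepted]
    if (!length(acc)) { perOrg[[cl@organism]] <- list(); next }
    seqs <- sequences(proteomes[[cl@organism]])
    perOrg[[cl@organism]] <- lapply(acc, function(id) {
      s <- as.character(seqs[[id]])
      list(seq = s,
           arch = annotateDomains(s, domainProfiles, domainCals,
                                  domThreshold))
    })
  }
  rows <- list()
  for (pn in names(patterns)) {
    pat <- patterns[[pn]]
    pol <- if (is.null(policyOverride)) pat$policy else policyOverride
    counts <- lapply(perOrg, function(prots)
      vapply(prots, function(pr)
        scanMotif(extractTail(pr$seq, pr$arch, pol), pat)$count, 0L))
    for (gn in names(groups)) {
      st <- motifOccurrence(counts, groups[[gn]])
      rows[[length(rows) + 1L]] <-
        data.frame(pattern = pn, group = gn, occurrence = st$occurrence,
                   medianCount = st$medianCount, nWith = st$nWith,
                   nTotal = st$nTotal)
    }
  }
  do.call(rbind, rows)
}
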