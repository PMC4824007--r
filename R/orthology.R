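#' Describe a query family
#'
#' Bundles what the survey needs to know about one animal protein family: the
#' reference domain architecture (ordered domain ids, as in the designated
#' reference organism), the designated reference-proteome members (the full
#' paralog set; any of them ranked first passes the reciprocal test), whether
#' the reciprocal requirement is relaxed (used for very distant homologs,
#' where typical architecture alone is accepted), and whether tandem repeats
#' of one domain are collapsed when comparing architectures (so that, e.g., a
#' two-SH3 and a five-SH3 form of the same scaffold both count as full
#' matches).
#'
#' @param family family id.
#' @param refArchitecture ordered character vector of domain ids (non-empty).
#' @param designated character vector of reference-proteome member ids
#'   (non-empty).
#' @param relaxReciprocal accept on architecture alone.
#' @param collapseRepeats collapse tandem repeats when matching.
#' @param seedId id of the family's seed alignment.
#' @return A `queryFamily` list.
#' @export
queryFamily <- function(family, refArchitecture, designated,
                        relaxReciprocal = FALSE, collapseRepeats = TRUE,
                        seedId = family) {
  stopifnot(length(refArchitecture) >= 1L, length(designated) >= 1L)
  structure(list(family = family, refArchitecture = refArchitecture,
                 designated = designated, relaxReciprocal = relaxReciprocal,
                 collapseRepeats = collapseRepeats, seedId = seedId),
            class = "queryFamily")
}

collapseRuns <- function(x) if (length(x)) rle(x)$values else character(0)

#' Compare a hit's domain architecture with a reference architecture
#'
#' `full` when the ordered domain ids match the reference exactly; with
#' `collapseRepeats` a run of k >= 1 copies of one domain matches a reference
#' run of that domain (tandem-repeat copy-number tolerance). `partial` when
#' not full but at least one domain id is shared; `none` otherwise.
#'
#' @param hitArch character vector of ordered domain ids (or the data.frame
#'   returned by [annotateDomains()]).
#' @param refArch ordered reference domain ids.
#' @param collapseRepeats collapse tandem repeats before comparing.
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
matchArchitecture <- function(hitArch, refArch, collapseRepeats = TRUE) {
  if (is.data.frame(hitArch)) hitArch <- hitArch$domain
  a <- if (collapseRepeats) collapseRuns(hitArch) else hitArch
  r <- if (collapseRepeats) collapseRuns(refArch) else refArch
  if (length(a) == length(r) && all(a == r)) return("full")
  if (length(intersect(hitArch, refArch))) return("partial")
  "none"
}

#' Reciprocal-best-hit test
#'
#' TRUE iff ranking the reference proteome against the hit sequence (local
#' alignment, see [rankProteome()]) places one of the designated
#' reference-family members first.
#'
#' @param hitSeq hit protein sequence (string).
#' @param refProteome reference [Proteome-class] (e.g. the human-like
#'   proteome).
#' @param designated ids of the designated family members; all must be
#'   present in the reference proteome.
#' @param ... passed to [rankProteome()].
#' @return Logical.
#' @export
reciprocalCheck <- function(hitSeq, refProteome, designated, ...) {
  missing <- setdiff(designated, names(sequences(refProteome)))
  if (length(missing))
    stop("designated member(s) absent from reference proteome: ",
         paste(missing, collapse = ", "))
  rk <- rankProteome(hitSeq, refProteome, ...)
  rk$id[1L] %in% designated
}

#' Call homologs of one family in one proteome
#'
#' The survey's decision procedure: every forward-search hit at or below the
#' sequence e-value threshold is annotated with its domain architecture and
#' (unless the family relaxes it) the reciprocal-best-hit verdict. A hit is
#' accepted as a homolog iff its architecture fully matches the reference and
#' (relaxed families aside) the reciprocal test passes. If no hit is accepted
#' but some hit combines a partial architecture with a passing reciprocal
#' test, the family is called `analog_ancestor` (a putative analog or
#' ancestor of the animal protein); otherwise `absent`. Partial-architecture
#' hits failing reciprocity are reported absent, with the evidence retained.
#'
#' @param family a [queryFamily()].
#' @param prot the scanned [Proteome-class].
#' @param familyProfile calibrated family [ProfileHMM-class].
#' @param familyCal its [EvalueCalibration-class].
#' @param domainProfiles,domainCals named lists covering at least the
#'   reference-architecture domains.
#' @param refProteome reference proteome for the reciprocal test.
#' @param seqThreshold,domThreshold sequence/domain e-value inclusion
#'   thresholds.
#' @param mat substitution matrix for the reciprocal ranking.
#' @return A [HomologCall-class].
#' @export
callHomologs <- function(family, prot, familyProfile, familyCal,
                         domainProfiles, domainCals, refProteome,
                         seqThreshold = 0.01, domThreshold = 0.01,
                         mat = blosum62()) {
  hits <- scanProteome(familyProfile, prot, familyCal, seqThreshold)
  seqs <- sequences(prot)
  n <- nrow(hits)
  arch <- character(n); recip <- rep(NA, n)
  archStr <- character(n)
  for (k in seq_len(n)) {
    s <- as.character(seqs[[hits$id[k]]])
    da <- annotateDomains(s, domainProfiles, domainCals, domThreshold)
    arch[k] <- matchArchitecture(da, family$refArchitecture,
                                 family$collapseRepeats)
    archStr[k] <- paste(da$domain, collapse = "+")
    if (!family$relaxReciprocal && arch[k] %in% c("full", "partial"))
      recip[k] <- reciprocalCheck(s, refProteome, family$designated,
                                  mat = mat)
  }
  accepted <- arch == "full" &
    (family$relaxReciprocal | (!is.na(recip) & recip))
  status <- if (any(accepted)) "homolog"
  else if (any(arch == "partial" & !is.na(recip) & recip)) "analog_ancestor"
  else "absent"
  hitdf <- if (n) data.frame(id = hits$id, bits = hits$bits,
                             evalue = hits$evalue,
                             architecture = arch, domains = archStr,
                             reciprocal = recip, accepted = accepted)
  else data.frame(id = character(), bits = numeric(), evalue = numeric(),
                  architecture = character(), domains = character(),
                  reciprocal = logical(), accepted = logical())
  methods::new("HomologCall", family = family$family,
               organism = organism(prot), status = status, hits = hitdf)
}

#' Count paralogs from a set of homolog calls
#'
#' Per (family, organism), the number of accepted homolog hits (all retained
#' paralog copies; zero when the status is not `homolog`).
#'
#' @param calls list of [HomologCall-class] objects.
#' @return Integer matrix, families x organisms.
#' @export
countParalogs <- function(calls) {
  fams <- unique(vapply(calls, function(x) x@family, ""))
  orgs <- unique(vapply(calls, function(x) x@organism, ""))
  m <- matrix(0L, length(fams), length(orgs), dimnames = list(fams, orgs))
  for (cl in calls) {
    nacc <- if (nrow(cl@hits)) sum(cl@hits$accepted) else 0L
    m[cl@family, cl@organism] <- as.integer(nacc)
  }
  m
}

#' Emergence epoch of a family
#'
#' The smallest named clade on the taxonomy's focal path (root included) that
#' contains every organism where the family's homolog was found; `"not_found"`
#' when the presence set is empty.
#'
#' @param presentOrgs character vector of organisms with a homolog.
#' @param tax a [Taxonomy-class].
#' @return Clade name, or `"not_found"`.
#' @export
emergenceEpoch <- function(presentOrgs, tax) {
  if (!length(presentOrgs)) return("not_found")
  allLeaves <- tax@tree$tip.label
  unknown <- setdiff(presentOrgs, allLeaves)
  if (length(unknown))
    stop("organism not in taxonomy: ", paste(unknown, collapse = ", "))
  path <- rev(tax@focalPath)  # focal clade first, root last
  for (clade in path)
    if (all(presentOrgs %in% tax@cladeLeaves[[clade]])) return(clade)
  tax@focalPath[1L]  # root always contains everything
}

#' Build the emergence matrix from homolog calls
#'
#' Families-by-organisms presence (status `homolog`), aggregated to
#' families-by-clades presence (an organism count of at least `minOrganisms`
#' marks a clade, default 1), and the per-family emergence epoch via
#' [emergenceEpoch()].
#'
#' @param calls list of [HomologCall-class] objects.
#' @param tax a [Taxonomy-class].
#' @param minOrganisms organisms required to mark a clade as possessing the
#'   family.
#' @return An [EmergenceMatrix-class].
#' @export
buildEmergenceMatrix <- function(calls, tax, minOrganisms = 1L) {
  fams <- unique(vapply(calls, function(x) x@family, ""))
  orgs <- unique(vapply(calls, function(x) x@organism, ""))
  pres <- matrix(FALSE, length(fams), length(orgs),
                 dimnames = list(fams, orgs))
  for (cl in calls)
    pres[cl@family, cl@organism] <- cl@status == "homolog"
  clades <- names(tax@cladeLeaves)
  cp <- matrix(FALSE, length(fams), length(clades),
               dimnames = list(fams, clades))
  for (cl in clades) {
    members <- intersect(tax@cladeLeaves[[cl]], orgs)
    if (length(members))
      cp[, cl] <- rowSums(pres[, members, drop = FALSE]) >= minOrganisms
  }
  ep <- vapply(fams, function(f)
    emergenceEpoch(orgs[pres[f, ]], tax), "")
  methods::new("EmergenceMatrix", presence = pres, cladePresence = cp,
               epochs = ep, focalPath = tax@focalPath)
}
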