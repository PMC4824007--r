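#' @importClassesFrom Biostrings AAStringSet
NULL

setOldClass("phylo")
setOldClass("igraph")

#' Proteome: the protein complement of one organism
#'
#' Container for all protein sequences of one organism, together with the
#' organism identifier and its clade path (root to leaf) on the survey
#' taxonomy. Sequences are stored as a [Biostrings::AAStringSet] over the
#' 20-letter alphabet plus X; record identifiers are unique within the
#' proteome.
#'
#' @slot organism single organism identifier.
#' @slot sequences `AAStringSet`, names are record ids.
#' @slot taxonPath character vector of clade names from root to this
#'   organism's leaf (may be empty until attached to a taxonomy).
#'
#' @seealso [readProteome()], [taxonPath()]
#' @export
setClass("Proteome",
  slots = c(organism = "character", sequences = "AAStringSet",
            taxonPath = "character"))

setValidity("Proteome", function(object) {
  ids <- names(object@sequences)
  if (length(object@organism) != 1L) return("organism must be a single string")
  if (length(object@sequences) == 0L) return(TRUE)  # empty proteome is valid
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("every record must have an id")
  if (anyDuplicated(ids))
    return(paste0("duplicate record id: ", ids[duplicated(ids)][1L]))
  if (any(Biostrings::width(object@sequences) == 0L))
    return("empty sequence not allowed")
  TRUE
})

#' Seed alignment
#'
#' A fixed multiple alignment used as input for profile construction:
#' equal-length gapped rows over the amino-acid alphabet plus `-` and X.
#'
#' @slot id alignment identifier.
#' @slot rows `AAStringSet` of gapped rows (equal widths), names are row ids.
#' @export
setClass("SeedAlignment", slots = c(id = "character", rows = "AAStringSet"))

setValidity("SeedAlignment", function(object) {
  w <- Biostrings::width(object@rows)
  if (length(w) < 1L) return("alignment must have at least one row")
  if (length(unique(w)) != 1L) return("all rows must have equal length")
  TRUE
})

#' Survey taxonomy
#'
#' A rooted tree whose leaves are organisms and whose internal nodes carry
#' unique clade names, together with a focal path: the ordered clade series
#' from the root to a designated focal clade (for this survey, the series
#' ending in the metazoan-like clade along which emergence epochs are
#' assigned).
#'
#' @slot tree an [ape] `phylo` object with `node.label` set.
#' @slot focalPath character vector of clade names, root first.
#' @slot cladeLeaves named list mapping every named clade to the organisms
#'   (tip labels) it contains.
#' @export
setClass("Taxonomy",
  slots = c(tree = "phylo", focalPath = "character", cladeLeaves = "list"))

setValidity("Taxonomy", function(object) {
  nl <- object@tree$node.label
  named <- nl[!is.na(nl) & nl != ""]
  if (anyDuplicated(named))
    return(paste0("duplicate clade name: ", named[duplicated(named)][1L]))
  if (length(object@focalPath) < 1L) return("focalPath must be non-empty")
  if (!all(object@focalPath %in% names(object@cladeLeaves)))
    return("focalPath contains an unknown clade")
  TRUE
})

#' Profile hidden Markov model
#'
#' Position-specific scoring model built from a seed alignment: match states
#' with estimated emission distributions, insert states emitting the
#' background, and per-position match/insert/delete transitions (simplified
#' Plan7, single-hit). Used for forward/Viterbi scoring, proteome scanning and
#' domain annotation.
#'
#' @slot id profile identifier.
#' @slot seedId identifier of the source alignment.
#' @slot M number of match states.
#' @slot matchEmis `M x 20` matrix of match emission probabilities (rows sum
#'   to 1), columns in alphabetical one-letter order.
#' @slot bg background distribution (length 20).
#' @slot tMM,tMI,tMD numeric length `M`; `tMM[M]` is the probability of
#'   `M_M -> end` and `tMD[M]` is 0.
#' @slot tIM,tII numeric length `M + 1` for insert states `I_0..I_M`;
#'   `tIM[M + 1]` is `I_M -> end`.
#' @slot tDM,tDD numeric length `M`; `tDM[M]` is `D_M -> end`.
#' @slot tBM,tBI,tBD begin-state transitions into `M_1`, `I_0`, `D_1`.
#' @seealso [buildProfile()], [forwardScore()], [viterbiAlign()]
#' @export
setClass("ProfileHMM",
  slots = c(id = "character", seedId = "character", M = "integer",
            matchEmis = "matrix", bg = "numeric",
            tMM = "numeric", tMI = "numeric", tMD = "numeric",
            tIM = "numeric", tII = "numeric",
            tDM = "numeric", tDD = "numeric",
            tBM = "numeric", tBI = "numeric", tBD = "numeric"))

setValidity("ProfileHMM", function(object) {
  M <- object@M
  if (M < 1L) return("M must be >= 1")
  if (!all(dim(object@matchEmis) == c(M, 20L)))
    return("matchEmis must be M x 20")
  tol <- 1e-9
  if (any(abs(rowSums(object@matchEmis) - 1) > tol))
    return("match emission rows must sum to 1")
  if (abs(sum(object@bg) - 1) > tol) return("background must sum to 1")
  if (abs(object@tBM + object@tBI + object@tBD - 1) > tol)
    return("begin transitions must sum to 1")
  out <- object@tMM + object@tMI + object@tMD
  if (any(abs(out - 1) > tol)) return("match transitions must sum to 1")
  if (any(abs(object@tIM + object@tII - 1) > tol))
    return("insert transitions must sum to 1")
  if (any(abs(object@tDM + object@tDD - 1) > tol))
    return("delete transitions must sum to 1")
  TRUE
})

#' E-value calibration for a profile
#'
#' Gumbel (type-I extreme value) location/scale fitted to the distribution of
#' forward bit scores of random background sequences, from which per-hit
#' p-values and database-size-scaled e-values are computed.
#'
#' @slot profileId profile this calibration belongs to.
#' @slot mu Gumbel location.
#' @slot lambda Gumbel scale (> 0).
#' @slot nNull number of null sequences scored (>= 100).
#' @slot seed RNG seed used to draw the null set.
#' @seealso [calibrateProfile()], [hitEvalue()]
#' @export
setClass("EvalueCalibration",
  slots = c(profileId = "character", mu = "numeric", lambda = "numeric",
            nNull = "integer", seed = "integer"))

setValidity("EvalueCalibration", function(object) {
  if (object@lambda <= 0) return("lambda must be > 0")
  if (object@nNull < 100L) return("nNull must be >= 100")
  TRUE
})

#' Homolog call for one family in one proteome
#'
#' The verdict of the survey for one query family in one organism:
#' `homolog` (at least one forward-search hit with the full reference domain
#' architecture that passes the reciprocal-best-hit test, or architecture
#' alone when the family's reciprocal requirement is relaxed),
#' `analog_ancestor` (no homolog, but a reciprocal-passing hit with a
#' partially matching architecture), or `absent`. The full evidence trail for
#' every thresholded hit is retained.
#'
#' @slot family family id.
#' @slot organism organism id.
#' @slot status one of `"homolog"`, `"analog_ancestor"`, `"absent"`.
#' @slot hits data.frame with columns `id`, `bits`, `evalue`, `architecture`
#'   (full/partial/none), `reciprocal` (logical or NA when not evaluated) and
#'   `accepted`.
#' @export
setClass("HomologCall",
  slots = c(family = "character", organism = "character", status = "character",
            hits = "data.frame"))

setValidity("HomologCall", function(object) {
  if (!object@status %in% c("homolog", "analog_ancestor", "absent"))
    return("invalid status")
  nacc <- if (nrow(object@hits)) sum(object@hits$accepted) else 0L
  if (object@status == "homolog" && nacc < 1L)
    return("homolog status requires >= 1 accepted hit")
  if (object@status != "homolog" && nacc > 0L)
    return("non-homolog status must have 0 accepted hits")
  TRUE
})

#' Emergence matrix
#'
#' Family-by-organism presence (homolog detected), its aggregation to
#' family-by-clade presence (logical OR over member organisms), and the
#' inferred emergence epoch per family: the smallest clade on the taxonomy's
#' focal path, root included, containing every organism where the family's
#' homolog was found.
#'
#' @slot presence logical matrix, families x organisms.
#' @slot cladePresence logical matrix, families x focal-path clades.
#' @slot epochs named character vector, family -> clade name (or
#'   `"not_found"`).
#' @slot focalPath the focal path of the taxonomy used.
#' @seealso [buildEmergenceMatrix()], [emergenceEpoch()]
#' @export
setClass("EmergenceMatrix",
  slots = c(presence = "matrix", cladePresence = "matrix",
            epochs = "character", focalPath = "character"))

setValidity("EmergenceMatrix", function(object) {
  if (!is.logical(object@presence)) return("presence must be logical")
  ok <- object@epochs %in% c(object@focalPath, "not_found")
  if (!all(ok)) return("epochs must lie on the focal path (or be not_found)")
  TRUE
})

#' Evidence-filtered protein-interaction network
#'
#' Undirected graph of binary interactions that survived evidence filtering,
#' with nodes annotated by family emergence epoch and functional class and
#' each edge carrying the identifiers of its supporting records.
#'
#' @slot graph an [igraph] graph; vertex attributes `epoch` and `class`, edge
#'   attributes `records` (;-separated) and `selfLoop`.
#' @seealso [buildNetwork()], [filterInteractions()], [exportNetwork()]
#' @export
setClass("PINGraph", slots = c(graph = "igraph"))

#' Structural model (coordinate set)
#'
#' Heavy-atom coordinates parsed from PDB ATOM records: chains, 1-based
#' author residue numbering, residue and atom names, and x/y/z in Angstrom.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z`.
#' @seealso [readCoords()], [residueContacts()]
#' @export
setClass("StructureModel", slots = c(atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    return("atoms must have chain/resno/resname/atom/x/y/z")
  if (any(!is.finite(object@atoms$x)) || any(!is.finite(object@atoms$y)) ||
      any(!is.finite(object@atoms$z)))
    return("coordinates must be finite")
  TRUE
})
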