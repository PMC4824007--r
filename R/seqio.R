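#' Construct a Proteome
#'
#' @param organism organism identifier.
#' @param sequences named character vector or `AAStringSet` of protein
#'   sequences (ids as names).
#' @param taxonPath optional clade path, root to leaf.
#' @return A [Proteome-class] object.
#' @export
Proteome <- function(organism, sequences, taxonPath = character()) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  methods::new("Proteome", organism = organism, sequences = sequences,
               taxonPath = taxonPath)
}

# uppercase, strip one terminal '*', map U/O to X (warning); returns character
normalizeAA <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("[UO]", seqs))) {
    warning("selenocysteine/pyrrolysine (U/O) mapped to X")
    seqs <- gsub("[UO]", "X", seqs)
  }
  for (k in seq_along(seqs)) checkAASequence(seqs[k], ids[k])
  seqs
}

#' Read a proteome from a FASTA file
#'
#' One record per header; wrapped sequence lines are concatenated, lowercase
#' is uppercased, a single terminal `*` (stop) is stripped, and U/O are mapped
#' to X with a warning. Duplicate ids or characters outside the 20-letter
#' alphabet plus X are errors.
#'
#' @param path FASTA file.
#' @param organism organism identifier; defaults to the file base name.
#' @param taxonPath optional clade path.
#' @return A [Proteome-class].
#' @export
readProteome <- function(path, organism = NULL,
                         taxonPath = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1L])
  seqs <- normalizeAA(as.character(raw), ids)
  names(seqs) <- ids
  if (is.null(organism))
    organism <- sub("\\.(fa|fasta|faa)$", "", basename(path))
  Proteome(organism, seqs, taxonPath)
}

#' Write a proteome to FASTA
#'
#' @param x a [Proteome-class].
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(sequences(x), path, width = width)
  invisible(path)
}

#' Read a seed alignment (aligned FASTA)
#'
#' Rows must have equal gapped length; `.` is normalised to `-`; ungapping a
#' row must yield a valid protein sequence.
#'
#' @param path aligned FASTA file.
#' @param id alignment id; defaults to the file base name.
#' @return A [SeedAlignment-class].
#' @export
readSeedAlignment <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate row id: ", ids[duplicated(ids)][1L])
  seqs <- gsub(".", "-", toupper(as.character(raw)), fixed = TRUE)
  if (any(grepl("[UO]", seqs))) {
    warning("selenocysteine/pyrrolysine (U/O) mapped to X")
    seqs <- gsub("[UO]", "X", seqs)
  }
  for (k in seq_along(seqs)) checkAASequence(gsub("-", "", seqs[k]), ids[k])
  names(seqs) <- ids
  if (is.null(id)) id <- sub("\\.(afa|fasta|fa|aln)$", "", basename(path))
  methods::new("SeedAlignment", id = id, rows = Biostrings::AAStringSet(seqs))
}

#' Construct a SeedAlignment from gapped strings
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @param id alignment identifier.
#' @return A [SeedAlignment-class].
#' @export
SeedAlignment <- function(rows, id = "seed") {
  methods::new("SeedAlignment", id = id, rows = Biostrings::AAStringSet(rows))
}

# ---- taxonomy ---------------------------------------------------------------

taxonomyFromPhylo <- function(tree, focalClade) {
  if (is.null(tree$node.label))
    stop("taxonomy tree has no internal-node labels")
  labs <- tree$node.label
  named <- labs[!is.na(labs) & labs != ""]
  if (anyDuplicated(named))
    stop("duplicate clade name: ", named[duplicated(named)][1L])
  if (anyDuplicated(tree$tip.label))
    stop("duplicate organism name: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  ntip <- length(tree$tip.label)
  nodeIds <- ntip + seq_along(labs)
  names(nodeIds) <- labs
  if (!focalClade %in% named) stop("focal clade not found: ", focalClade)

  cladeLeaves <- lapply(nodeIds[named], function(nd) {
    if (nd == ntip + 1L) tree$tip.label
    else ape::extract.clade(tree, nd)$tip.label
  })

  root <- ntip + 1L
  target <- nodeIds[[focalClade]]
  pathNodes <- if (target == root) root else ape::nodepath(tree, root, target)
  pathLabs <- labs[pathNodes - ntip]
  if (any(is.na(pathLabs) | pathLabs == ""))
    stop("unlabeled internal node on the focal path")
  methods::new("Taxonomy", tree = tree, focalPath = pathLabs,
               cladeLeaves = cladeLeaves)
}

#' Read a taxonomy from Newick
#'
#' The Newick string must label internal nodes with unique clade names; the
#' focal path is the series of named clades from the root to `focalClade`
#' (e.g. the metazoan-like clade), along which emergence epochs are assigned.
#'
#' @param path Newick file (or a literal Newick string via `text`).
#' @param focalClade clade name terminating the focal path.
#' @param text optional Newick string instead of a file.
#' @return A [Taxonomy-class].
#' @export
readTaxonomy <- function(path = NULL, focalClade, text = NULL) {
  tree <- if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    ape::read.tree(path)
  } else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input")
  taxonomyFromPhylo(tree, focalClade)
}

#' Build a taxonomy from a structured clade -> children configuration
#'
#' `config` maps each clade name to a character vector of children, each
#' either another clade name or an organism. Cycles and duplicate clade names
#' are errors.
#'
#' @param config named list, clade -> children.
#' @param root name of the root clade.
#' @param focalClade clade name terminating the focal path.
#' @return A [Taxonomy-class].
#' @export
taxonomyFromConfig <- function(config, root, focalClade) {
  if (anyDuplicated(names(config)))
    stop("duplicate clade name: ",
         names(config)[duplicated(names(config))][1L])
  emit <- function(clade, seen) {
    if (clade %in% seen) stop("cycle detected at clade: ", clade)
    kids <- config[[clade]]
    if (is.null(kids)) return(clade)  # an organism leaf
    inner <- vapply(kids, emit, "", seen = c(seen, clade))
    paste0("(", paste(inner, collapse = ","), ")", clade)
  }
  nwk <- paste0(emit(root, character()), ";")
  readTaxonomy(text = nwk, focalClade = focalClade)
}

#' Clade path from the root to an organism
#'
#' @param tax a [Taxonomy-class].
#' @param org organism (tip label).
#' @return Character vector of named clades, root first.
#' @export
organismPath <- function(tax, org) {
  tree <- tax@tree
  ntip <- length(tree$tip.label)
  tip <- match(org, tree$tip.label)
  if (is.na(tip)) stop("organism not in taxonomy: ", org)
  nodes <- ape::nodepath(tree, ntip + 1L, tip)
  inner <- nodes[nodes > ntip]
  labs <- tree$node.label[inner - ntip]
  labs[!is.na(labs) & labs != ""]
}

# ---- interactions -----------------------------------------------------------

#' Read interaction records from a PSI-MI-TAB-like TSV
#'
#' Tab-delimited with one record per line; lines starting with `#` are
#' skipped. `columns` maps the fields to column indices (PSI-MI TAB 2.5
#' defaults: ids in 1/2, detection method in 7, source database in 13).
#'
#' @param path TSV file.
#' @param columns named integer vector with entries `a`, `b`, `method`,
#'   `source`.
#' @return data.frame with columns `proteinA`, `proteinB`, `method`,
#'   `sourceDb`, `selfLoop`.
#' @export
readInteractions <- function(path,
                             columns = c(a = 1L, b = 2L, method = 7L,
                                         source = 13L)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(proteinA = character(), proteinB = character(),
                      method = character(), sourceDb = character(),
                      selfLoop = logical()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(columns)
  getf <- function(p, i, ln, what) {
    if (length(p) < i)
      stop(sprintf("line %d: missing mapped column %d (%s)", ln, i, what))
    p[[i]]
  }
  rec <- lapply(seq_along(parts), function(k) {
    p <- parts[[k]]; ln <- lineNo[k]
    m <- getf(p, columns[["method"]], ln, "method")
    if (m == "" || m == "-")
      stop(sprintf("line %d: empty interaction detection method", ln))
    data.frame(proteinA = getf(p, columns[["a"]], ln, "a"),
               proteinB = getf(p, columns[["b"]], ln, "b"),
               method = m,
               sourceDb = getf(p, columns[["source"]], ln, "source"))
  })
  out <- do.call(rbind, rec)
  out$selfLoop <- out$proteinA == out$proteinB
  if (any(out$selfLoop))
    message(sum(out$selfLoop), " self-loop record(s) flagged")
  out
}

# ---- coordinates ------------------------------------------------------------

#' Read a structural model from PDB ATOM records
#'
#' Only `ATOM` records are parsed; hydrogens are dropped; alternate locations
#' other than blank or `A` are dropped. A non-numeric coordinate field is an
#' error reporting the offending line number.
#'
#' @param path PDB-format file (ATOM-record subset; no MODEL/ANISOU support).
#' @return A [StructureModel-class].
#' @export
readCoords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  atomLn <- which(startsWith(lines, "ATOM"))
  if (!length(atomLn)) stop("no ATOM records in ", path)
  for (ln in atomLn) {
    for (fld in list(c(31L, 38L, "x"), c(39L, 46L, "y"), c(47L, 54L, "z"))) {
      v <- suppressWarnings(as.numeric(substr(lines[ln], fld[1], fld[2])))
      if (is.na(v))
        stop(sprintf("line %d: non-numeric %s coordinate field", ln, fld[3]))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  alt <- a$alt
  a <- a[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  isH <- (!is.na(a$elesy) & a$elesy == "H") |
    grepl("^[0-9]*H", a$elety)
  a <- a[!isH, , drop = FALSE]
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno, resname = a$resid, atom = a$elety,
                      x = a$x, y = a$y, z = a$z)
  for (ch in unique(atoms$chain)) {
    r <- rle(atoms$resno[atoms$chain == ch])$values
    if (any(diff(r) <= 0))
      stop("residue numbering not strictly increasing in chain ", ch)
  }
  methods::new("StructureModel", atoms = atoms)
}
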