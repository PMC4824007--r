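#' Map reference residue positions to alignment columns
#'
#' Column `c` maps to reference position `p` iff the reference row's `p`-th
#' non-gap character sits in column `c` (all coordinates 1-based).
#'
#' @param aln a [SeedAlignment-class].
#' @param refId row id of the reference sequence.
#' @param positions 1-based residue positions in the ungapped reference.
#' @return Integer vector of alignment column indices.
#' @export
mapReferencePositions <- function(aln, refId, positions) {
  rows <- as.character(sequences(aln))
  if (!refId %in% names(rows)) stop("reference row not in alignment: ", refId)
  chars <- strsplit(rows[[refId]], "", fixed = TRUE)[[1L]]
  nonGap <- which(chars != "-")
  bad <- positions < 1L | positions > length(nonGap)
  if (any(bad))
    stop("position out of reference range (1..", length(nonGap), "): ",
         paste(positions[bad], collapse = ", "))
  nonGap[positions]
}

#' Column conservation profile (sequence-logo matrix)
#'
#' Per selected column: residue frequencies over the non-gap characters,
#' Shannon entropy H (bits) and information content
#' `IC = log2(20) - H - e_n`, with the small-sample correction
#' `e_n = 19 / (2 ln(2) n)` (`n` = non-gap count; correction togglable,
#' IC clipped at 0 from below). Gaps are excluded from the denominators;
#' an all-gap column is an error. X characters are excluded from the
#' 20-letter frequency basis.
#'
#' @param aln a [SeedAlignment-class].
#' @param columns alignment column indices.
#' @param correction apply the small-sample correction.
#' @param refPositions optional vector (same length as `columns`) of mapped
#'   reference positions to carry through.
#' @return List with `freq` (20 x k matrix) and `stats` (data.frame with
#'   `column`, `refPosition`, `n`, `entropy`, `ic`, `consensus`).
#' @export
conservationProfile <- function(aln, columns, correction = TRUE,
                                refPositions = NULL) {
  rows <- as.character(sequences(aln))
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  k <- length(columns)
  freq <- matrix(0, 20L, k, dimnames = list(AA20, columns))
  stats <- data.frame(column = columns,
                      refPosition = if (is.null(refPositions)) NA_integer_
                                    else refPositions,
                      n = NA_integer_, entropy = NA_real_, ic = NA_real_,
                      consensus = NA_character_)
  for (i in seq_len(k)) {
    col <- chars[, columns[i]]
    col <- col[col != "-"]
    if (!length(col)) stop("all-gap column: ", columns[i])
    col <- col[col %in% AA20]
    if (!length(col)) stop("column ", columns[i], " has only X characters")
    n <- length(col)
    f <- as.numeric(table(factor(col, levels = AA20))) / n
    freq[, i] <- f
    nz <- f[f > 0]
    H <- -sum(nz * log2(nz))
    en <- if (correction) 19 / (2 * log(2) * n) else 0
    stats$n[i] <- n
    stats$entropy[i] <- H
    stats$ic[i] <- max(0, log2(20) - H - en)
    stats$consensus[i] <- AA20[which.max(f)]
  }
  list(freq = freq, stats = stats)
}

# charged-group and side-chain atom-name sets for contact classification
.chargedAtoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                      HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2"),
                      GLU = c("OE1", "OE2"))
.positiveRes <- c("LYS", "ARG", "HIS")
.negativeRes <- c("ASP", "GLU")
.hydrophobicRes <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "TYR", "PRO")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

normResName <- function(r) {
  r <- toupper(r)
  ifelse(nchar(r) == 1L, unname(.aa1to3[r]), r)
}

.minDist <- function(xyzA, xyzB) {
  if (!nrow(xyzA) || !nrow(xyzB)) return(Inf)
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * (xyzA %*% t(xyzB))
  sqrt(max(0, min(d2)))
}

.resAtoms <- function(model, chain, resno) {
  a <- atomTable(model)
  sel <- a[a$chain == chain & a$resno == resno, , drop = FALSE]
  if (!nrow(sel))
    stop(sprintf("residue %s/%d not present in the model", chain, resno))
  sel
}

#' Classify a residue contact
#'
#' `electrostatic` iff the residues form an opposite-charge pair (K/R/H
#' versus D/E) whose charged-group atoms come within `chargedCutoff`;
#' `hydrophobic` iff both residues are hydrophobic (A/V/L/I/M/F/W/Y/P) with
#' side-chain carbons within `hydroCutoff`; `other` otherwise.
#'
#' @param resA,resB residue names (3-letter or 1-letter).
#' @param atomsA,atomsB data.frames with columns `atom`, `x`, `y`, `z` for
#'   each residue's heavy atoms.
#' @param chargedCutoff,hydroCutoff distance cutoffs in Angstrom.
#' @return `"electrostatic"`, `"hydrophobic"` or `"other"`.
#' @export
classifyContact <- function(resA, resB, atomsA, atomsB,
                            chargedCutoff = 4.0, hydroCutoff = 4.5) {
  resA <- normResName(resA); resB <- normResName(resB)
  xyz <- function(df, keep) as.matrix(df[df$atom %in% keep,
                                         c("x", "y", "z"), drop = FALSE])
  opposite <- (resA %in% .positiveRes && resB %in% .negativeRes) ||
    (resA %in% .negativeRes && resB %in% .positiveRes)
  if (opposite) {
    dA <- xyz(atomsA, .chargedAtoms[[resA]])
    dB <- xyz(atomsB, .chargedAtoms[[resB]])
    if (.minDist(dA, dB) <= chargedCutoff) return("electrostatic")
  }
  if (resA %in% .hydrophobicRes && resB %in% .hydrophobicRes) {
    scC <- function(df) as.matrix(
      df[grepl("^C", df$atom) & !df$atom %in% c("C", "CA"),
         c("x", "y", "z"), drop = FALSE])
    if (.minDist(scC(atomsA), scC(atomsB)) <= hydroCutoff)
      return("hydrophobic")
  }
  "other"
}

#' Detect and classify residue contacts
#'
#' For each queried residue pair, the minimal heavy-atom distance is
#' computed; the pair is a contact iff that distance is at most `tau`
#' (default 4.5 Angstrom), and contacts are classified with
#' [classifyContact()]. Symmetric in pair order; a missing residue is an
#' error naming chain and position.
#'
#' @param model a [StructureModel-class].
#' @param pairs data.frame with columns `chainA`, `resnoA`, `chainB`,
#'   `resnoB`.
#' @param tau contact distance cutoff in Angstrom.
#' @param chargedCutoff,hydroCutoff classification cutoffs.
#' @return data.frame with per-pair `distance`, `contact` and `class`.
#' @export
residueContacts <- function(model, pairs, tau = 4.5,
                            chargedCutoff = 4.0, hydroCutoff = 4.5) {
  stopifnot(tau > 0)
  out <- pairs
  out$distance <- NA_real_
  out$contact <- NA
  out$class <- NA_character_
  for (k in seq_len(nrow(pairs))) {
    A <- .resAtoms(model, pairs$chainA[k], pairs$resnoA[k])
    B <- .resAtoms(model, pairs$chainB[k], pairs$resnoB[k])
    d <- .minDist(as.matrix(A[, c("x", "y", "z")]),
                  as.matrix(B[, c("x", "y", "z")]))
    out$distance[k] <- d
    out$contact[k] <- d <= tau
    out$class[k] <- if (d <= tau)
      classifyContact(A$resname[1L], B$resname[1L], A, B,
                      chargedCutoff, hydroCutoff)
    else "other"
  }
  out
}
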