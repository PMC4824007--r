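#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout (`#` comments, a header row of
#' residue letters, one row per residue). The X row and column are forced to
#' zero so that ambiguous residues neither reward nor penalise alignment.
#'
#' @param path matrix file.
#' @return Symmetric integer matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- matrix(0L, length(rows), length(cols),
              dimnames = list(vapply(rows, `[`, "", 1L), cols))
  for (k in seq_along(rows))
    m[k, ] <- as.integer(rows[[k]][-1])
  if (!identical(rownames(m), colnames(m)))
    stop("matrix rows and columns disagree")
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  if (!isSymmetric(unname(m))) stop("substitution matrix must be symmetric")
  m
}

.pkgCache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 matrix
#'
#' BLOSUM62 as shipped with the package (NCBI text format), with X scoring 0
#' against everything.
#'
#' @return Integer substitution matrix.
#' @export
blosum62 <- function() {
  if (is.null(.pkgCache$blosum62))
    .pkgCache$blosum62 <- readSubstitutionMatrix(
      system.file("extdata", "BLOSUM62.txt", package = "CMETrace",
                  mustWork = TRUE))
  .pkgCache$blosum62
}

alignResult <- function(score, alignedA = "", alignedB = "",
                        startA = NA_integer_, endA = NA_integer_,
                        startB = NA_integer_, endB = NA_integer_) {
  list(score = score, alignedA = alignedA, alignedB = alignedB,
       startA = startA, endA = endA, startB = startB, endB = endB)
}

.pairAlign <- function(a, b, mat, gapOpen, gapExtend, type) {
  if (nchar(a) == 0L || nchar(b) == 0L) {
    if (type == "local") return(alignResult(0))
    n <- max(nchar(a), nchar(b))
    if (n == 0L) return(alignResult(0, "", "", 1L, 0L, 1L, 0L))
    gap <- strrep("-", n)
    long <- if (nchar(a) > 0L) a else b
    return(alignResult(-(gapOpen + n * gapExtend),
                       if (nchar(a)) a else gap, if (nchar(b)) b else gap,
                       1L, nchar(a), 1L, nchar(b)))
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = type, substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend)
  sc <- Biostrings::score(al)
  if (type == "local" && sc < 0) return(alignResult(0))
  p <- Biostrings::alignedPattern(al)[[1L]]
  s <- Biostrings::alignedSubject(al)[[1L]]
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  alignResult(sc, as.character(p), as.character(s),
              Biostrings::start(pat), Biostrings::end(pat),
              Biostrings::start(sub), Biostrings::end(sub))
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Optimal global alignment score under the affine cost
#' `gap(k) = gapOpen + k * gapExtend`, with end gaps penalised.
#'
#' @param a,b protein sequences (strings over the 20-letter alphabet plus X;
#'   either may be empty).
#' @param mat substitution matrix (default [blosum62()]).
#' @param gapOpen,gapExtend non-negative gap parameters.
#' @return List with `score`, gapped `alignedA`/`alignedB` and 1-based
#'   inclusive `startA`/`endA`/`startB`/`endB`.
#' @examples
#' globalAlign("ACDE", "ACDE")$score  # 24
#' @export
globalAlign <- function(a, b, mat = blosum62(), gapOpen = 11, gapExtend = 1)
  .pairAlign(a, b, mat, gapOpen, gapExtend, "global")

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Optimal local alignment score; when no pair of substrings scores
#' positively the empty alignment (score 0) is returned.
#'
#' @inheritParams globalAlign
#' @return As [globalAlign()]; `score >= 0`.
#' @export
localAlign <- function(a, b, mat = blosum62(), gapOpen = 11, gapExtend = 1)
  .pairAlign(a, b, mat, gapOpen, gapExtend, "local")

#' Rank a reference proteome against a query sequence
#'
#' Scores every reference record against the query by Smith-Waterman with
#' BLOSUM62 and BLAST-protein gap defaults (open 11, extend 1) and returns the
#' records in descending score order, ties broken by lexicographic id. This is
#' the ranking engine of the reciprocal-best-hit test.
#'
#' @param query protein sequence (string).
#' @param ref a [Proteome-class] (non-empty).
#' @param mat,gapOpen,gapExtend alignment parameters.
#' @return data.frame with columns `id` and `score`, best first.
#' @export
rankProteome <- function(query, ref, mat = blosum62(), gapOpen = 11,
                         gapExtend = 1) {
  seqs <- sequences(ref)
  if (!length(seqs)) stop("reference proteome is empty")
  scores <- Biostrings::pairwiseAlignment(
    pattern = seqs, subject = query, type = "local",
    substitutionMatrix = mat, gapOpening = gapOpen,
    gapExtension = gapExtend, scoreOnly = TRUE)
  scores <- pmax(scores, 0)
  ids <- names(seqs)
  o <- order(-scores, ids, method = "radix")
  data.frame(id = ids[o], score = scores[o])
}
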