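#' @useDynLib CMETrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# The 20-letter amino-acid alphabet used throughout; 'X' is the only extra
# symbol and always emits/scores as background.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid frequencies
#'
#' The BLOSUM62 marginal amino-acid frequencies, used as the null (background)
#' model for profile scoring, e-value calibration and synthetic sequence
#' generation.
#'
#' @return Named numeric vector of length 20 summing to 1, in alphabetical
#'   one-letter order.
#' @export
aaBackground <- function() {
  q <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  q / sum(q)
}

# residue characters -> 0-based integer codes for the DP kernels (X = 20)
aaToInt <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- match(v, AA20) - 1L
  i[v == "X"] <- 20L
  if (anyNA(i))
    stop("sequence contains characters outside the amino-acid alphabet: ",
         paste(unique(v[is.na(i)]), collapse = ", "))
  i
}

intToAa <- function(i) {
  out <- c(AA20, "X")[i + 1L]
  paste(out, collapse = "")
}

# validate a protein sequence (20 AA + X); returns invisibly or stops with the
# 1-based position of the first illegal character
checkAASequence <- function(seq, id = "<sequence>") {
  bad <- regexpr(sprintf("[^%sX]", paste(AA20, collapse = "")), seq)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 substr(seq, bad, bad), bad, id))
  invisible(TRUE)
}

# deterministic child RNG seed derived from a parent seed and a label
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

# run an expression with a temporary RNG seed, restoring the RNG state after
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# write a data.frame as TSV atomically (write to tmp, then rename)
writeTsvAtomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
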