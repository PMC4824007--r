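#' Low-level ProfileHMM constructor
#'
#' Builds a [ProfileHMM-class] directly from emission and transition
#' parameters. Defaults give a pure match-chain ("no-indel") model:
#' begin -> M_1 -> ... -> M_M -> end with probability 1, which is the
#' configuration used by closed-form tests (for such a model in glocal mode
#' the probabilities of all sequences of length M sum to 1).
#'
#' @param matchEmis `M x 20` matrix of match emission probabilities.
#' @param id,seedId identifiers.
#' @param bg background distribution.
#' @param tMM,tMI,tMD,tIM,tII,tDM,tDD,tBM,tBI,tBD transition probabilities;
#'   see [ProfileHMM-class] for the indexing convention. Defaults are the
#'   no-indel chain.
#' @return A [ProfileHMM-class].
#' @export
makeProfileHMM <- function(matchEmis, id = "profile", seedId = "none",
                           bg = aaBackground(),
                           tMM = NULL, tMI = NULL, tMD = NULL,
                           tIM = NULL, tII = NULL, tDM = NULL, tDD = NULL,
                           tBM = 1, tBI = 0, tBD = 0) {
  M <- nrow(matchEmis)
  if (is.null(tMM)) tMM <- rep(1, M)
  if (is.null(tMI)) tMI <- rep(0, M)
  if (is.null(tMD)) tMD <- rep(0, M)
  if (is.null(tIM)) tIM <- rep(1, M + 1)
  if (is.null(tII)) tII <- rep(0, M + 1)
  if (is.null(tDM)) tDM <- rep(1, M)
  if (is.null(tDD)) tDD <- rep(0, M)
  colnames(matchEmis) <- AA20
  methods::new("ProfileHMM", id = id, seedId = seedId, M = as.integer(M),
               matchEmis = matchEmis, bg = bg,
               tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
               tDM = tDM, tDD = tDD, tBM = tBM, tBI = tBI, tBD = tBD)
}

#' Build a profile HMM from a seed alignment
#'
#' Columns with less than 50% gap characters become match states (exactly 50%
#' is an insert column). Match emissions are smoothed with
#' background-proportional pseudocounts of total mass `pseudoTotal`;
#' transitions are estimated from the per-row state paths with a Laplace
#' pseudocount of `transPseudo` on every allowed transition. Insert emissions
#' are fixed to the background. X residues are excluded from emission counts
#' (they score as background everywhere).
#'
#' @param aln a [SeedAlignment-class] with at least 2 rows.
#' @param id profile id; defaults to the alignment id.
#' @param pseudoTotal total emission pseudocount mass.
#' @param transPseudo Laplace pseudocount for transitions.
#' @param matchGapFrac gap-fraction threshold below which a column is a match
#'   column.
#' @param bg background distribution.
#' @return A [ProfileHMM-class].
#' @export
buildProfile <- function(aln, id = NULL, pseudoTotal = 1.0,
                         transPseudo = 0.1, matchGapFrac = 0.5,
                         bg = aaBackground()) {
  rows <- as.character(sequences(aln))
  if (length(rows) < 2L) stop("seed alignment needs >= 2 rows")
  if (is.null(id)) id <- aln@id
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  W <- ncol(chars)
  gapFrac <- colMeans(chars == "-")
  isMatch <- gapFrac < matchGapFrac
  M <- sum(isMatch)
  if (M < 1L) stop("alignment has no match columns")
  matchCols <- which(isMatch)

  # emissions
  em <- matrix(0, M, 20L, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- chars[, matchCols[k]]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    em[k, ] <- (as.numeric(cnt) + bg * pseudoTotal) /
      (length(col) + pseudoTotal)
  }

  # transition counts from per-row state paths (Plan7: no I<->D transitions;
  # the rare seed transitions of that kind are not counted)
  cMM <- cMI <- cMD <- numeric(M)         # index j = from position j (j = M -> end)
  cIM <- cII <- numeric(M + 1L)           # I_0..I_M
  cDM <- cDD <- numeric(M)
  cB <- c(M = 0, I = 0, D = 0)
  colPos <- cumsum(isMatch)               # match index at/before each column
  for (r in seq_len(nrow(chars))) {
    prev <- "B"; prevJ <- 0L
    for (w in seq_len(W)) {
      ch <- chars[r, w]
      if (isMatch[w]) {
        st <- if (ch == "-") "D" else "M"
        j <- colPos[w]
      } else {
        if (ch == "-") next
        st <- "I"
        j <- colPos[w]
      }
      if (prev == "B") {
        if (st == "I" && j == 0L) cB["I"] <- cB["I"] + 1
        else if (st == "M" && j == 1L) cB["M"] <- cB["M"] + 1
        else if (st == "D" && j == 1L) cB["D"] <- cB["D"] + 1
      } else if (prev == "M") {
        if (st == "M") cMM[prevJ] <- cMM[prevJ] + 1
        else if (st == "I") cMI[prevJ] <- cMI[prevJ] + 1
        else cMD[prevJ] <- cMD[prevJ] + 1
      } else if (prev == "I") {
        if (st == "M") cIM[prevJ + 1L] <- cIM[prevJ + 1L] + 1
        else if (st == "I") cII[prevJ + 1L] <- cII[prevJ + 1L] + 1
        # I -> D not modelled
      } else {  # prev == "D"
        if (st == "M") cDM[prevJ] <- cDM[prevJ] + 1
        else if (st == "D") cDD[prevJ] <- cDD[prevJ] + 1
        # D -> I not modelled
      }
      prev <- st; prevJ <- j
    }
    # exit to end
    if (prev == "M") cMM[prevJ] <- cMM[prevJ] + 1
    else if (prev == "I") cIM[prevJ + 1L] <- cIM[prevJ + 1L] + 1
    else if (prev == "D") cDM[prevJ] <- cDM[prevJ] + 1
  }

  lp <- transPseudo
  norm2 <- function(a, b) { s <- a + b; list(a / s, b / s) }
  norm3 <- function(a, b, c) { s <- a + b + c; list(a / s, b / s, c / s) }
  tMM <- tMI <- tMD <- numeric(M)
  for (j in seq_len(M)) {
    if (j < M) {
      v <- norm3(cMM[j] + lp, cMI[j] + lp, cMD[j] + lp)
      tMM[j] <- v[[1]]; tMI[j] <- v[[2]]; tMD[j] <- v[[3]]
    } else {
      v <- norm2(cMM[j] + lp, cMI[j] + lp)  # M_M -> {end, I_M}
      tMM[j] <- v[[1]]; tMI[j] <- v[[2]]; tMD[j] <- 0
    }
  }
  v <- norm2(cIM + lp, cII + lp)
  tIM <- v[[1]]; tII <- v[[2]]
  tDM <- tDD <- numeric(M)
  for (j in seq_len(M)) {
    if (j < M) {
      v <- norm2(cDM[j] + lp, cDD[j] + lp)
      tDM[j] <- v[[1]]; tDD[j] <- v[[2]]
    } else { tDM[j] <- 1; tDD[j] <- 0 }
  }
  v <- norm3(cB[["M"]] + lp, cB[["I"]] + lp, cB[["D"]] + lp)
  makeProfileHMM(em, id = id, seedId = aln@id, bg = bg,
                 tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
                 tDM = tDM, tDD = tDD,
                 tBM = v[[1]], tBI = v[[2]], tBD = v[[3]])
}

# log-space parameter bundle for the DP kernels
.phmmParams <- function(p) {
  lq <- log(p@bg)
  lem <- cbind(log(p@matchEmis) - matrix(lq, p@M, 20L, byrow = TRUE), 0)
  list(lem = lem,
       ltMM = log(p@tMM), ltMI = log(p@tMI), ltMD = log(p@tMD),
       ltIM = log(p@tIM), ltII = log(p@tII),
       ltDM = log(p@tDM), ltDD = log(p@tDD),
       ltBM = log(p@tBM), ltBI = log(p@tBI), ltBD = log(p@tBD))
}

.forwardInt <- function(pp, seqInt, local) {
  .phmmForward(pp$lem, pp$ltMM, pp$ltMI, pp$ltMD, pp$ltIM, pp$ltII,
               pp$ltDM, pp$ltDD, pp$ltBM, pp$ltBI, pp$ltBD,
               seqInt, local)
}

.forwardBatchInt <- function(pp, seqList, local) {
  .phmmForwardBatch(pp$lem, pp$ltMM, pp$ltMI, pp$ltMD, pp$ltIM, pp$ltII,
                    pp$ltDM, pp$ltDD, pp$ltBM, pp$ltBI, pp$ltBD,
                    seqList, local)
}

#' Forward log-odds score of a sequence under a profile
#'
#' Sum over all state paths of the profile/background odds, in bits
#' (`log2 P(s | profile) / P(s | background)`), computed in log space. In the
#' default local mode the profile matches any subsequence (uniform entry over
#' match states, free exit, cost-free background flanks); in glocal mode the
#' model must account for the whole sequence. X residues emit the background
#' everywhere (log-odds contribution 0).
#'
#' @param p a [ProfileHMM-class].
#' @param s protein sequence (non-empty string).
#' @param mode `"local"` (single-hit subsequence match, the scanning mode) or
#'   `"glocal"` (whole-sequence, used by closed-form tests).
#' @return Bit score (can be `-Inf` in local mode if the profile cannot emit
#'   any subsequence).
#' @export
forwardScore <- function(p, s, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  if (nchar(s) == 0L) stop("sequence must be non-empty")
  .forwardInt(.phmmParams(p), aaToInt(s), mode == "local")
}

#' Viterbi alignment of a sequence to a profile
#'
#' Best single state path and its log-odds bit score; the envelope is the
#' 1-based span of sequence positions consumed by match/insert states.
#'
#' @inheritParams forwardScore
#' @return List with `bits`, `path` (data.frame: `state` in M/I/D, profile
#'   `position`, sequence `residue` or NA for deletes), `envStart`, `envEnd`.
#' @export
viterbiAlign <- function(p, s, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  if (nchar(s) == 0L) stop("sequence must be non-empty")
  r <- .phmmViterbi(.phmmParams(p)$lem, log(p@tMM), log(p@tMI), log(p@tMD),
                    log(p@tIM), log(p@tII), log(p@tDM), log(p@tDD),
                    log(p@tBM), log(p@tBI), log(p@tBD),
                    aaToInt(s), mode == "local")
  list(bits = r$bits,
       path = data.frame(state = c("M", "I", "D")[r$states + 1L],
                         position = r$positions, residue = r$residues),
       envStart = r$envStart, envEnd = r$envEnd)
}

# draw n background sequences as 0-based integer vectors
.sampleNullSeqs <- function(n, lengths, bg) {
  lens <- if (length(lengths) == 1L) rep(lengths, n)
          else sample(lengths, n, replace = TRUE)
  lapply(lens, function(L) sample.int(20L, L, replace = TRUE, prob = bg) - 1L)
}

# Gumbel (max) ML fit; moments start, degenerate variance is an error
fitGumbel <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("degenerate null score variance")
  lambda0 <- pi / (s * sqrt(6))
  mu0 <- mean(x) - 0.5772156649015329 / lambda0
  nll <- function(par) {
    lam <- exp(par[2]); z <- lam * (x - par[1])
    -sum(log(lam) - z - exp(-z))
  }
  fit <- stats::optim(c(mu0, log(lambda0)), nll, method = "BFGS")
  list(mu = fit$par[1], lambda = exp(fit$par[2]))
}

#' Calibrate e-values for a profile
#'
#' Scores `nNull` i.i.d. background sequences (lengths resampled from
#' `lenDist`) with the local forward algorithm and fits a Gumbel
#' (extreme-value) distribution to the null scores by maximum likelihood
#' (method-of-moments start). Deterministic given `seed`.
#'
#' @param p a [ProfileHMM-class].
#' @param nNull number of null sequences (>= 100).
#' @param lenDist integer vector of sequence lengths to resample from,
#'   typically the empirical lengths of the target proteome.
#' @param seed RNG seed.
#' @return An [EvalueCalibration-class].
#' @export
calibrateProfile <- function(p, nNull = 1000L, lenDist = 100:400,
                             seed = 1L) {
  if (nNull < 100L) stop("nNull must be >= 100")
  pp <- .phmmParams(p)
  scores <- withSeed(seed, {
    seqs <- .sampleNullSeqs(nNull, lenDist, p@bg)
    .forwardBatchInt(pp, seqs, TRUE)
  })
  fit <- fitGumbel(scores)
  methods::new("EvalueCalibration", profileId = p@id, mu = fit$mu,
               lambda = fit$lambda, nNull = as.integer(nNull),
               seed = as.integer(seed))
}

#' Gumbel tail p-value of a bit score
#'
#' @param S bit score(s).
#' @param cal an [EvalueCalibration-class].
#' @return `P(score >= S)` under the fitted null.
#' @export
gumbelPvalue <- function(S, cal) {
  z <- cal@lambda * (S - cal@mu)
  # 1 - exp(-exp(-z)), stable for both tails
  -expm1(-exp(-z))
}

#' E-value of a bit score
#'
#' `E = dbSize * P(score >= S)` under the calibrated null: the expected number
#' of equal-or-better hits among `dbSize` random sequences. Monotone
#' decreasing in `S`, linear in `dbSize`.
#'
#' @param S bit score(s).
#' @param cal an [EvalueCalibration-class].
#' @param dbSize number of sequences in the scanned database.
#' @return E-value(s).
#' @export
hitEvalue <- function(S, cal, dbSize) dbSize * gumbelPvalue(S, cal)

#' Scan a proteome with a calibrated profile
#'
#' Computes the local forward bit score and e-value for every sequence
#' (database size = number of sequences in the proteome, following the usual
#' search-tool convention) and returns the hits with `E <= threshold`, sorted
#' by ascending e-value (ties by id). Envelopes come from the Viterbi path.
#'
#' @param p a [ProfileHMM-class].
#' @param prot a [Proteome-class]; empty proteome yields an empty hit table.
#' @param cal an [EvalueCalibration-class] for `p`.
#' @param threshold e-value inclusion threshold.
#' @return data.frame with columns `profile`, `id`, `bits`, `evalue`,
#'   `envStart`, `envEnd`.
#' @export
scanProteome <- function(p, prot, cal, threshold = 0.01) {
  seqs <- sequences(prot)
  empty <- data.frame(profile = character(), id = character(),
                      bits = numeric(), evalue = numeric(),
                      envStart = integer(), envEnd = integer())
  if (!length(seqs)) return(empty)
  pp <- .phmmParams(p)
  ints <- lapply(as.character(seqs), aaToInt)
  bits <- .forwardBatchInt(pp, ints, TRUE)
  ev <- hitEvalue(bits, cal, length(seqs))
  keep <- which(ev <= threshold)
  if (!length(keep)) return(empty)
  env <- t(vapply(keep, function(k) {
    v <- .phmmViterbi(pp$lem, pp$ltMM, pp$ltMI, pp$ltMD, pp$ltIM, pp$ltII,
                      pp$ltDM, pp$ltDD, pp$ltBM, pp$ltBI, pp$ltBD,
                      ints[[k]], TRUE)
    c(v$envStart, v$envEnd)
  }, integer(2)))
  out <- data.frame(profile = p@id, id = names(seqs)[keep],
                    bits = bits[keep], evalue = ev[keep],
                    envStart = env[, 1], envEnd = env[, 2])
  out[order(out$evalue, out$id, method = "radix"), , drop = FALSE]
}

#' Annotate the domain architecture of a protein
#'
#' Scans the sequence with each calibrated domain profile, iteratively
#' masking the envelope of the best hit so that repeated domains (e.g. tandem
#' SH3 copies) are all recovered despite the single-hit scoring model. All
#' hits with `E <= threshold` are pooled, overlaps are resolved greedily by
#' ascending e-value (the better hit survives, any worse hit sharing a
#' residue is dropped), and the survivors are reported sorted by start.
#'
#' @param seq protein sequence (string).
#' @param domainProfiles named list of [ProfileHMM-class] objects.
#' @param cals named list of matching [EvalueCalibration-class] objects.
#' A hit must also cover at least `minCoverage` of the domain model (span of
#' matched model positions over model length): chance few-residue matches in
#' disordered regions can clear the e-value threshold but never represent a
#' domain, and fragment suppression is the standard guard against them.
#'
#' @param threshold domain inclusion e-value threshold.
#' @param dbSize database size used for domain e-values (default 1: the
#'   single scanned sequence).
#' @param maxCopies maximum copies of one domain recovered per sequence.
#' @param minCoverage minimum fraction of model positions a hit must span.
#' @return data.frame with columns `domain`, `start`, `end`, `evalue`,
#'   sorted by `start` (zero rows when nothing passes).
#' @export
annotateDomains <- function(seq, domainProfiles, cals, threshold = 0.01,
                            dbSize = 1L, maxCopies = 12L,
                            minCoverage = 0.5) {
  hits <- list()
  for (nm in names(domainProfiles)) {
    p <- domainProfiles[[nm]]
    cal <- cals[[nm]]
    if (is.null(cal)) stop("no calibration for domain profile ", nm)
    pp <- .phmmParams(p)
    cur <- aaToInt(seq)
    for (it in seq_len(maxCopies)) {
      bits <- .forwardInt(pp, cur, TRUE)
      ev <- hitEvalue(bits, cal, dbSize)
      if (!is.finite(bits) || ev > threshold) break
      v <- .phmmViterbi(pp$lem, pp$ltMM, pp$ltMI, pp$ltMD, pp$ltIM, pp$ltII,
                        pp$ltDM, pp$ltDD, pp$ltBM, pp$ltBI, pp$ltBD,
                        cur, TRUE)
      if (is.na(v$envStart)) break
      mpos <- v$positions[v$states == 0L]  # model positions of match states
      coverage <- (max(mpos) - min(mpos) + 1L) / p@M
      if (coverage >= minCoverage)
        hits[[length(hits) + 1L]] <-
          data.frame(domain = nm, start = v$envStart, end = v$envEnd,
                     evalue = ev)
      cur[v$envStart:v$envEnd] <- 20L  # mask with X (fragments too)
    }
  }
  if (!length(hits))
    return(data.frame(domain = character(), start = integer(),
                      end = integer(), evalue = numeric()))
  df <- do.call(rbind, hits)
  df <- df[order(df$evalue, df$start, method = "radix"), , drop = FALSE]
  kept <- logical(0)
  sel <- integer(0)
  for (k in seq_len(nrow(df))) {
    ov <- FALSE
    for (j in sel)
      if (df$start[k] <= df$end[j] && df$end[k] >= df$start[j]) { ov <- TRUE; break }
    if (!ov) sel <- c(sel, k)
  }
  df <- df[sel, , drop = FALSE]
  df <- df[order(df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}
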