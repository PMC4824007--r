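# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's DP code paths: profile scores come from explicit path
# enumeration, alignment scores from enumeration of alignment strings, motif
# counts from per-position anchored matching.

# ---- profile HMM path-enumeration oracle -----------------------------------

oraclePHMM <- function(p, s, mode = "glocal") {
  M <- profileLength(p)
  em <- matchEmissions(p)
  q <- background(p)
  sv <- strsplit(s, "")[[1]]
  L <- length(sv)
  ratio <- function(j, i) {
    a <- sv[i]
    if (a == "X") return(1)
    em[j, a] / q[[a]]
  }
  tMM <- p@tMM; tMI <- p@tMI; tMD <- p@tMD
  tIM <- p@tIM; tII <- p@tII; tDM <- p@tDM; tDD <- p@tDD
  paths <- c()
  if (mode == "glocal") {
    rec <- function(state, j, i, w) {
      if (w == 0) return()
      if (state == "E") {
        if (i == L + 1) paths[[length(paths) + 1]] <<- w
        return()
      }
      if (state %in% c("M", "I")) {
        if (i > L) return()
        if (state == "M") w <- w * ratio(j, i)
      }
      if (state == "B") {
        rec("M", 1, i, w * p@tBM)
        rec("I", 0, i, w * p@tBI)
        rec("D", 1, i, w * p@tBD)
      } else if (state == "M") {
        i2 <- i + 1
        if (j < M) {
          rec("M", j + 1, i2, w * tMM[j])
          rec("I", j, i2, w * tMI[j])
          rec("D", j + 1, i2, w * tMD[j])
        } else {
          rec("E", M, i2, w * tMM[M])
          rec("I", M, i2, w * tMI[M])
        }
      } else if (state == "I") {
        i2 <- i + 1
        if (j < M) {
          rec("M", j + 1, i2, w * tIM[j + 1])
          rec("I", j, i2, w * tII[j + 1])
        } else {
          rec("E", M, i2, w * tIM[M + 1])
          rec("I", M, i2, w * tII[M + 1])
        }
      } else if (state == "D") {
        if (j < M) {
          rec("M", j + 1, i, w * tDM[j])
          rec("D", j + 1, i, w * tDD[j])
        } else {
          rec("E", M, i, w * tDM[M])
        }
      }
    }
    rec("B", 0, 1, 1)
  } else {
    rec <- function(state, j, i, w) {
      if (w == 0) return()
      if (state %in% c("M", "I")) {
        if (i > L) return()
        if (state == "M") w <- w * ratio(j, i)
      }
      if (state == "M") paths[[length(paths) + 1]] <<- w  # free exit
      i2 <- if (state == "D") i else i + 1
      if (j < M) {
        if (state == "M") {
          rec("M", j + 1, i2, w * tMM[j])
          rec("I", j, i2, w * tMI[j])
          rec("D", j + 1, i2, w * tMD[j])
        } else if (state == "I") {
          rec("M", j + 1, i2, w * tIM[j + 1])
          rec("I", j, i2, w * tII[j + 1])
        } else {
          rec("M", j + 1, i, w * tDM[j])
          rec("D", j + 1, i, w * tDD[j])
        }
      }
    }
    for (k in seq_len(M)) for (i0 in seq_len(L)) rec("M", k, i0, 1 / M)
  }
  if (!length(paths)) return(list(forward = -Inf, viterbi = -Inf))
  list(forward = log2(sum(unlist(paths))),
       viterbi = log2(max(unlist(paths))))
}

randomProfile <- function(M) {
  em <- matrix(stats::rgamma(M * 20, 1), M, 20)
  em <- em / rowSums(em)
  r3 <- function() { x <- stats::rgamma(3, 1); x / sum(x) }
  r2 <- function() { x <- stats::rgamma(2, 1); x / sum(x) }
  tMM <- tMI <- tMD <- numeric(M)
  for (j in seq_len(M)) {
    if (j < M) { v <- r3(); tMM[j] <- v[1]; tMI[j] <- v[2]; tMD[j] <- v[3] }
    else { v <- r2(); tMM[j] <- v[1]; tMI[j] <- v[2] }
  }
  tIM <- tII <- numeric(M + 1)
  for (j in seq_len(M + 1)) { v <- r2(); tIM[j] <- v[1]; tII[j] <- v[2] }
  tDM <- tDD <- numeric(M)
  for (j in seq_len(M)) {
    if (j < M) { v <- r2(); tDM[j] <- v[1]; tDD[j] <- v[2] }
    else { tDM[j] <- 1 }
  }
  v <- r3()
  makeProfileHMM(em, bg = aaBackground(), tMM = tMM, tMI = tMI, tMD = tMD,
                 tIM = tIM, tII = tII, tDM = tDM, tDD = tDD,
                 tBM = v[1], tBI = v[2], tBD = v[3])
}

# ---- alignment enumeration oracle ------------------------------------------

.alnTemplates <- new.env(parent = emptyenv())

# all op sequences ("M","A","B") aligning la letters of a with lb of b
alignmentTemplates <- function(la, lb) {
  key <- paste(la, lb)
  if (!is.null(.alnTemplates[[key]])) return(.alnTemplates[[key]])
  res <- list()
  rec <- function(i, j, ops) {
    if (i == la && j == lb) { res[[length(res) + 1]] <<- ops; return() }
    if (i < la && j < lb) rec(i + 1, j + 1, c(ops, "M"))
    if (i < la) rec(i + 1, j, c(ops, "A"))       # gap in b
    if (j < lb) rec(i, j + 1, c(ops, "B"))       # gap in a
  }
  rec(0L, 0L, character())
  .alnTemplates[[key]] <- res
  res
}

affineAlnScore <- function(av, bv, ops, mat, go, ge) {
  s <- 0; i <- 0L; j <- 0L; prev <- ""
  for (op in ops) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      s <- s + mat[av[i], bv[j]]
    } else if (op == "A") {
      i <- i + 1L
      s <- s - ge - if (prev != "A") go else 0
    } else {
      j <- j + 1L
      s <- s - ge - if (prev != "B") go else 0
    }
    prev <- op
  }
  s
}

oracleGlobal <- function(a, b, mat, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  if (la == 0 && lb == 0) return(0)
  tpl <- alignmentTemplates(la, lb)
  max(vapply(tpl, affineAlnScore, 0, av = av, bv = bv, mat = mat,
             go = go, ge = ge))
}

oracleLocal <- function(a, b, mat, go, ge) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (j1 in i1:length(av)) {
    if (j1 > length(av)) next
    for (i2 in seq_along(bv)) for (j2 in i2:length(bv)) {
      if (j2 > length(bv)) next
      sub1 <- av[i1:j1]; sub2 <- bv[i2:j2]
      tpl <- alignmentTemplates(length(sub1), length(sub2))
      sc <- max(vapply(tpl, affineAlnScore, 0, av = sub1, bv = sub2,
                       mat = mat, go = go, ge = ge))
      if (sc > best) best <- sc
    }
  }
  best
}

# ---- motif oracle ----------------------------------------------------------

oracleMotifCount <- function(region, pattern) {
  alts <- strsplit(pattern, "|", fixed = TRUE)[[1]]
  L <- nchar(region)
  hits <- 0L
  for (i in seq_len(L)) {
    suf <- substr(region, i, L)
    if (any(vapply(alts, function(al)
      regexpr(paste0("^(?:", al, ")"), suf, perl = TRUE) == 1L, TRUE)))
      hits <- hits + 1L
  }
  hits
}

randomAASeq <- function(L, bg = aaBackground())
  paste(sample(names(bg), L, replace = TRUE, prob = bg), collapse = "")
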