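# Independent dynamic-programming oracle for alignment identity, written in
# plain R against the same contract as the package kernel: match +1,
# mismatch -2, internal gap 10 + L, terminal gap columns (global mode)
# charged 1 per skipped base and excluded from the identity denominator;
# ties prefer more matches, then more diagonal columns, with a fixed
# candidate order (start, M, X, Y).
oracleAlign <- function(a, b, local = FALSE) {
  MATCH <- 1; MISMATCH <- -2; EXT <- 1; GAPF <- 11
  bases <- c("A", "C", "G", "T")
  ac <- match(strsplit(toupper(a), "")[[1]], bases)
  bc <- match(strsplit(toupper(b), "")[[1]], bases)
  n <- length(ac); m <- length(bc)
  NEG <- -1e15
  none <- c(NEG, 0, 0, 0, 0)   # score, matches, diag, ai, bj
  strictlyBetter <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] > y[3]
  }
  newRow <- function() matrix(none, 5, m + 1)   # columns are j = 0..m
  Mp <- newRow(); Xp <- newRow(); Yp <- newRow()
  best <- none
  for (i in seq_len(n)) {
    Mc <- newRow(); Xc <- newRow(); Yc <- newRow()
    for (j in seq_len(m)) {
      isMatch <- !is.na(ac[i]) && !is.na(bc[j]) && ac[i] == bc[j]
      sc <- if (isMatch) MATCH else MISMATCH
      mt <- as.numeric(isMatch)
      M <- none
      if (local || i - 1 == 0 || j - 1 == 0) {
        lead <- if (local) 0 else if (i - 1 == 0) j - 1 else i - 1
        cand <- c(sc - EXT * lead, mt, 1, 1, 1)
        if (strictlyBetter(cand, M)) M <- cand
      }
      for (P in list(Mp[, j], Xp[, j], Yp[, j])) {   # predecessor (i-1,j-1)
        if (P[1] <= NEG) next
        cand <- P + c(sc, mt, 1, 1, 1)
        if (strictlyBetter(cand, M)) M <- cand
      }
      Mc[, j + 1] <- M
      X <- none
      for (cost in list(c(Mp[, j + 1], GAPF), c(Xp[, j + 1], EXT))) {
        P <- cost[1:5]
        if (P[1] <= NEG) next
        cand <- P + c(-cost[6], 0, 0, 1, 0)
        if (strictlyBetter(cand, X)) X <- cand
      }
      Xc[, j + 1] <- X
      Y <- none
      for (cost in list(c(Mc[, j], GAPF), c(Yc[, j], EXT))) {
        P <- cost[1:5]
        if (P[1] <= NEG) next
        cand <- P + c(-cost[6], 0, 0, 0, 1)
        if (strictlyBetter(cand, Y)) Y <- cand
      }
      Yc[, j + 1] <- Y
      if (local) {
        if (strictlyBetter(M, best)) best <- M
      } else if (i == n || j == m) {
        trail <- if (i == n) m - j else n - i
        cand <- M - c(EXT * trail, 0, 0, 0, 0)
        if (M[1] > NEG && strictlyBetter(cand, best)) best <- cand
      }
    }
    Mp <- Mc; Xp <- Xc; Yp <- Yc
  }
  if (best[1] <= NEG) return(NULL)
  columns <- best[4] + best[5] - best[3]
  list(identity = 100 * best[2] / columns, score = best[1],
       matches = best[2], columns = columns)
}
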