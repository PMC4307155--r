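# Independent brute-force re-evaluation of the stage scores, written as
# naive scan-by-scan loops against the raw trace matrix.  Used to
# cross-check the engine; deliberately shares no code with it.

oracle_apices <- function(y) {
  n <- length(y)
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L  # plateau run [i, j]
    left_ok <- (i == 1L) || (y[i - 1L] < y[i])
    right_ok <- (j == n) || (y[j + 1L] < y[i])
    if (left_ok && right_ok) out <- c(out, i)
    i <- j + 1L
  }
  out
}

oracle_trace <- function(chrom, mz) {
  key <- as.character(mz)
  if (key %in% colnames(chrom$traces)) as.numeric(chrom$traces[, key])
  else rep(0, length(chrom$rts))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

oracle_stage1 <- function(chrom, entry, t_j, params) {
  mzs <- as.integer(unlist(entry[c("m1", "m2", "m3", "m4")]))
  idx <- which(chrom$rts == t_j)
  lo <- entry$expected_rt - params$w
  hi <- entry$expected_rt + params$w
  hood_lo <- max(lo, t_j - params$delta)
  hood_hi <- min(hi, t_j + params$delta)
  total <- 0L
  for (m in mzs) {
    y <- oracle_trace(chrom, m)
    v <- y[idx]
    if (v > 0) total <- total + 1L
    ap <- oracle_apices(y)
    ap <- ap[y[ap] > 0]
    if (any(abs(ap - idx) <= 1L)) total <- total + 1L
    best <- 0
    for (s in seq_along(chrom$rts)) {
      if (chrom$rts[s] >= hood_lo && chrom$rts[s] <= hood_hi && y[s] > best) {
        best <- y[s]
      }
    }
    if (v > 0 && v >= best) total <- total + 1L
  }
  total
}

oracle_stage2 <- function(chrom, entry, t_j, params) {
  mzs <- as.integer(unlist(entry[c("m1", "m2", "m3", "m4")]))
  rl <- as.numeric(unlist(entry[c("r2", "r3", "r4")]))
  idx <- which(chrom$rts == t_j)
  i1 <- oracle_trace(chrom, mzs[1])[idx]
  if (i1 <= 0) return(0L)
  total <- 0L
  for (k in 2:4) {
    robs <- oracle_trace(chrom, mzs[k])[idx] / i1
    lo <- params$f * rl[k - 1]
    hi <- (2 - params$f) * rl[k - 1]
    if (robs >= lo && robs <= hi) total <- total + 1L
  }
  total
}

oracle_stage3 <- function(chrom, entry, t_j, params) {
  mzs <- as.integer(unlist(entry[c("m1", "m2", "m3", "m4")]))
  sel <- which(chrom$rts >= t_j - params$delta & chrom$rts <= t_j + params$delta)
  if (length(sel) < 3L) return(0L)
  x <- oracle_trace(chrom, mzs[1])[sel]
  total <- 0L
  for (k in 2:4) {
    rho <- oracle_pearson(x, oracle_trace(chrom, mzs[k])[sel])
    if (!is.na(rho) && rho >= params$ct) total <- total + 1L
  }
  total
}

# Welch t-test from the textbook formulas (statistic, Welch-Satterthwaite
# df, two-sided p from the t distribution).
oracle_welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(tstat), df)
}
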