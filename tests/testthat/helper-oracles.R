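# Independent oracles, deliberately implemented with different machinery
# than the package routines they cross-check.

# Binomial coefficients by Pascal-triangle addition: exact integers in
# doubles for n up to 50, with no call to choose()/gamma().
pascalTriangle <- function(n) {
  P <- matrix(0, n + 1, n + 1)
  P[, 1] <- 1
  for (i in 2:(n + 1))
    for (j in 2:i)
      P[i, j] <- P[i - 1, j - 1] + P[i - 1, j]
  P
}

# Two-sided Fisher p by brute enumeration over the hypergeometric support,
# comparing exact integer table counts (sum-of-small-p rule, no tolerance).
fisherOracle <- function(a, b, c, d, P = pascalTriangle(a + b + c + d)) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
  xs <- max(0, k - r2):min(k, r1)
  cnt <- vapply(xs, function(x) P[r1 + 1, x + 1] * P[r2 + 1, k - x + 1],
                numeric(1))
  obs <- cnt[xs == a]
  sum(cnt[cnt <= obs]) / sum(cnt)
}

# Independent re-implementation of the carrier run-length filter used by
# findSro (zero out aberration runs shorter than minRun windows).
filterRunsOracle <- function(A, minRun) {
  minRun <- min(minRun, nrow(A))
  if (minRun <= 1) return(A)
  for (s in seq_len(ncol(A))) {
    v <- A[, s]
    i <- 1
    while (i <= length(v)) {
      if (v[i]) {
        j <- i
        while (j < length(v) && v[j + 1]) j <- j + 1
        if (j - i + 1 < minRun) v[i:j] <- FALSE
        i <- j + 1
      } else i <- i + 1
    }
    A[, s] <- v
  }
  A
}

# Brute-force SRO: enumerate every contiguous sub-interval and recount
# carriers from scratch with colSums, independent of the package's
# incremental running-AND scan.
sroOracle <- function(A, enrIdx, starts, ends) {
  k <- nrow(A)
  best <- NULL
  for (i in seq_len(k)) for (j in i:k) {
    sub <- A[i:j, enrIdx, drop = FALSE]
    carriers <- sum(colSums(sub) == (j - i + 1L))
    extent <- ends[j] - starts[i] + 1
    if (is.null(best) ||
        carriers > best$carriers ||
        (carriers == best$carriers && carriers > 0 &&
         extent > best$extent))
      best <- list(i = i, j = j, carriers = carriers, extent = extent)
  }
  best
}
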