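#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `rbind(c(a, b), c(c, d))` by the
#' standard "sum of small p" rule: the sum of the hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table.
#'
#' For tables whose binomial coefficients are exactly representable in
#' doubles (row sums up to ~50, covering 23-vs-17 cohorts many times over)
#' the tail is accumulated in exact integer arithmetic, so ties are resolved
#' without any floating-point tolerance. Larger tables fall back to
#' log-space probabilities with a 1e-7 relative tie tolerance, the
#' conventional guard.
#'
#' @param a,b,c,d non-negative integer cell counts; `a,b` are the carriers
#'   and non-carriers of the first group, `c,d` of the second.
#' @return two-sided p-value in `[0, 1]`; an empty margin yields 1.
#' @examples
#' fisherExact2x2(14, 9, 2, 15)   # ~0.003
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  if (!isWholeNumber(c(a, b, c, d)) || any(c(a, b, c, d) < 0))
    stop("cell counts must be non-negative integers")
  a <- round(a); b <- round(b); c <- round(c); d <- round(d)
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == N) return(1)
  x <- max(0, k - r2):min(k, r1)

  ## exact-integer path: counts choose(r1,x)*choose(r2,k-x) fit in 2^53
  if (lchoose(r1, floor(r1 / 2)) + lchoose(r2, floor(r2 / 2)) < 52 * log(2)) {
    cnt <- round(choose(r1, x)) * round(choose(r2, k - x))
    obs <- cnt[x == a]
    return(min(1, sum(cnt[cnt <= obs]) / sum(cnt)))
  }
  lp <- stats::dhyper(x, r1, r2, k, log = TRUE)
  lobs <- lp[x == a]
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}
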