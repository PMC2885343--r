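#' @importFrom stats median qnorm rnorm runif rbinom cor t.test wilcox.test
#' @importFrom utils read.delim write.table
NULL

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

## Deterministic per-component substream seeds derived from one master seed.
## Lehmer step keeps everything inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

## Fixed 6-significant-digit formatting shared by all writers so output files
## are byte-identical across runs.
fmtNum <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
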