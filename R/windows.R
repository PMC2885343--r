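#' Fixed probe-count window grid
#'
#' Partitions the probes of each chromosome into consecutive runs of
#' `probesPerWindow` probes (the last window of a chromosome may hold
#' fewer). At ~6 kb probe spacing the default 10-probe window spans roughly
#' 60 kb. Windows never cross a chromosome boundary; the genomic bounds of a
#' window are `[first probe start, last probe end]`.
#'
#' @param probes sorted probe map `GRanges`.
#' @param probesPerWindow probes averaged per window (>= 1).
#' @return `GRanges` with mcols `probe_first`, `probe_last` (global probe
#'   indices, 1-based inclusive) and `n_probes`.
#' @export
buildWindows <- function(probes, probesPerWindow = 10) {
  stopifnot(probesPerWindow >= 1)
  if (length(probes) == 0) stop("empty probe map")
  chr <- as.character(seqnames(probes))
  parts <- lapply(unique(chr), function(cn) {
    idx <- which(chr == cn)
    n <- length(idx)
    w <- ceiling(seq_along(idx) / probesPerWindow)
    first <- idx[!duplicated(w)]
    last <- idx[!duplicated(w, fromLast = TRUE)]
    GRanges(cn, IRanges(start(probes)[first], end(probes)[last]),
            probe_first = first, probe_last = last,
            n_probes = last - first + 1L,
            seqinfo = seqinfo(probes))
  })
  do.call(c, parts)
}

#' Window-averaged log2 ratios
#'
#' Arithmetic mean of the non-missing probe ratios in each window. A window
#' whose probes are all missing for a sample yields `NA` (flagged
#' undefined; [callWindows()] treats it conservatively as `NORMAL`).
#'
#' @param lr numeric matrix or vector of probe log2 ratios (probes x
#'   samples), aligned to the probe map the grid was built from.
#' @param grid window `GRanges` from [buildWindows()].
#' @return matrix of window means (windows x samples).
#' @export
windowMeans <- function(lr, grid) {
  lr <- as.matrix(lr)
  nProbes <- max(mcols(grid)$probe_last)
  if (nrow(lr) != nProbes)
    stop("ratio track has ", nrow(lr), " probes but the grid expects ",
         nProbes)
  widx <- rep.int(seq_along(grid), mcols(grid)$n_probes)
  ok <- !is.na(lr)
  num <- rowsum(ifelse(ok, lr, 0), widx, reorder = TRUE)
  den <- rowsum(ok + 0, widx, reorder = TRUE)
  out <- num / den
  out[den == 0] <- NA_real_
  dimnames(out) <- list(NULL, colnames(lr))
  out
}

#' Calling thresholds
#'
#' @param gainCut,lossCut log2-ratio cuts on window means; a window is
#'   called `GAIN` strictly above `gainCut` and `LOSS` strictly below
#'   `lossCut` (exclusive boundaries keep the control false-positive rate at
#'   or below its target). Defaults are the conventional +/-0.1.
#' @return a list of class `CNThresholds`.
#' @export
cnThresholds <- function(gainCut = 0.1, lossCut = -0.1) {
  if (!(lossCut < 0 && 0 < gainCut))
    stop("need lossCut < 0 < gainCut")
  structure(list(gainCut = gainCut, lossCut = lossCut),
            class = "CNThresholds")
}

#' @export
print.CNThresholds <- function(x, ...) {
  cat("CNThresholds: GAIN > ", fmtNum(x$gainCut),
      ", LOSS < ", fmtNum(x$lossCut), "\n", sep = "")
  invisible(x)
}

#' Empirical false-positive rate of thresholds on a null control
#'
#' Fraction of control window means (or probe ratios) beyond each cut.
#' The input should already be restricted to unmasked autosomal territory —
#' the variation used to set thresholds in the first place.
#'
#' @param controlMeans numeric vector of null window means.
#' @param thresholds a [cnThresholds()].
#' @return named list `fprGain`, `fprLoss`.
#' @export
empiricalFpr <- function(controlMeans, thresholds) {
  x <- controlMeans[!is.na(controlMeans)]
  if (!length(x)) stop("no unmasked windows to evaluate")
  list(fprGain = mean(x > thresholds$gainCut),
       fprLoss = mean(x < thresholds$lossCut))
}

#' Calibrate calling thresholds to target false-positive rates
#'
#' Sets the gain cut at the `1 - targetFprGain` empirical quantile of the
#' null control means and the loss cut at the `targetFprLoss` quantile,
#' using order statistics chosen so that, with the strict call inequalities,
#' the empirical FPR at the returned cuts never exceeds the targets on the
#' calibration control itself.
#'
#' @param controlMeans null window means, restricted to unmasked autosomes.
#' @param targetFprGain,targetFprLoss target rates (defaults 0.005 / 0.007).
#' @return a [cnThresholds()].
#' @export
calibrateThresholds <- function(controlMeans, targetFprGain = 0.005,
                                targetFprLoss = 0.007) {
  x <- sort(controlMeans[!is.na(controlMeans)])
  n <- length(x)
  if (n == 0) stop("no unmasked windows to calibrate on")
  if (x[1] == x[n]) stop("degenerate (constant) control; cannot calibrate")
  if (n < 1000)
    warning("only ", n, " control windows; calibration will be coarse")
  ## #(x > x[k]) <= n - k <= n * t  for k = ceiling(n * (1 - t))
  kg <- max(1L, ceiling(n * (1 - targetFprGain)))
  ## #(x < x[k]) <= k - 1 <= n * t  for k = floor(n * t) + 1
  kl <- min(n, floor(n * targetFprLoss) + 1L)
  gain <- x[kg]; loss <- x[kl]
  if (loss > gain) stop("calibrated cuts collapsed; control too coarse")
  if (!(loss < 0 && gain > 0)) {
    ## extreme targets (or a biased control) can put a quantile past zero;
    ## return the empirical cuts anyway, flagged for the analyst
    warning("calibrated thresholds do not bracket zero (gain ",
            fmtNum(gain), ", loss ", fmtNum(loss), ")")
    return(structure(list(gainCut = gain, lossCut = loss),
                     class = "CNThresholds"))
  }
  cnThresholds(gainCut = gain, lossCut = loss)
}

#' Threshold window means into copy-number states
#'
#' `GAIN` strictly above the gain cut, `LOSS` strictly below the loss cut,
#' otherwise `NORMAL`; windows flagged masked are `MASKED` regardless of
#' their mean. Undefined (all-missing) unmasked means are called `NORMAL`
#' with a warning.
#'
#' @param means window-mean matrix from [windowMeans()].
#' @param thresholds a [cnThresholds()].
#' @param masked logical vector, one per window.
#' @return character matrix of states, same shape as `means`.
#' @export
callWindows <- function(means, thresholds, masked) {
  means <- as.matrix(means)
  stopifnot(length(masked) == nrow(means))
  st <- matrix("NORMAL", nrow(means), ncol(means),
               dimnames = dimnames(means))
  st[!is.na(means) & means > thresholds$gainCut] <- "GAIN"
  st[!is.na(means) & means < thresholds$lossCut] <- "LOSS"
  undef <- is.na(means) & !masked
  if (any(undef))
    warning(sum(undef), " unmasked window mean(s) undefined; called NORMAL")
  st[masked, ] <- "MASKED"
  st
}

#' Window-based copy-number calling
#'
#' The full calling step: build the window grid, average the probe ratios,
#' apply the exclusion masks (a window intersecting any mask is wholly
#' `MASKED`), and threshold. Thresholds can be given directly or calibrated
#' on a self-control experiment to target false-positive rates.
#'
#' @param cgh a [CGHExperiment-class].
#' @param genome the matching [GenomeBuild-class].
#' @param probesPerWindow probes averaged per window (default 10).
#' @param thresholds a [cnThresholds()] (default +/-0.1).
#' @param control optional one-sample [CGHExperiment-class] self-control;
#'   if supplied, thresholds are calibrated on its unmasked autosomal
#'   window means.
#' @param targetFprGain,targetFprLoss calibration targets when `control`
#'   is given.
#' @param masks mask `GRanges`; defaults to [buildMasks()] of `genome`.
#'   Pass a custom set (e.g. without the sex-chromosome rule) for control
#'   checks that look at X/Y.
#' @return a [WindowCalls-class].
#' @export
callCopyNumber <- function(cgh, genome, probesPerWindow = 10,
                           thresholds = cnThresholds(),
                           control = NULL,
                           targetFprGain = 0.005, targetFprLoss = 0.007,
                           masks = buildMasks(genome)) {
  probes <- probeRanges(cgh)
  grid <- buildWindows(probes, probesPerWindow)
  masked <- countOverlaps(grid, masks) > 0
  hit <- findOverlaps(grid, masks)
  reason <- rep(NA_character_, length(grid))
  if (length(hit))
    reason[queryHits(hit)[!duplicated(queryHits(hit))]] <-
      as.character(mcols(masks)$reason[subjectHits(hit)[
        !duplicated(queryHits(hit))]])
  means <- windowMeans(lrMatrix(cgh), grid)

  if (!is.null(control)) {
    cm <- windowMeans(lrMatrix(control), grid)[, 1L]
    auto <- as.character(seqnames(grid)) %in% autosomeNames(genome)
    thresholds <- calibrateThresholds(cm[auto & !masked],
                                      targetFprGain, targetFprLoss)
  }
  states <- callWindows(means, thresholds, masked)

  mcols(grid)$masked <- masked
  mcols(grid)$mask_reason <- reason
  se <- SummarizedExperiment(assays = list(means = means, states = states),
                             rowRanges = grid, colData = colData(cgh))
  metadata(se)$thresholds <- thresholds
  metadata(se)$probesPerWindow <- probesPerWindow
  new("WindowCalls", se)
}

#' @rdname WindowCalls-class
#' @export
setMethod("callStates", "WindowCalls", function(x) assay(x, "states"))

#' @rdname WindowCalls-class
#' @export
setMethod("callMeans", "WindowCalls", function(x) assay(x, "means"))

#' @rdname WindowCalls-class
#' @export
setMethod("windowRanges", "WindowCalls", function(x) rowRanges(x))

#' @rdname WindowCalls-class
#' @export
setMethod("thresholdsOf", "WindowCalls", function(x) metadata(x)$thresholds)

setMethod("show", "WindowCalls", function(object) {
  th <- thresholdsOf(object)
  st <- callStates(object)
  cat("WindowCalls:", nrow(object), "windows x", ncol(object), "samples;",
      sum(mcols(rowRanges(object))$masked), "masked windows\n")
  cat("  thresholds: GAIN > ", fmtNum(th$gainCut), ", LOSS < ",
      fmtNum(th$lossCut), "\n", sep = "")
  tab <- table(factor(st, c("LOSS", "NORMAL", "GAIN", "MASKED")))
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' Unmasked autosomal window means of a control experiment
#'
#' Convenience extractor producing the input [calibrateThresholds()] and
#' [empiricalFpr()] expect: window means of a (self-)control restricted to
#' unmasked autosomal windows.
#'
#' @param control a one-sample [CGHExperiment-class].
#' @param genome the matching [GenomeBuild-class].
#' @param probesPerWindow probes per window.
#' @param masks mask `GRanges`.
#' @return numeric vector of null window means.
#' @export
autosomalNullMeans <- function(control, genome, probesPerWindow = 10,
                               masks = buildMasks(genome)) {
  grid <- buildWindows(probeRanges(control), probesPerWindow)
  masked <- countOverlaps(grid, masks) > 0
  auto <- as.character(seqnames(grid)) %in% autosomeNames(genome)
  windowMeans(lrMatrix(control), grid)[auto & !masked, 1L]
}
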