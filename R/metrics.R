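#' Maximal same-state aberration segments per sample
#'
#' Extracts maximal runs of identical non-`NORMAL` state per chromosome and
#' sample. With `bridgeMasked = TRUE` (default) a masked gap flanked by the
#' same state is bridged into one segment, so a centromere does not split a
#' p-to-q event in two; with `FALSE` masked windows break runs.
#'
#' A segment "touches" a chromosome end when no unmasked window lies beyond
#' it on that side; a segment touching both ends is a whole-chromosome
#' aberration.
#'
#' @param calls a [WindowCalls-class].
#' @param bridgeMasked bridge masked gaps between same-state runs.
#' @return `data.frame` with one row per segment: `sample_id`, `chrom`,
#'   `window_first`, `window_last` (global window indices, 1-based
#'   inclusive), `start`, `end` (bp), `direction`, `n_windows`,
#'   `touches_start`, `touches_end`, `whole_chromosome`.
#' @export
segmentsFromCalls <- function(calls, bridgeMasked = TRUE) {
  st <- callStates(calls)
  grid <- windowRanges(calls)
  chr <- as.character(seqnames(grid))
  samples <- colnames(st)
  out <- list()
  for (cn in unique(chr)) {
    widx <- which(chr == cn)
    for (s in samples) {
      states <- st[widx, s]
      if (bridgeMasked) {
        keep <- states != "MASKED"
        pos <- widx[keep]
        sq <- states[keep]
      } else {
        pos <- widx
        sq <- states
      }
      if (!length(pos)) next
      r <- rle(sq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ab <- which(r$values %in% c("GAIN", "LOSS"))
      if (!length(ab)) next
      unmaskedPos <- widx[st[widx, s] != "MASKED"]
      firstUn <- if (length(unmaskedPos)) min(unmaskedPos) else NA_integer_
      lastUn <- if (length(unmaskedPos)) max(unmaskedPos) else NA_integer_
      for (k in ab) {
        wf <- pos[starts[k]]; wl <- pos[ends[k]]
        tS <- !is.na(firstUn) && wf <= firstUn
        tE <- !is.na(lastUn) && wl >= lastUn
        out[[length(out) + 1L]] <- data.frame(
          sample_id = s, chrom = cn,
          window_first = wf, window_last = wl,
          start = start(grid)[wf], end = end(grid)[wl],
          direction = if (r$values[k] == "GAIN") "gain" else "loss",
          n_windows = ends[k] - starts[k] + 1L,
          touches_start = tS, touches_end = tE,
          whole_chromosome = tS && tE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      window_first = integer(0), window_last = integer(0),
                      start = numeric(0), end = numeric(0),
                      direction = character(0), n_windows = integer(0),
                      touches_start = logical(0), touches_end = logical(0),
                      whole_chromosome = logical(0)))
  do.call(rbind, out)
}

#' Aberration and breakpoint counts
#'
#' Applies the counting rule: each maximal segment is one chromosomal
#' aberration; a whole-chromosome segment contributes zero breakpoints, an
#' interior segment two. A segment touching exactly one chromosome end
#' contributes one breakpoint — the rule's unique consistent extension (one
#' breakpoint per internal state boundary).
#'
#' @param segments segment table from [segmentsFromCalls()].
#' @param samples sample ids to report (defaults to those present);
#'   samples without segments get zero counts.
#' @return `data.frame` with `sample_id`, `n_aberrations`, `n_breakpoints`.
#' @export
countAberrations <- function(segments, samples = unique(segments$sample_id)) {
  bp <- ifelse(segments$whole_chromosome, 0L,
               2L - segments$touches_start - segments$touches_end)
  agg_n <- table(factor(segments$sample_id, levels = samples))
  agg_bp <- tapply(bp, factor(segments$sample_id, levels = samples), sum,
                   default = 0L)
  data.frame(sample_id = samples,
             n_aberrations = as.integer(agg_n[samples]),
             n_breakpoints = as.integer(agg_bp[samples]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Genome fraction aberrant and percentage normal
#'
#' Computed over unmasked windows only, weighted by window bp length
#' (`"bp"`, default) or by window count (`"windows"`). The two outputs sum
#' to one exactly.
#'
#' @param calls a [WindowCalls-class].
#' @param weightBy `"bp"` or `"windows"`.
#' @return `data.frame` with `sample_id`, `fraction_aberrant`,
#'   `pct_windows_normal`.
#' @export
genomeFractions <- function(calls, weightBy = c("bp", "windows")) {
  weightBy <- match.arg(weightBy)
  st <- callStates(calls)
  grid <- windowRanges(calls)
  un <- !mcols(grid)$masked
  if (!any(un)) stop("no unmasked windows")
  w <- if (weightBy == "bp") width(grid)[un] else rep(1, sum(un))
  stU <- st[un, , drop = FALSE]
  ab <- apply(stU, 2L, function(s) sum(w[s %in% c("GAIN", "LOSS")]) / sum(w))
  data.frame(sample_id = colnames(st), fraction_aberrant = unname(ab),
             pct_windows_normal = unname(1 - ab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample metrics table
#'
#' Wrapper combining [segmentsFromCalls()], [countAberrations()] and
#' [genomeFractions()] into one table, the standard per-sample summary of a
#' calling run.
#'
#' @inheritParams segmentsFromCalls
#' @inheritParams genomeFractions
#' @return `data.frame` with `sample_id`, `group`, `n_aberrations`,
#'   `n_breakpoints`, `fraction_aberrant`, `pct_windows_normal`.
#' @export
sampleMetrics <- function(calls, bridgeMasked = TRUE,
                          weightBy = c("bp", "windows")) {
  samples <- colnames(callStates(calls))
  seg <- segmentsFromCalls(calls, bridgeMasked = bridgeMasked)
  cnt <- countAberrations(seg, samples = samples)
  fr <- genomeFractions(calls, weightBy = weightBy)
  grp <- colData(calls)$group
  data.frame(sample_id = samples,
             group = if (is.null(grp)) NA_character_ else as.character(grp),
             n_aberrations = cnt$n_aberrations,
             n_breakpoints = cnt$n_breakpoints,
             fraction_aberrant = fr$fraction_aberrant,
             pct_windows_normal = fr$pct_windows_normal,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Replicate concordance R-squared
#'
#' Squared Pearson correlation between two ratio tracks over all probes
#' lying in windows where at least one of the two samples is called
#' non-`NORMAL` — the replicate-concordance protocol for re-hybridized
#' samples.
#'
#' @param lrA,lrB probe log2-ratio vectors on a shared probe map.
#' @param statesA,statesB state vectors for the two samples (one per
#'   window).
#' @param grid the shared window `GRanges`.
#' @return squared correlation coefficient.
#' @export
replicateR2 <- function(lrA, lrB, statesA, statesB, grid) {
  stopifnot(length(lrA) == length(lrB),
            length(statesA) == length(grid),
            length(statesB) == length(grid))
  sel <- statesA %in% c("GAIN", "LOSS") | statesB %in% c("GAIN", "LOSS")
  if (!any(sel)) stop("no aberrant loci in either sample")
  pidx <- unlist(lapply(which(sel), function(w) {
    seq.int(mcols(grid)$probe_first[w], mcols(grid)$probe_last[w])
  }))
  a <- lrA[pidx]; b <- lrB[pidx]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 aberrant probes; R2 undefined")
  cor(a[ok], b[ok])^2
}

#' Group comparison of per-sample metrics
#'
#' Two-sided two-sample test of each metric between the `early` and `late`
#' groups; Mann-Whitney (default) or t-test.
#'
#' @param metrics table from [sampleMetrics()] (needs a `group` column).
#' @param method `"wilcox"` or `"t"`.
#' @param columns metric columns to test.
#' @return named numeric vector of two-sided p-values.
#' @export
compareGroupCounts <- function(metrics, method = c("wilcox", "t"),
                               columns = c("n_aberrations", "n_breakpoints",
                                           "fraction_aberrant")) {
  method <- match.arg(method)
  g <- metrics$group
  if (!all(c("early", "late") %in% g))
    stop("both groups must be non-empty")
  vapply(columns, function(cl) {
    x <- metrics[[cl]][g == "early"]
    y <- metrics[[cl]][g == "late"]
    if (length(unique(c(x, y))) == 1L) {
      warning("metric '", cl, "' constant in both groups; p = 1")
      return(1)
    }
    if (method == "wilcox")
      suppressWarnings(wilcox.test(x, y)$p.value)
    else
      t.test(x, y, var.equal = TRUE)$p.value
  }, numeric(1))
}
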