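#' Per-window Fisher tests of gain/loss frequency between groups
#'
#' For every unmasked window, two 2x2 Fisher exact tests compare the groups:
#' patients with gain vs no-gain, and with loss vs no-loss. Masked windows
#' are skipped. Identical carrier tables share one p-value computation.
#'
#' @param calls a [WindowCalls-class] whose `colData$group` labels samples
#'   `early`/`late`.
#' @return `data.frame` with `window` (global window index), `chrom`,
#'   `start`, `end`, `direction`, `a_early`, `n_early`, `a_late`, `n_late`,
#'   `p`.
#' @export
testAllWindows <- function(calls) {
  st <- callStates(calls)
  grid <- windowRanges(calls)
  grp <- as.character(colData(calls)$group)
  if (sum(grp == "early") < 1 || sum(grp == "late") < 1)
    stop("need at least one sample per group (early/late)")
  e <- grp == "early"; l <- grp == "late"
  nE <- sum(e); nL <- sum(l)
  un <- which(!mcols(grid)$masked)

  res <- lapply(c(gain = "GAIN", loss = "LOSS"), function(state) {
    aE <- rowSums(st[un, e, drop = FALSE] == state)
    aL <- rowSums(st[un, l, drop = FALSE] == state)
    key <- paste(aE, aL)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i)
      fisherExact2x2(aE[i], nE - aE[i], aL[i], nL - aL[i]), numeric(1))
    p <- pv[match(key, key[uk])]
    data.frame(window = un, chrom = as.character(seqnames(grid))[un],
               start = start(grid)[un], end = end(grid)[un],
               a_early = aE, n_early = nE, a_late = aL, n_late = nL, p = p,
               stringsAsFactors = FALSE)
  })
  res$gain$direction <- "gain"
  res$loss$direction <- "loss"
  out <- rbind(res$gain, res$loss)
  out[order(out$direction, out$window),
      c("window", "chrom", "start", "end", "direction",
        "a_early", "n_early", "a_late", "n_late", "p")]
}

#' Merge significant windows into differential regions
#'
#' Maximal runs of same-direction windows with `p < alpha` become candidate
#' regions; masked gaps between significant windows are bridged (consistent
#' with segment extraction), and any region whose span then intersects a
#' centromere mask is discarded, mirroring the exclusion of
#' centromere-spanning hits. `avg_p` is the unweighted mean of the member
#' windows' p-values. The enriched group is the one with the larger mean
#' carrier fraction across member windows.
#'
#' @param tests window test table from [testAllWindows()].
#' @param calls the [WindowCalls-class] the tests came from.
#' @param alpha significance cutoff (default 0.05, uncorrected as is
#'   conventional for this window-frequency mapping; apply
#'   [stats::p.adjust()] to `tests$p` beforehand for a corrected variant).
#' @param masks mask `GRanges` used for the centromere exclusion; defaults
#'   to the masks recorded in the calls' window grid.
#' @param dropCentromereSpanning discard regions overlapping a centromere
#'   mask.
#' @return `GRanges` of regions with mcols `direction`, `avg_p`,
#'   `n_windows`, `window_first`, `window_last`, `enriched_group`.
#' @export
mergeRegions <- function(tests, calls, alpha = 0.05, masks = NULL,
                         dropCentromereSpanning = TRUE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  grid <- windowRanges(calls)
  maskedVec <- mcols(grid)$masked
  chr <- as.character(seqnames(grid))
  if (is.null(masks)) {
    cenIdx <- which(maskedVec & mcols(grid)$mask_reason == "centromere")
  } else {
    cen <- masks[mcols(masks)$reason == "centromere"]
    cenIdx <- which(countOverlaps(grid, cen) > 0)
  }

  regions <- list()
  for (dir in c("gain", "loss")) {
    tt <- tests[tests$direction == dir & tests$p < alpha, , drop = FALSE]
    if (!nrow(tt)) next
    tt <- tt[order(tt$window), , drop = FALSE]
    ## runs: consecutive significant windows, allowing gaps that consist
    ## entirely of masked windows on the same chromosome
    brk <- c(TRUE, vapply(seq_len(nrow(tt) - 1L), function(i) {
      w1 <- tt$window[i]; w2 <- tt$window[i + 1L]
      if (tt$chrom[i] != tt$chrom[i + 1L]) return(TRUE)
      gap <- setdiff(seq.int(w1 + 1L, length.out = w2 - w1 - 1L), integer(0))
      !(w2 == w1 + 1L || all(maskedVec[gap]))
    }, logical(1)))
    runId <- cumsum(brk)
    for (r in unique(runId)) {
      m <- tt[runId == r, , drop = FALSE]
      wf <- min(m$window); wl <- max(m$window)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = m$chrom[1], start = start(grid)[wf], end = end(grid)[wl],
        direction = dir, avg_p = mean(m$p), n_windows = nrow(m),
        window_first = wf, window_last = wl,
        enriched_group = if (mean(m$a_early / m$n_early) >=
                             mean(m$a_late / m$n_late)) "early" else "late",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(regions)) return(GRanges(seqinfo = seqinfo(grid)))
  df <- do.call(rbind, regions)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                direction = df$direction, avg_p = df$avg_p,
                n_windows = df$n_windows, window_first = df$window_first,
                window_last = df$window_last,
                enriched_group = df$enriched_group,
                seqinfo = seqinfo(grid))
  if (dropCentromereSpanning && length(cenIdx)) {
    spans <- mapply(function(wf, wl) any(cenIdx > wf & cenIdx < wl),
                    df$window_first, df$window_last)
    gr <- gr[!spans]
  }
  sort(gr)
}

#' Smallest region of overlap (SRO) of a differential region
#'
#' Among all contiguous window sub-intervals of a region, finds the one
#' carried (aberrant in the region's direction across the whole
#' sub-interval) by the largest number of enriched-group samples. Among
#' sub-intervals tied on carriers the maximal (largest-extent, then
#' leftmost) one is returned: the SRO is the intersection of the carriers'
#' aberrations — "smallest" relative to each carrier's own aberration, not
#' the smallest window set attaining the count (under which any uniform
#' carrier set would degenerate to a single window). Exhaustive search
#' over all sub-intervals.
#'
#' A sample only counts as a carrier where its aberration spans at least
#' `minRun` consecutive member windows (capped at the region width).
#' Without this guard a single noise-called window in one extra sample
#' would beat the sustained overlap of the true carriers and collapse the
#' SRO to one window; requiring a few consecutive windows is the usual
#' aCGH defense against isolated threshold crossings. Set `minRun = 1` for
#' the unfiltered search.
#'
#' @param calls a [WindowCalls-class].
#' @param region a single region from [mergeRegions()] (length-1 `GRanges`
#'   with `window_first`, `window_last`, `direction`, `enriched_group`).
#' @param minRun minimum consecutive-window span of an aberration for a
#'   sample to count as a carrier (default 3).
#' @return list with `sro` (`GRanges`), `window_first`, `window_last`,
#'   `carriers_early`, `carriers_late` (carriers of the full SRO in each
#'   group).
#' @export
findSro <- function(calls, region, minRun = 3) {
  stopifnot(length(region) == 1L)
  grid <- windowRanges(calls)
  st <- callStates(calls)
  grp <- as.character(colData(calls)$group)
  dir <- mcols(region)$direction
  state <- if (dir == "gain") "GAIN" else "LOSS"
  enr <- mcols(region)$enriched_group
  members <- seq.int(mcols(region)$window_first, mcols(region)$window_last)
  members <- members[!mcols(grid)$masked[members]]
  k <- length(members)
  A <- st[members, , drop = FALSE] == state
  A <- dropShortRuns(A, min(minRun, k))
  enrIdx <- which(grp == enr)

  best <- NULL
  for (i in seq_len(k)) {
    cur <- rep(TRUE, ncol(A))
    for (j in i:k) {
      cur <- cur & A[j, ]
      carriers <- sum(cur[enrIdx])
      if (carriers == 0) break
      extent <- end(grid)[members[j]] - start(grid)[members[i]] + 1
      cand <- list(i = i, j = j, carriers = carriers, extent = extent)
      if (is.null(best) || carriers > best$carriers ||
          (carriers == best$carriers && extent > best$extent))
        best <- cand
    }
  }
  if (is.null(best)) best <- list(i = 1L, j = 1L, carriers = 0L,
                                  extent = width(grid)[members[1]])
  wf <- members[best$i]; wl <- members[best$j]
  sub <- seq.int(best$i, best$j)
  carried <- colSums(A[sub, , drop = FALSE]) == length(sub)
  list(sro = GRanges(as.character(seqnames(grid))[wf],
                     IRanges(start(grid)[wf], end(grid)[wl]),
                     seqinfo = seqinfo(grid)),
       window_first = wf, window_last = wl,
       carriers_early = sum(carried & grp == "early"),
       carriers_late = sum(carried & grp == "late"))
}

## Zero out per-sample aberration runs shorter than minRun windows.
dropShortRuns <- function(A, minRun) {
  if (minRun <= 1L) return(A)
  for (s in seq_len(ncol(A))) {
    r <- rle(A[, s])
    short <- r$values & r$lengths < minRun
    if (any(short)) {
      r$values <- r$values & !short
      A[, s] <- inverse.rle(r)
    }
  }
  A
}

#' Annotate regions with their SRO and carrier counts
#'
#' @param regions `GRanges` from [mergeRegions()].
#' @param calls the matching [WindowCalls-class].
#' @param minRun passed to [findSro()].
#' @return `regions` with added mcols `sro_start`, `sro_end`,
#'   `carriers_early`, `carriers_late`.
#' @export
annotateSro <- function(regions, calls, minRun = 3) {
  if (!length(regions)) return(regions)
  res <- lapply(seq_along(regions),
                function(i) findSro(calls, regions[i], minRun = minRun))
  mcols(regions)$sro_start <- vapply(res, function(x) start(x$sro), 0)
  mcols(regions)$sro_end <- vapply(res, function(x) end(x$sro), 0)
  mcols(regions)$carriers_early <-
    vapply(res, function(x) x$carriers_early, 0L)
  mcols(regions)$carriers_late <-
    vapply(res, function(x) x$carriers_late, 0L)
  regions
}

#' Percentage of the unmasked autosomal genome in differential regions
#'
#' @param regions disjoint region `GRanges`.
#' @param genome a [GenomeBuild-class].
#' @param masks mask `GRanges`; defaults to [buildMasks()].
#' @return percentage (0-100).
#' @export
significantGenomeFraction <- function(regions, genome,
                                      masks = buildMasks(genome)) {
  auto <- autosomeNames(genome)
  lens <- chromLengths(genome)[auto]
  mAuto <- reduce(masks[as.character(seqnames(masks)) %in% auto])
  denom <- sum(lens) - sum(width(mAuto))
  if (!length(regions)) return(0)
  r <- reduce(regions)
  100 * sum(width(r[as.character(seqnames(r)) %in% auto])) / denom
}
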