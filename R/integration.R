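#' Per-gene copy-number states from window calls
#'
#' Each gene takes the state of the windows it overlaps: if all overlapped
#' unmasked windows agree, that state; if they disagree, the state of the
#' window containing the gene midpoint; if every overlapped window is
#' masked, `MASKED`. A gene overlapping no window is an error.
#'
#' @param genes gene annotation `GRanges` with unique `gene_id`.
#' @param calls a [WindowCalls-class].
#' @return character matrix, genes x samples.
#' @export
geneStates <- function(genes, calls) {
  grid <- windowRanges(calls)
  st <- callStates(calls)
  gid <- mcols(genes)$gene_id
  hits <- findOverlaps(genes, grid)
  if (length(unique(queryHits(hits))) < length(genes)) {
    missing <- setdiff(seq_along(genes), queryHits(hits))
    stop("gene(s) overlapping no window: ",
         paste(gid[missing], collapse = ", "))
  }
  mid <- floor((start(genes) + end(genes)) / 2)
  midGr <- GRanges(seqnames(genes), IRanges(mid, mid),
                   seqinfo = seqinfo(genes))
  midHit <- findOverlaps(midGr, grid, select = "first")
  byGene <- split(subjectHits(hits), queryHits(hits))

  out <- matrix(NA_character_, length(genes), ncol(st),
                dimnames = list(gid, colnames(st)))
  maskedVec <- mcols(grid)$masked
  for (g in seq_along(genes)) {
    widx <- byGene[[as.character(g)]]
    un <- widx[!maskedVec[widx]]
    if (!length(un)) {
      out[g, ] <- "MASKED"
      next
    }
    sub <- st[un, , drop = FALSE]
    agree <- apply(sub, 2L, function(s) length(unique(s)) == 1L)
    out[g, agree] <- sub[1L, agree]
    if (any(!agree)) {
      mw <- midHit[g]
      if (is.na(mw)) mw <- un[1L]  # midpoint in an inter-window gap
      out[g, !agree] <- st[mw, !agree]
    }
  }
  out
}

#' Median-expression dosage ratios per gene
#'
#' For each gene and each direction independently, the median linear-scale
#' expression of the carrier samples (gain, respectively loss) divided by
#' the median of the normal-copy-number samples. A direction with no
#' carriers, or a gene with no normal-state samples, yields `NA`.
#'
#' @param states gene-state matrix from [geneStates()].
#' @param expr an [ExpressionMatrix-class] covering the same genes and
#'   samples.
#' @return `data.frame` with `gene_id`, `ratio_gain`, `ratio_loss`,
#'   `n_gain`, `n_loss`, `n_normal`.
#' @export
expressionRatios <- function(states, expr) {
  lin <- linearExpr(expr)
  genes <- rownames(states)
  if (!all(genes %in% rownames(lin)))
    stop("expression matrix is missing gene(s): ",
         paste(setdiff(genes, rownames(lin))[1:3], collapse = ", "))
  samples <- colnames(states)
  if (!all(samples %in% colnames(lin)))
    stop("expression matrix is missing sample(s): ",
         paste(setdiff(samples, colnames(lin))[1:3], collapse = ", "))
  lin <- lin[genes, samples, drop = FALSE]
  noNormal <- FALSE
  out <- t(vapply(seq_along(genes), function(g) {
    s <- states[g, ]
    e <- lin[g, ]
    nrm <- e[s == "NORMAL"]
    gn <- e[s == "GAIN"]; ls <- e[s == "LOSS"]
    if (!length(nrm)) {
      noNormal <<- TRUE
      return(c(NA_real_, NA_real_, length(gn), length(ls), 0))
    }
    c(if (length(gn)) median(gn) / median(nrm) else NA_real_,
      if (length(ls)) median(ls) / median(nrm) else NA_real_,
      length(gn), length(ls), length(nrm))
  }, numeric(5)))
  if (noNormal)
    warning("gene(s) with no normal-copy-number samples; ratios undefined")
  data.frame(gene_id = genes, ratio_gain = out[, 1], ratio_loss = out[, 2],
             n_gain = as.integer(out[, 3]), n_loss = as.integer(out[, 4]),
             n_normal = as.integer(out[, 5]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Dosage-concordance flags
#'
#' A gene is concordant-gain when `ratio_gain >= gainThreshold` (inclusive)
#' and concordant-loss when `ratio_loss < lossThreshold` (strictly below,
#' matching the usual phrasing of the loss cutoff). Undefined ratios are
#' never concordant.
#'
#' @param ratios table from [expressionRatios()].
#' @param gainThreshold,lossThreshold ratio cutoffs (defaults 1.5 / 0.75).
#' @return `ratios` with added logical columns `concordant_gain`,
#'   `concordant_loss`.
#' @export
concordanceFlags <- function(ratios, gainThreshold = 1.5,
                             lossThreshold = 0.75) {
  ratios$concordant_gain <- !is.na(ratios$ratio_gain) &
    ratios$ratio_gain >= gainThreshold
  ratios$concordant_loss <- !is.na(ratios$ratio_loss) &
    ratios$ratio_loss < lossThreshold
  ratios
}

#' Flag genes inside direction-matched significant regions
#'
#' A gene is in a significant region when its interval intersects a
#' differential region whose direction matches the gene's concordant
#' direction (a concordant-loss gene inside a gain-enriched region does not
#' count).
#'
#' @param records concordance table (with `gene_id`, `concordant_gain`,
#'   `concordant_loss`).
#' @param genes gene `GRanges` matching `records$gene_id`.
#' @param regions region `GRanges` from [mergeRegions()].
#' @return `records` with added logical columns `in_region_gain`,
#'   `in_region_loss`, `in_significant_region`.
#' @export
restrictToRegions <- function(records, genes, regions) {
  ord <- match(records$gene_id, mcols(genes)$gene_id)
  g <- genes[ord]
  inDir <- function(dir) {
    if (!length(regions)) return(rep(FALSE, length(g)))
    countOverlaps(g, regions[mcols(regions)$direction == dir]) > 0
  }
  records$in_region_gain <- inDir("gain")
  records$in_region_loss <- inDir("loss")
  records$in_significant_region <-
    (records$concordant_gain & records$in_region_gain) |
    (records$concordant_loss & records$in_region_loss)
  records
}

#' Group-difference t-test on expression
#'
#' Two-sided independent-samples t-test per gene on the log2 gene-median-
#' centered expression between the `early` and `late` groups. Equal
#' variances are pooled by default (the classic independent-samples t-test);
#' set `varEqual = FALSE` for Welch. Genes with zero variance in both
#' groups get p = 1 with a warning.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param groups named character vector (`early`/`late`) indexed by sample
#'   id, or a vector aligned to the expression columns.
#' @param varEqual pool variances.
#' @return named numeric vector of p-values, one per gene.
#' @export
groupExpressionTest <- function(expr, groups, varEqual = TRUE) {
  cl <- centeredLogExpr(expr)
  if (!is.null(names(groups))) {
    if (!all(colnames(cl) %in% names(groups)))
      stop("groups missing for sample(s): ",
           paste(setdiff(colnames(cl), names(groups))[1:3], collapse = ", "))
    groups <- groups[colnames(cl)]
  }
  e <- groups == "early"; l <- groups == "late"
  if (sum(e) < 2 || sum(l) < 2)
    stop("need at least two samples per group")
  constant <- FALSE
  p <- apply(cl, 1L, function(v) {
    x <- v[e]; y <- v[l]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      constant <<- TRUE
      return(1)
    }
    t.test(x, y, var.equal = varEqual)$p.value
  })
  if (constant)
    warning("gene(s) with zero variance in both groups; p set to 1")
  p
}

#' Integrate copy-number calls with expression
#'
#' The full integration step: per-gene copy-number states, median-ratio
#' dosage statistics with concordance flags, restriction to direction-
#' matched significant regions, the early-vs-late expression t-test, and
#' the shortlist flag
#' (`(concordant_gain | concordant_loss) & in_significant_region &
#' group_p < alpha`).
#'
#' @param calls a [WindowCalls-class] (its `colData$group` provides the
#'   labels).
#' @param expr an [ExpressionMatrix-class].
#' @param genes gene `GRanges` with unique `gene_id`.
#' @param regions region `GRanges` from [mergeRegions()].
#' @param gainThreshold,lossThreshold concordance cutoffs.
#' @param alpha significance cutoff for the expression t-test.
#' @param varEqual pool variances in the t-test.
#' @return `data.frame`, one row per gene, sorted shortlist-first by
#'   increasing `group_p` then decreasing ratio extremity.
#' @export
integrateExpression <- function(calls, expr, genes, regions,
                                gainThreshold = 1.5, lossThreshold = 0.75,
                                alpha = 0.05, varEqual = TRUE) {
  states <- geneStates(genes, calls)
  rec <- expressionRatios(states, expr)
  rec <- concordanceFlags(rec, gainThreshold, lossThreshold)
  rec <- restrictToRegions(rec, genes, regions)
  grp <- as.character(colData(calls)$group)
  names(grp) <- colData(calls)$sample_id
  lin <- linearExpr(expr)[rec$gene_id, colnames(states), drop = FALSE]
  pv <- groupExpressionTest(ExpressionMatrix(lin), grp,
                            varEqual = varEqual)
  rec$group_p <- unname(pv[rec$gene_id])
  rec$shortlisted <- (rec$concordant_gain | rec$concordant_loss) &
    rec$in_significant_region & rec$group_p < alpha
  ## extremity: how far the concordant ratio departs from 1, either side
  extremity <- pmax(ifelse(is.na(rec$ratio_gain), 0, rec$ratio_gain),
                    ifelse(is.na(rec$ratio_loss) | rec$ratio_loss <= 0,
                           0, 1 / rec$ratio_loss))
  rec[order(!rec$shortlisted, rec$group_p, -extremity), , drop = FALSE]
}

#' Shortlisted candidate genes
#'
#' @param records table from [integrateExpression()].
#' @return the shortlisted rows, in the table's order (increasing p, then
#'   ratio extremity).
#' @export
shortlistGenes <- function(records) {
  records[records$shortlisted, , drop = FALSE]
}
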