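#' Construct a CGHExperiment
#'
#' @param lr numeric matrix of normalized log2 ratios, probes x samples.
#' @param probes `GRanges` probe map with unique mcols `probe_id`, sorted by
#'   chromosome then start.
#' @param sampleInfo optional `data.frame`/`DataFrame` with one row per
#'   sample; columns `group` (`early`/`late`/`control`) and `sex`
#'   (`female`/`male`) are recognized downstream. Row order must match the
#'   columns of `lr`.
#' @return A [CGHExperiment-class].
#' @export
CGHExperiment <- function(lr, probes, sampleInfo = NULL) {
  lr <- as.matrix(lr)
  if (is.null(colnames(lr)))
    colnames(lr) <- paste0("S", seq_len(ncol(lr)))
  if (is.null(sampleInfo)) {
    sampleInfo <- DataFrame(sample_id = colnames(lr),
                            group = NA_character_, sex = NA_character_)
  } else {
    sampleInfo <- DataFrame(sampleInfo)
    if (is.null(sampleInfo$sample_id)) sampleInfo$sample_id <- colnames(lr)
  }
  rownames(sampleInfo) <- colnames(lr)
  se <- SummarizedExperiment(assays = list(lr = lr), rowRanges = probes,
                             colData = sampleInfo)
  new("CGHExperiment", se)
}

#' @rdname CGHExperiment-class
#' @export
setMethod("lrMatrix", "CGHExperiment", function(x) assay(x, "lr"))

#' @rdname CGHExperiment-class
#' @export
setMethod("probeRanges", "CGHExperiment", function(x) rowRanges(x))

setMethod("show", "CGHExperiment", function(object) {
  grp <- table(colData(object)$group, useNA = "no")
  cat("CGHExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  if (length(grp))
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", paste(seqlevels(rowRanges(object)), collapse = ", "),
      "\n")
})

#' Construct an ExpressionMatrix
#'
#' @param linear positive numeric matrix, genes x samples, with unique
#'   row/column names.
#' @return An [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(linear) {
  new("ExpressionMatrix", linear = as.matrix(linear))
}

#' @rdname ExpressionMatrix-class
#' @export
setMethod("linearExpr", "ExpressionMatrix", function(x) x@linear)

#' @rdname ExpressionMatrix-class
#' @details `centeredLogExpr()` returns `log2(linear)` with each gene's
#'   median subtracted, so every gene has median exactly 0 — the
#'   quantile-normalized, gene-median-centered view used for group
#'   comparisons.
#' @export
setMethod("centeredLogExpr", "ExpressionMatrix", function(x) {
  lg <- log2(x@linear)
  med <- apply(lg, 1L, median)
  sweep(lg, 1L, med)
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat("ExpressionMatrix:", nrow(object@linear), "genes x",
      ncol(object@linear), "samples (positive linear scale)\n")
})
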