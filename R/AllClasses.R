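#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps countOverlaps reduce sort.GenomicRanges
#' @importFrom GenomeInfoDb Seqinfo seqlevels seqlengths seqinfo seqinfo<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData rowRanges<- colData<-
NULL

#' Reference genome skeleton for aCGH analysis
#'
#' A `GenomeBuild` holds the chromosome geometry every other step consults:
#' chromosome lengths, centromere intervals, acrocentric flags (whole p-arm
#' treated as unreliable) and sex-chromosome flags, plus the width of the
#' telomeric pad excluded at each chromosome end. The chromosome table uses
#' 0-based half-open centromere coordinates, matching the on-disk genome-spec
#' format; conversion to 1-based `GRanges` happens when masks are built.
#'
#' @slot chromosomes `data.frame` with columns `name`, `length`,
#'   `centromere_start`, `centromere_end`, `acrocentric`, `is_sex`.
#' @slot telomerePad Width in bp masked at both ends of every chromosome.
#'
#' @seealso [buildMasks()], [toyGenome()], [readGenomeSpec()]
#' @export
setClass("GenomeBuild",
  representation(chromosomes = "data.frame", telomerePad = "numeric")
)

setValidity("GenomeBuild", function(object) {
  ch <- object@chromosomes
  need <- c("name", "length", "centromere_start", "centromere_end",
            "acrocentric", "is_sex")
  if (!all(need %in% names(ch)))
    return(paste("chromosome table must have columns:",
                 paste(need, collapse = ", ")))
  msgs <- character(0)
  if (anyDuplicated(ch$name)) msgs <- c(msgs, "chromosome names must be unique")
  if (any(ch$length <= 0)) msgs <- c(msgs, "chromosome lengths must be positive")
  bad <- !(ch$centromere_start > 0 & ch$centromere_start < ch$centromere_end &
             ch$centromere_end < ch$length)
  if (any(bad))
    msgs <- c(msgs, paste0("centromere interval invalid for: ",
                           paste(ch$name[bad], collapse = ", ")))
  if (length(object@telomerePad) != 1L || object@telomerePad < 0)
    msgs <- c(msgs, "telomerePad must be a single non-negative number")
  else if (any(object@telomerePad > ch$length / 2))
    msgs <- c(msgs, "telomerePad exceeds half a chromosome length")
  ## acrocentric chromosomes carry their centromere in the proximal portion
  acro_bad <- ch$acrocentric & ch$centromere_start > 0.4 * ch$length
  if (any(acro_bad))
    msgs <- c(msgs, paste0("acrocentric chromosome with distal centromere: ",
                           paste(ch$name[acro_bad], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Probe-level aCGH experiment
#'
#' A thin `RangedSummarizedExperiment` subclass: one assay `"lr"` of
#' normalized log2 ratios (probes x samples), `rowRanges` holding the probe
#' map (sorted, non-overlapping, with a unique `probe_id`), and `colData`
#' with `sample_id`, `group` (`early`/`late`/`control` or `NA`) and `sex`.
#'
#' @seealso [CGHExperiment()], [callCopyNumber()]
#' @export
setClass("CGHExperiment", contains = "RangedSummarizedExperiment")

setValidity("CGHExperiment", function(object) {
  msgs <- character(0)
  if (!"lr" %in% assayNames(object))
    return("assay 'lr' (log2 ratios) is required")
  if (!is.numeric(assay(object, "lr")))
    msgs <- c(msgs, "assay 'lr' must be numeric")
  rr <- rowRanges(object)
  if (is.null(mcols(rr)$probe_id) || anyDuplicated(mcols(rr)$probe_id))
    msgs <- c(msgs, "rowRanges must carry unique 'probe_id'")
  if (is.unsorted(order(as.integer(seqnames(rr)), start(rr))))
    msgs <- c(msgs, "probes must be sorted by chromosome then start")
  if (length(msgs)) msgs else TRUE
})

#' Windowed copy-number calls
#'
#' `RangedSummarizedExperiment` subclass produced by [callCopyNumber()].
#' `rowRanges` are the fixed probe-count windows (with `probe_first`,
#' `probe_last`, `n_probes`, `masked`, `mask_reason`); assays are `"means"`
#' (window-averaged log2 ratios) and `"states"` (`"LOSS"`, `"NORMAL"`,
#' `"GAIN"`, `"MASKED"`). `metadata()` records the thresholds and the
#' probes-per-window setting.
#'
#' @seealso [buildWindows()], [segmentsFromCalls()], [testAllWindows()]
#' @export
setClass("WindowCalls", contains = "RangedSummarizedExperiment")

setValidity("WindowCalls", function(object) {
  msgs <- character(0)
  if (!all(c("means", "states") %in% assayNames(object)))
    return("assays 'means' and 'states' are required")
  st <- assay(object, "states")
  ok <- st %in% c("LOSS", "NORMAL", "GAIN", "MASKED")
  if (!all(ok)) msgs <- c(msgs, "states must be LOSS/NORMAL/GAIN/MASKED")
  masked <- mcols(rowRanges(object))$masked
  if (is.null(masked)) msgs <- c(msgs, "rowRanges must carry 'masked'")
  else if (ncol(object) > 0 &&
           !all(st[masked, , drop = FALSE] == "MASKED"))
    msgs <- c(msgs, "masked windows must be MASKED in every sample")
  if (length(msgs)) msgs else TRUE
})

#' Gene x sample expression matrix on a positive linear scale
#'
#' Expression is stored on the positive linear scale; the log2 gene-median-
#' centered view used by the group t-test is derived on demand by
#' [centeredLogExpr()]. The median-ratio dosage statistic always uses the
#' linear view (ratios of medians of centered log values would be
#' ill-defined because centered values can be negative or zero).
#'
#' @slot linear numeric matrix, genes x samples, strictly positive.
#' @seealso [simulateExpression()], [integrateExpression()]
#' @export
setClass("ExpressionMatrix", representation(linear = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  x <- object@linear
  msgs <- character(0)
  if (!is.numeric(x)) return("expression matrix must be numeric")
  if (any(!is.finite(x)) || any(x <= 0))
    msgs <- c(msgs, "linear expression values must be finite and > 0")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    msgs <- c(msgs, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msgs <- c(msgs, "sample ids (colnames) must be present and unique")
  if (length(msgs)) msgs else TRUE
})
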