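#' Read/write the probe-level ratio table
#'
#' Tab-separated, one probe per row: `chrom`, `start`, `end` (0-based
#' half-open, as in BED), `probe_id`, then one numeric column per sample.
#' Missing measurements are written as `NA` and excluded from window means
#' on the way back in. Writers format floats at 6 significant digits and
#' are byte-deterministic.
#'
#' @param path file path.
#' @param missingToken token marking a missing ratio.
#' @return [readProbeTable()] returns a [CGHExperiment-class] (with empty
#'   group/sex metadata; attach a metadata table separately);
#'   [writeProbeTable()] returns `path` invisibly.
#' @export
readProbeTable <- function(path, missingToken = "NA") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  need <- c("chrom", "start", "end", "probe_id")
  if (!all(need %in% names(df)))
    stop("probe table must start with columns: ",
         paste(need, collapse = ", "))
  sampleCols <- setdiff(names(df), need)
  if (!length(sampleCols)) stop("probe table has no sample columns")
  start0 <- as.numeric(df$start); end0 <- as.numeric(df$end)
  if (anyNA(start0) || anyNA(end0)) stop("non-numeric probe coordinates")
  ## sortedness: strictly increasing starts within chromosome
  byChr <- split(seq_len(nrow(df)), df$chrom)
  for (rows in byChr) {
    bad <- which(diff(start0[rows]) <= 0)
    if (length(bad))
      stop("probes not sorted by increasing start: row ",
           rows[bad[1] + 1L], " (", df$probe_id[rows[bad[1] + 1L]], ")")
  }
  lr <- matrix(NA_real_, nrow(df), length(sampleCols),
               dimnames = list(df$probe_id, sampleCols))
  for (j in seq_along(sampleCols)) {
    raw <- df[[sampleCols[j]]]
    isMiss <- raw == missingToken
    v <- suppressWarnings(as.numeric(raw))
    badRow <- which(is.na(v) & !isMiss)
    if (length(badRow))
      stop("non-numeric ratio at row ", badRow[1],
           ", column '", sampleCols[j], "'")
    v[isMiss] <- NA_real_
    lr[, j] <- v
  }
  probes <- GRanges(df$chrom, IRanges(start0 + 1, end0),
                    probe_id = df$probe_id)
  CGHExperiment(lr, probes)
}

#' @rdname readProbeTable
#' @param cgh a [CGHExperiment-class] to serialize.
#' @export
writeProbeTable <- function(cgh, path, missingToken = "NA") {
  probes <- probeRanges(cgh)
  lr <- lrMatrix(cgh)
  vals <- apply(lr, 2L, function(v) {
    out <- fmtNum(v)
    out[is.na(v)] <- missingToken
    out
  })
  df <- data.frame(chrom = as.character(seqnames(probes)),
                   start = start(probes) - 1L, end = end(probes),
                   probe_id = mcols(probes)$probe_id,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample segment table for SEG export
#'
#' Condenses a [WindowCalls-class] into per-sample segments with probe
#' counts and mean log2 ratio (probe-count-weighted mean of window means).
#'
#' @param calls a [WindowCalls-class].
#' @param bridgeMasked passed to [segmentsFromCalls()].
#' @return `data.frame` with `sample_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), `n_probes`, `seg_mean`, `direction`.
#' @export
segTable <- function(calls, bridgeMasked = TRUE) {
  seg <- segmentsFromCalls(calls, bridgeMasked = bridgeMasked)
  if (!nrow(seg))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_probes = integer(0), seg_mean = numeric(0),
                      direction = character(0)))
  grid <- windowRanges(calls)
  means <- callMeans(calls)
  np <- mcols(grid)$n_probes
  seg$n_probes <- mapply(function(wf, wl) sum(np[wf:wl]),
                         seg$window_first, seg$window_last)
  seg$seg_mean <- mapply(function(wf, wl, s) {
    w <- wf:wl
    sum(means[w, s] * np[w], na.rm = TRUE) /
      sum(np[w][!is.na(means[w, s])])
  }, seg$window_first, seg$window_last, seg$sample_id)
  seg[, c("sample_id", "chrom", "start", "end", "n_probes", "seg_mean",
          "direction")]
}

#' Read/write SEG files
#'
#' Standard segmented-data exchange: header `Sample Chromosome Start End
#' Num_Probes Segment_Mean`, tab-separated, 1-based inclusive coordinates.
#'
#' @param segments table from [segTable()] (columns `sample_id`, `chrom`,
#'   `start`, `end`, `n_probes`, `seg_mean`).
#' @param path file path.
#' @return [readSeg()] returns the segment `data.frame`; [writeSeg()]
#'   returns `path` invisibly.
#' @export
writeSeg <- function(segments, path) {
  ## overlap check per sample
  if (nrow(segments)) {
    bySample <- split(segments, paste(segments$sample_id, segments$chrom))
    for (s in bySample) {
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping segments for sample ", s$sample_id[1],
             " on ", s$chrom[1])
    }
  }
  lines <- c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
             if (nrow(segments))
               sprintf("%s\t%s\t%d\t%d\t%d\t%s",
                       segments$sample_id, segments$chrom,
                       as.integer(segments$start), as.integer(segments$end),
                       as.integer(segments$n_probes),
                       fmtNum(segments$seg_mean)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSeg
#' @export
readSeg <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
            "Segment_Mean")
  if (!identical(names(df), need))
    stop("not a SEG file (expected header: ",
         paste(need, collapse = " "), ")")
  data.frame(sample_id = as.character(df$Sample),
             chrom = as.character(df$Chromosome),
             start = df$Start, end = df$End, n_probes = df$Num_Probes,
             seg_mean = df$Segment_Mean, stringsAsFactors = FALSE)
}

#' Read a gene annotation BED
#'
#' Standard BED (0-based half-open); the name column becomes `gene_id`,
#' which must be unique.
#'
#' @param path BED file.
#' @return `GRanges` with `gene_id`.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$name))
    stop("gene BED needs a name column with gene ids")
  if (anyDuplicated(mcols(gr)$name))
    stop("duplicate gene id(s): ",
         paste(unique(mcols(gr)$name[duplicated(mcols(gr)$name)])[1:3],
               collapse = ", "))
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 gene_id = mcols(gr)$name)
  sort(out)
}

#' Write gene or truth intervals as BED
#'
#' @param gr `GRanges`; mcols `gene_id` (or `name`) provides the name
#'   column.
#' @param path output file.
#' @export
writeGeneBed <- function(gr, path) {
  nm <- mcols(gr)$gene_id
  if (is.null(nm)) nm <- mcols(gr)$name
  if (is.null(nm)) nm <- paste0("feat", seq_along(gr))
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr), nm)
  writeLines(lines, path)
  invisible(path)
}

#' Write differential regions as BED
#'
#' 0-based half-open; the name column packs
#' `direction|avg_p|enriched_group[|carriersEarly/carriersLate]`.
#'
#' @param regions `GRanges` from [mergeRegions()] (optionally annotated by
#'   [annotateSro()]).
#' @param path output file.
#' @export
writeRegionsBed <- function(regions, path) {
  m <- mcols(regions)
  name <- sprintf("%s|%s|%s", m$direction, fmtNum(m$avg_p),
                  m$enriched_group)
  if (!is.null(m$carriers_early))
    name <- sprintf("%s|%d/%d", name, m$carriers_early, m$carriers_late)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", as.character(seqnames(regions)),
                   start(regions) - 1L, end(regions), name,
                   fmtNum(m$avg_p))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write the expression matrix TSV
#'
#' First column `gene_id`, one numeric column per sample, positive linear
#' scale.
#'
#' @param path file path.
#' @return [readExpression()] returns an [ExpressionMatrix-class].
#' @export
readExpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id")
    stop("expression table must start with a gene_id column")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s) in expression table: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3],
               collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  ExpressionMatrix(m)
}

#' @rdname readExpression
#' @param expr an [ExpressionMatrix-class].
#' @export
writeExpression <- function(expr, path) {
  lin <- linearExpr(expr)
  df <- data.frame(gene_id = rownames(lin),
                   apply(lin, 2L, fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `group` (`early` or `late`;
#' `control` is tolerated for control tracks), `sex` (`female`/`male`).
#'
#' @param path file path.
#' @return [readMetadata()] returns a `data.frame`.
#' @export
readMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "sex")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  badG <- setdiff(unique(df$group), c("early", "late", "control"))
  if (length(badG))
    stop("unknown group label(s): ", paste(badG, collapse = ", "),
         " (expected early/late)")
  badS <- setdiff(unique(df$sex), c("female", "male", NA))
  if (length(badS))
    stop("unknown sex label(s): ", paste(badS, collapse = ", "))
  df[, need]
}

#' @rdname readMetadata
#' @param metadata `data.frame` with `sample_id`, `group`, `sex`.
#' @export
writeMetadata <- function(metadata, path) {
  write.table(metadata[, c("sample_id", "group", "sex")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that ratio table, metadata and expression matrix name the same
#' samples
#'
#' @param cgh a [CGHExperiment-class].
#' @param metadata table from [readMetadata()].
#' @param expr optional [ExpressionMatrix-class].
#' @return invisibly `TRUE`; otherwise a named error per mismatch.
#' @export
checkSampleConsistency <- function(cgh, metadata, expr = NULL) {
  sRatio <- colnames(lrMatrix(cgh))
  miss <- setdiff(sRatio, metadata$sample_id)
  if (length(miss))
    stop("sample(s) in ratio table but not metadata: ",
         paste(miss, collapse = ", "))
  if (!is.null(expr)) {
    sExpr <- colnames(linearExpr(expr))
    miss2 <- setdiff(sExpr, metadata$sample_id)
    if (length(miss2))
      stop("sample(s) in expression matrix but not metadata: ",
           paste(miss2, collapse = ", "))
  }
  invisible(TRUE)
}

#' Attach a metadata table to a CGHExperiment
#'
#' @param cgh a [CGHExperiment-class].
#' @param metadata table from [readMetadata()].
#' @return the experiment with `group`/`sex` filled in from the table.
#' @export
attachMetadata <- function(cgh, metadata) {
  checkSampleConsistency(cgh, metadata)
  idx <- match(colnames(lrMatrix(cgh)), metadata$sample_id)
  cd <- colData(cgh)
  cd$group <- metadata$group[idx]
  cd$sex <- metadata$sex[idx]
  colData(cgh) <- cd
  cgh
}
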