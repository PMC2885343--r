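#' Construct a GenomeBuild
#'
#' @param name character vector of unique chromosome names.
#' @param length chromosome lengths in bp.
#' @param centromereStart,centromereEnd centromere interval per chromosome,
#'   0-based half-open (matching the genome-spec TSV format).
#' @param acrocentric logical; whole p-arm treated as unreliable and masked.
#' @param isSex logical; chromosome fully masked for tumor analysis.
#' @param telomerePad bp masked at each chromosome end. The conventional
#'   exclusion of "telomere regions" has no canonical width, so it is a
#'   parameter; the default is two 10-probe windows at 6 kb spacing.
#'
#' @return A [GenomeBuild-class] object.
#' @examples
#' gb <- GenomeBuild("chr1", 1e6, 4.5e5, 4.7e5, telomerePad = 1e4)
#' buildMasks(gb)
#' @export
GenomeBuild <- function(name, length, centromereStart, centromereEnd,
                        acrocentric = FALSE, isSex = FALSE,
                        telomerePad = 120000) {
  n <- base::length(name)
  ch <- data.frame(
    name = as.character(name),
    length = as.numeric(length),
    centromere_start = as.numeric(centromereStart),
    centromere_end = as.numeric(centromereEnd),
    acrocentric = rep_len(as.logical(acrocentric), n),
    is_sex = rep_len(as.logical(isSex), n),
    stringsAsFactors = FALSE
  )
  new("GenomeBuild", chromosomes = ch, telomerePad = as.numeric(telomerePad))
}

#' @rdname GenomeBuild-class
#' @export
setMethod("chromTable", "GenomeBuild", function(x) x@chromosomes)

#' @rdname GenomeBuild-class
#' @export
setMethod("chromLengths", "GenomeBuild", function(x) {
  stats::setNames(x@chromosomes$length, x@chromosomes$name)
})

#' @rdname GenomeBuild-class
#' @export
setMethod("telomerePad", "GenomeBuild", function(x) x@telomerePad)

#' @rdname GenomeBuild-class
#' @export
setMethod("autosomeNames", "GenomeBuild", function(x) {
  x@chromosomes$name[!x@chromosomes$is_sex]
})

setMethod("show", "GenomeBuild", function(object) {
  ch <- object@chromosomes
  cat("GenomeBuild with", nrow(ch), "chromosomes (",
      sum(ch$is_sex), "sex,", sum(ch$acrocentric), "acrocentric )\n")
  cat("  total length:", fmtNum(sum(ch$length)), "bp;",
      "telomere pad:", fmtNum(object@telomerePad), "bp\n")
})

seqinfoOf <- function(genome) {
  ch <- chromTable(genome)
  Seqinfo(seqnames = ch$name, seqlengths = as.integer(ch$length))
}

#' Exclusion masks for a genome build
#'
#' Builds the interval set every analysis step excludes: a centromere
#' interval per chromosome, a telomeric pad at both chromosome ends, the
#' whole p-arm of acrocentric chromosomes, and whole sex chromosomes.
#' Windows intersecting any mask are set to `MASKED` by [callCopyNumber()],
#' and differential regions spanning a centromere are discarded by
#' [mergeRegions()].
#'
#' @param genome a [GenomeBuild-class].
#' @return `GRanges` with an mcols column `reason` in
#'   `centromere`, `telomere`, `acrocentric_p`, `sex`.
#' @export
buildMasks <- function(genome) {
  validObject(genome)
  ch <- chromTable(genome)
  pad <- telomerePad(genome)
  si <- seqinfoOf(genome)

  gr_list <- list()
  ## centromeres (0-based half-open table -> 1-based closed GRanges)
  gr_list$centromere <- GRanges(ch$name,
    IRanges(ch$centromere_start + 1, ch$centromere_end),
    reason = "centromere", seqinfo = si)
  if (pad > 0) {
    gr_list$tel_p <- GRanges(ch$name, IRanges(1, pad),
                             reason = "telomere", seqinfo = si)
    gr_list$tel_q <- GRanges(ch$name, IRanges(ch$length - pad + 1, ch$length),
                             reason = "telomere", seqinfo = si)
  }
  acro <- ch[ch$acrocentric, , drop = FALSE]
  if (nrow(acro))
    gr_list$acro <- GRanges(acro$name, IRanges(1, acro$centromere_start),
                            reason = "acrocentric_p", seqinfo = si)
  sex <- ch[ch$is_sex, , drop = FALSE]
  if (nrow(sex))
    gr_list$sex <- GRanges(sex$name, IRanges(1, sex$length),
                           reason = "sex", seqinfo = si)
  out <- sort(do.call(c, unname(gr_list)))
  out
}

#' Deterministic toy genome
#'
#' Builds a small multi-chromosome genome with seeded centromere placement,
#' used by the synthetic-cohort generator and throughout the test suite.
#' Centromeres of non-acrocentric chromosomes land near mid-chromosome with
#' jitter; acrocentric centromeres sit in the proximal ~15% of the
#' chromosome. Optionally appends an X and a smaller Y chromosome flagged
#' `is_sex`.
#'
#' @param nChrom number of autosomes (>= 1).
#' @param chromLength autosome length in bp.
#' @param seed integer seed; calls with equal arguments are identical.
#' @param includeSex append chrX (same length) and chrY (40% length).
#' @param acrocentric integer indices of autosomes made acrocentric.
#' @param telomerePad passed to [GenomeBuild()].
#' @return A [GenomeBuild-class].
#' @export
toyGenome <- function(nChrom, chromLength, seed = 1, includeSex = FALSE,
                      acrocentric = integer(0), telomerePad = 120000) {
  stopifnot(nChrom >= 1, chromLength > 4 * telomerePad)
  withSeed(childSeed(seed, 101), {
    names <- paste0("chr", seq_len(nChrom))
    acro <- seq_len(nChrom) %in% acrocentric
    mid <- ifelse(acro,
                  chromLength * runif(nChrom, 0.12, 0.18),
                  chromLength * runif(nChrom, 0.40, 0.60))
    cw <- round(chromLength * 0.03)
    cs <- round(mid - cw / 2)
    lens <- rep(chromLength, nChrom)
    sex <- rep(FALSE, nChrom)
    if (includeSex) {
      names <- c(names, "chrX", "chrY")
      lens <- c(lens, chromLength, round(0.4 * chromLength))
      csx <- round(c(chromLength * 0.45, 0.4 * chromLength * 0.45))
      cs <- c(cs, csx)
      cw2 <- c(rep(cw, nChrom), rep(cw, 2))
      acro <- c(acro, FALSE, FALSE)
      sex <- c(sex, TRUE, TRUE)
      GenomeBuild(names, lens, cs, cs + cw2, acrocentric = acro,
                  isSex = sex, telomerePad = telomerePad)
    } else {
      GenomeBuild(names, lens, cs, cs + cw, acrocentric = acro,
                  isSex = sex, telomerePad = telomerePad)
    }
  })
}

#' Read/write a genome specification TSV
#'
#' Tab-separated with header columns `name`, `length`, `centromere_start`,
#' `centromere_end`, `acrocentric` (0/1), `is_sex` (0/1); centromere
#' coordinates 0-based half-open.
#'
#' @param path file path.
#' @param telomerePad pad applied on read (not stored in the file).
#' @return [readGenomeSpec()] returns a [GenomeBuild-class];
#'   [writeGenomeSpec()] returns `path` invisibly.
#' @export
readGenomeSpec <- function(path, telomerePad = 120000) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "length", "centromere_start", "centromere_end",
            "acrocentric", "is_sex")
  if (!all(need %in% names(df)))
    stop("genome spec must have columns: ", paste(need, collapse = ", "))
  GenomeBuild(df$name, df$length, df$centromere_start, df$centromere_end,
              acrocentric = df$acrocentric != 0, isSex = df$is_sex != 0,
              telomerePad = telomerePad)
}

#' @rdname readGenomeSpec
#' @param genome a [GenomeBuild-class] to serialize.
#' @export
writeGenomeSpec <- function(genome, path) {
  ch <- chromTable(genome)
  out <- data.frame(name = ch$name, length = ch$length,
                    centromere_start = ch$centromere_start,
                    centromere_end = ch$centromere_end,
                    acrocentric = as.integer(ch$acrocentric),
                    is_sex = as.integer(ch$is_sex))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export masks as BED
#'
#' BED is 0-based half-open; the mask `reason` goes in the name column.
#' @param masks `GRanges` from [buildMasks()].
#' @param path output file.
#' @export
writeMasksBed <- function(masks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(seqnames(masks)), start(masks) - 1L,
                   end(masks), as.character(mcols(masks)$reason))
  writeLines(lines, path)
  invisible(path)
}
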