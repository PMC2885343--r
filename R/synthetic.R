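#' Synthetic probe map
#'
#' Tiles each chromosome with probes at a fixed mean spacing (default 6 kb,
#' the resolution of a 385k-probe whole-genome oligo array) with optional
#' seeded start jitter. With `jitterFrac = 0` probes are exactly equally
#' spaced.
#'
#' @param genome a [GenomeBuild-class].
#' @param spacing mean inter-probe distance in bp (>= 1, and at most the
#'   shortest chromosome length).
#' @param probeLength oligo footprint in bp.
#' @param jitterFrac uniform start jitter as a fraction of `spacing`;
#'   must satisfy `probeLength <= spacing * (1 - jitterFrac)` so probes
#'   never overlap.
#' @param seed integer seed.
#' @return sorted `GRanges` with unique `probe_id`.
#' @export
makeProbeMap <- function(genome, spacing = 6000, probeLength = 50,
                         jitterFrac = 0.25, seed = 1) {
  stopifnot(spacing >= 1, jitterFrac >= 0, jitterFrac < 1)
  ch <- chromTable(genome)
  if (any(spacing > ch$length))
    stop("spacing exceeds the length of chromosome ",
         ch$name[which(spacing > ch$length)[1]])
  if (probeLength > spacing * (1 - jitterFrac))
    stop("probeLength too large for the requested spacing/jitter")
  si <- seqinfoOf(genome)
  withSeed(childSeed(seed, 211), {
    parts <- lapply(seq_len(nrow(ch)), function(i) {
      n <- floor(ch$length[i] / spacing)
      base0 <- (seq_len(n) - 1) * spacing
      jit <- if (jitterFrac > 0)
        floor(runif(n) * jitterFrac * spacing) else 0
      start0 <- base0 + jit
      end0 <- pmin(start0 + probeLength, ch$length[i])
      GRanges(ch$name[i], IRanges(start0 + 1, end0),
              probe_id = sprintf("%s_P%06d", ch$name[i], seq_len(n)),
              seqinfo = si)
    })
    sort(do.call(c, parts))
  })
}

#' Synthetic gene annotation
#'
#' Uniformly placed gene intervals on the autosomes (length-proportional
#' chromosome choice). Genes may overlap each other, as real annotations do.
#'
#' @param genome a [GenomeBuild-class].
#' @param nGenes number of genes.
#' @param geneLength gene footprint in bp.
#' @param seed integer seed.
#' @return sorted `GRanges` with unique `gene_id`.
#' @export
makeGeneMap <- function(genome, nGenes = 520, geneLength = 20000, seed = 1) {
  ch <- chromTable(genome)
  auto <- ch[!ch$is_sex, , drop = FALSE]
  si <- seqinfoOf(genome)
  withSeed(childSeed(seed, 223), {
    idx <- sample.int(nrow(auto), nGenes, replace = TRUE,
                      prob = auto$length)
    start0 <- floor(runif(nGenes) * (auto$length[idx] - geneLength))
    gr <- GRanges(auto$name[idx], IRanges(start0 + 1, start0 + geneLength),
                  gene_id = sprintf("G%05d", seq_len(nGenes)), seqinfo = si)
    sort(gr)
  })
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study conditions the generator emulates: 23 early- vs
#' 17 late-onset tumors; a backbone of shared colorectal-cancer-typical
#' aberrations carried at ~60% penetrance in both groups; a set of
#' early-onset-specific loci carried at 14/23 vs 2/17; per-probe Gaussian
#' log2 noise whose 10-probe window means put the +/-0.1 calling thresholds
#' at a 0.005 false-positive rate (`0.1*sqrt(10)/qnorm(0.995)`); and event
#' magnitudes corresponding to single-copy changes at ~50% tumor-cell
#' content (`log2(2.5/2)` for gains, `log2(1.5/2)` for losses), which also
#' places the replicate concordance R-squared of re-hybridized samples in
#' the 0.7-0.9 band seen on real arrays.
#'
#' @param nEarly,nLate group sizes (>= 1).
#' @param nSharedLoci,nSpecificLoci numbers of planted shared and
#'   early-specific recurrent loci.
#' @param sharedPenetrance carrier probability of shared loci in both groups.
#' @param specificPenetranceEarly,specificPenetranceLate carrier
#'   probabilities of early-specific loci per group.
#' @param magnitudeGain,magnitudeLoss log2-ratio shift of planted gains
#'   (positive) and losses (negative).
#' @param noiseSd per-probe Gaussian noise sd (log2 scale), >= 0.
#' @param eventSizeBp,eventSizeJitter mean planted event size and its
#'   uniform relative jitter.
#' @param dosageEffect multiplicative expression shift per copy-number state
#'   for dosage-coupled genes (>= 1). The default 2.2 was fixed by a
#'   design-time power analysis of the group t-test under the planted
#'   14/23-vs-2/17 carrier contrast (per-gene power ~0.97 at log2 noise sd
#'   0.3), so planted-gene recovery experiments are adequately powered.
#' @param exactCarriers if `TRUE` (default) each event has exactly
#'   `round(p * n)` carriers per group (which samples is seeded-random), so
#'   planted penetrance patterns are reproduced exactly; if `FALSE` carriers
#'   are binomial.
#' @param seed master seed expanded into per-component substreams.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nEarly = 23, nLate = 17,
                         nSharedLoci = 8, nSpecificLoci = 6,
                         sharedPenetrance = 0.6,
                         specificPenetranceEarly = 14 / 23,
                         specificPenetranceLate = 2 / 17,
                         magnitudeGain = log2(2.5 / 2),
                         magnitudeLoss = log2(1.5 / 2),
                         noiseSd = 0.1 * sqrt(10) / qnorm(0.995),
                         eventSizeBp = 8e6, eventSizeJitter = 0.5,
                         dosageEffect = 2.2,
                         exactCarriers = TRUE, seed = 1) {
  cfg <- list(nEarly = nEarly, nLate = nLate, nSharedLoci = nSharedLoci,
              nSpecificLoci = nSpecificLoci,
              sharedPenetrance = sharedPenetrance,
              specificPenetranceEarly = specificPenetranceEarly,
              specificPenetranceLate = specificPenetranceLate,
              magnitudeGain = magnitudeGain, magnitudeLoss = magnitudeLoss,
              noiseSd = noiseSd, eventSizeBp = eventSizeBp,
              eventSizeJitter = eventSizeJitter,
              dosageEffect = dosageEffect,
              exactCarriers = isTRUE(exactCarriers), seed = seed)
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  if (cfg$nEarly < 1 || cfg$nLate < 1)
    stop("both groups need at least one sample")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  if (cfg$magnitudeGain <= 0) stop("magnitudeGain must be positive")
  if (cfg$magnitudeLoss >= 0) stop("magnitudeLoss must be negative")
  if (cfg$dosageEffect < 1) stop("dosageEffect must be >= 1")
  ps <- c(cfg$sharedPenetrance, cfg$specificPenetranceEarly,
          cfg$specificPenetranceLate)
  if (any(ps < 0 | ps > 1)) stop("penetrances must lie in [0, 1]")
  invisible(cfg)
}

## Place `n` non-overlapping events on unmasked autosomal territory.
placeEvents <- function(genome, n, sizeBp, sizeJitter, buffer = 1e6) {
  ch <- chromTable(genome)
  auto <- ch[!ch$is_sex, , drop = FALSE]
  masks <- buildMasks(genome)
  si <- seqinfoOf(genome)
  placed <- GRanges(seqinfo = si)
  tries <- 0L
  while (length(placed) < n && tries < 5000L) {
    tries <- tries + 1L
    i <- sample.int(nrow(auto), 1L, prob = auto$length)
    size <- round(sizeBp * (1 + sizeJitter * (runif(1) * 2 - 1)))
    size <- min(size, auto$length[i] - 2 * telomerePad(genome) - 2)
    start0 <- floor(runif(1) * (auto$length[i] - size))
    cand <- GRanges(auto$name[i], IRanges(start0 + 1, start0 + size),
                    seqinfo = si)
    if (length(findOverlaps(cand, masks)) > 0) next
    if (length(placed) &&
        length(findOverlaps(cand, placed, maxgap = buffer)) > 0) next
    placed <- c(placed, cand)
  }
  if (length(placed) < n)
    stop("could not place ", n, " events on this genome; ",
         "reduce event size or count")
  placed
}

#' Simulate a two-group aCGH tumor cohort with planted aberrations
#'
#' Per-probe log2 ratio = sum of the magnitudes of the planted events the
#' sample carries at that probe, plus Gaussian noise. Shared events are
#' carried at equal penetrance in both groups; early-specific events at the
#' configured contrast (default 14/23 vs 2/17). Fully reproducible for a
#' fixed `config$seed`.
#'
#' @param genome a [GenomeBuild-class].
#' @param probes probe map `GRanges` from [makeProbeMap()].
#' @param config a [cohortConfig()].
#' @param events optional explicit event table overriding the seeded
#'   placement: `data.frame` with `chrom`, `start`, `end` (1-based closed),
#'   `direction` (`gain`/`loss`), `magnitude`, `pEarly`, `pLate`,
#'   `group_specific` (logical).
#' @return list with `cgh` (a [CGHExperiment-class] whose `colData` carries
#'   `group` and `sex`), `truth` (per-sample carried events as `GRanges`
#'   with `sample_id`, `direction`, `magnitude`, `event_id`,
#'   `group_specific`), and `events` (the event table with realized carrier
#'   counts `carriersEarly`, `carriersLate`).
#' @export
simulateCohort <- function(genome, probes, config = cohortConfig(),
                           events = NULL) {
  validateCohortConfig(config)
  si <- seqinfoOf(genome)
  nE <- config$nEarly; nL <- config$nLate
  samples <- c(sprintf("E%02d", seq_len(nE)), sprintf("L%02d", seq_len(nL)))
  group <- rep(c("early", "late"), c(nE, nL))
  sex <- rep_len(c("female", "male"), nE + nL)

  if (is.null(events)) {
    events <- withSeed(childSeed(config$seed, 301), {
      loci <- placeEvents(genome, config$nSharedLoci + config$nSpecificLoci,
                          config$eventSizeBp, config$eventSizeJitter)
      nTot <- length(loci)
      specific <- rep(c(FALSE, TRUE),
                      c(config$nSharedLoci, config$nSpecificLoci))
      direction <- rep_len(c("gain", "loss"), nTot)
      data.frame(
        chrom = as.character(seqnames(loci)),
        start = start(loci), end = end(loci),
        direction = direction,
        magnitude = ifelse(direction == "gain",
                           config$magnitudeGain, config$magnitudeLoss),
        pEarly = ifelse(specific, config$specificPenetranceEarly,
                        config$sharedPenetrance),
        pLate = ifelse(specific, config$specificPenetranceLate,
                       config$sharedPenetrance),
        group_specific = specific,
        stringsAsFactors = FALSE)
    })
  }
  events$event_id <- sprintf("EV%03d", seq_len(nrow(events)))

  carriers <- withSeed(childSeed(config$seed, 302), {
    lapply(seq_len(nrow(events)), function(i) {
      pickGroup <- function(p, n) {
        if (config$exactCarriers) {
          k <- round(p * n)
          sort(sample.int(n, k))
        } else {
          which(rbinom(n, 1L, p) == 1L)
        }
      }
      list(early = pickGroup(events$pEarly[i], nE),
           late = pickGroup(events$pLate[i], nL))
    })
  })
  events$carriersEarly <- vapply(carriers, function(x) length(x$early), 0L)
  events$carriersLate <- vapply(carriers, function(x) length(x$late), 0L)

  ## per-sample truth ranges
  truth_rows <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    ids <- c(samples[carriers[[i]]$early], samples[nE + carriers[[i]]$late])
    if (!length(ids)) return(NULL)
    data.frame(chrom = events$chrom[i], start = events$start[i],
               end = events$end[i], sample_id = ids,
               direction = events$direction[i],
               magnitude = events$magnitude[i],
               event_id = events$event_id[i],
               group_specific = events$group_specific[i],
               stringsAsFactors = FALSE)
  }))
  truth <- if (is.null(truth_rows)) {
    GRanges(seqinfo = si)
  } else {
    GRanges(truth_rows$chrom, IRanges(truth_rows$start, truth_rows$end),
            sample_id = truth_rows$sample_id,
            direction = truth_rows$direction,
            magnitude = truth_rows$magnitude,
            event_id = truth_rows$event_id,
            group_specific = truth_rows$group_specific, seqinfo = si)
  }

  lr <- withSeed(childSeed(config$seed, 303), {
    m <- matrix(if (config$noiseSd > 0)
                  rnorm(length(probes) * length(samples),
                        sd = config$noiseSd) else 0,
                nrow = length(probes), ncol = length(samples),
                dimnames = list(mcols(probes)$probe_id, samples))
    if (length(truth)) {
      hits <- findOverlaps(probes, truth)
      if (length(hits)) {
        j <- match(mcols(truth)$sample_id[subjectHits(hits)], samples)
        mag <- mcols(truth)$magnitude[subjectHits(hits)]
        idx <- cbind(queryHits(hits), j)
        ## sum magnitudes where events stack (they are placed disjoint,
        ## but explicit event tables may overlap)
        for (k in seq_along(mag)) m[idx[k, 1L], idx[k, 2L]] <-
            m[idx[k, 1L], idx[k, 2L]] + mag[k]
      }
    }
    m
  })

  cgh <- CGHExperiment(lr, probes,
                       DataFrame(sample_id = samples, group = group,
                                 sex = sex))
  list(cgh = cgh, truth = truth, events = events)
}

#' Simulate a control hybridization
#'
#' `self_self` emulates re-hybridizing one reference pool against itself:
#' pure per-probe noise, the input for threshold calibration.
#' `female_vs_male` emulates hybridizing the female reference pool against
#' the male pool: a constant positive shift on all chrX probes (two X copies
#' vs one) and a negative shift on all chrY probes, noise elsewhere; after
#' calling, the whole of X reads as gain and the whole of Y as loss.
#'
#' @param probes probe map `GRanges`.
#' @param noiseSd per-probe Gaussian noise sd (>= 0).
#' @param kind `"self_self"` or `"female_vs_male"`.
#' @param seed integer seed.
#' @param xShift,yShift log2 shifts applied on chrX/chrY probes for the
#'   sex-mismatch control (defaults are intensity-attenuated single-copy
#'   differences as seen on real arrays).
#' @param sexChrom names of the X and Y chromosomes in the probe map.
#' @return a one-sample [CGHExperiment-class] with `group = "control"`.
#' @export
simulateControlPair <- function(probes, noiseSd,
                                kind = c("self_self", "female_vs_male"),
                                seed = 1, xShift = 0.8, yShift = -1.2,
                                sexChrom = c(X = "chrX", Y = "chrY")) {
  kind <- match.arg(kind)
  chr <- as.character(seqnames(probes))
  if (kind == "female_vs_male" &&
      !all(sexChrom %in% chr))
    stop("female_vs_male control requires probes on ",
         paste(sexChrom, collapse = " and "))
  vals <- withSeed(childSeed(seed, 401), {
    v <- if (noiseSd > 0) rnorm(length(probes), sd = noiseSd)
         else numeric(length(probes))
    if (kind == "female_vs_male") {
      v[chr == sexChrom[["X"]]] <- v[chr == sexChrom[["X"]]] + xShift
      v[chr == sexChrom[["Y"]]] <- v[chr == sexChrom[["Y"]]] + yShift
    }
    v
  })
  lr <- matrix(vals, ncol = 1,
               dimnames = list(mcols(probes)$probe_id, kind))
  CGHExperiment(lr, probes,
                DataFrame(sample_id = kind, group = "control",
                          sex = NA_character_))
}

#' Simulate dosage-coupled gene expression
#'
#' Generates a positive linear-scale expression matrix in which
#' dosage-coupled genes overlapping a carried gain (loss) have their
#' expectation multiplied (divided) by `dosageEffect`, while decoupled genes
#' ignore copy number entirely. Noise is log-normal (Gaussian on log2 with
#' sd `noiseSdExpr`). With `dosageEffect = 1` expression is independent of
#' copy number; with `noiseSdExpr = 0` the median-ratio statistic of a
#' coupled gained gene is exactly `dosageEffect`.
#'
#' @param genes gene annotation `GRanges` with `gene_id`.
#' @param truth per-sample carried events (`GRanges` from
#'   [simulateCohort()]).
#' @param samples character vector of sample ids (column order of the
#'   result).
#' @param dosageEffect multiplicative shift per copy-number state (>= 1).
#' @param noiseSdExpr log2-scale noise sd.
#' @param coupledGenes gene ids that respond to dosage; if `NULL`, a seeded
#'   random fraction `1 - decoupledFraction` of all genes is coupled.
#' @param decoupledFraction fraction of genes made dosage-blind when
#'   `coupledGenes` is `NULL`.
#' @param seed integer seed.
#' @param genome optional [GenomeBuild-class]; if supplied, genes falling
#'   outside its chromosome bounds raise an error.
#' @param baselineLog2Mean,baselineLog2Sd distribution of per-gene baseline
#'   abundance on log2 scale.
#' @return an [ExpressionMatrix-class].
#' @export
simulateExpression <- function(genes, truth, samples, dosageEffect = 1.8,
                               noiseSdExpr = 0.3, coupledGenes = NULL,
                               decoupledFraction = 0.3, seed = 1,
                               genome = NULL,
                               baselineLog2Mean = 7, baselineLog2Sd = 1) {
  stopifnot(dosageEffect >= 1, noiseSdExpr >= 0)
  gid <- mcols(genes)$gene_id
  if (is.null(gid) || anyDuplicated(gid)) stop("genes need unique gene_id")
  if (!is.null(genome)) {
    lens <- chromLengths(genome)
    chr <- as.character(seqnames(genes))
    if (!all(chr %in% names(lens)) || any(end(genes) > lens[chr]))
      stop("gene annotation extends outside the genome build")
  }
  nG <- length(genes); nS <- length(samples)
  withSeed(childSeed(seed, 501), {
    if (is.null(coupledGenes)) {
      nDec <- round(decoupledFraction * nG)
      coupledGenes <- gid[sample.int(nG, nG - nDec)]
    }
    coupled <- gid %in% coupledGenes
    base <- 2^rnorm(nG, baselineLog2Mean, baselineLog2Sd)
    ## net planted magnitude per (gene, sample) decides the dosage direction
    net <- matrix(0, nG, nS, dimnames = list(gid, samples))
    if (length(truth)) {
      hits <- findOverlaps(genes, truth)
      if (length(hits)) {
        j <- match(mcols(truth)$sample_id[subjectHits(hits)], samples)
        mag <- mcols(truth)$magnitude[subjectHits(hits)]
        for (k in seq_along(mag)) net[queryHits(hits)[k], j[k]] <-
            net[queryHits(hits)[k], j[k]] + mag[k]
      }
    }
    mult <- dosageEffect^(sign(net) * coupled)
    noise <- if (noiseSdExpr > 0)
      2^matrix(rnorm(nG * nS, sd = noiseSdExpr), nG, nS) else 1
    ExpressionMatrix(base * mult * noise)
  })
}

#' One-call synthetic study
#'
#' Convenience wrapper generating the full study scene at desk scale: an
#' 8-autosome + XY genome (80 Mb autosomes, ~6 kb probe spacing, ~125k
#' probes), a 23-vs-17 cohort with 8 shared and 6 early-specific planted
#' loci, a gene annotation in which a configurable set of genes placed
#' inside the early-specific loci is dosage-coupled while all background
#' genes are dosage-blind, and the matching expression matrix.
#'
#' @param seed master seed.
#' @param config a [cohortConfig()]; its seed is overridden by `seed`.
#' @param nChrom,chromLength autosome count and length for the toy genome.
#' @param spacing probe spacing in bp.
#' @param nBackgroundGenes decoupled background genes.
#' @param nCoupledGenes dosage-coupled genes planted inside distinct
#'   early-specific loci (capped at the number of such loci).
#' @param noiseSdExpr expression noise sd (log2 scale).
#' @param dosageEffect expression shift of coupled genes; defaults to the
#'   cohort config's value.
#' @return list with `genome`, `probes`, `cgh`, `truth`, `events`, `genes`,
#'   `expr`, `coupledGenes`.
#' @export
simulateStudy <- function(seed = 1, config = NULL, nChrom = 8,
                          chromLength = 8e7, spacing = 6000,
                          nBackgroundGenes = 513, nCoupledGenes = 7,
                          noiseSdExpr = 0.3, dosageEffect = NULL) {
  if (is.null(config)) config <- cohortConfig(seed = seed)
  else config$seed <- seed
  if (is.null(dosageEffect)) dosageEffect <- config$dosageEffect
  genome <- toyGenome(nChrom, chromLength, seed = seed, includeSex = TRUE)
  probes <- makeProbeMap(genome, spacing = spacing, seed = childSeed(seed, 5))
  sim <- simulateCohort(genome, probes, config)
  samples <- colData(sim$cgh)$sample_id

  ## plant coupled genes inside the early-specific loci; when there are
  ## more genes than loci, several genes share a locus at distinct offsets
  spec <- sim$events[sim$events$group_specific, , drop = FALSE]
  geneLen <- 20000
  planted <- GRanges(seqinfo = seqinfoOf(genome))
  if (nCoupledGenes > 0 && nrow(spec) > 0) {
    i <- seq_len(nCoupledGenes)
    locus <- ((i - 1L) %% nrow(spec)) + 1L
    lap <- (i - 1L) %/% nrow(spec)            # 0,1,2,... within a locus
    frac <- pmin(0.35 + 0.2 * lap, 0.85)
    gstart <- floor(spec$start[locus] +
                      frac * (spec$end[locus] - spec$start[locus] - geneLen))
    planted <- GRanges(spec$chrom[locus],
                       IRanges(gstart, gstart + geneLen - 1),
                       gene_id = sprintf("CPL%02d", i),
                       seqinfo = seqinfoOf(genome))
  }
  bg <- makeGeneMap(genome, nGenes = nBackgroundGenes,
                    geneLength = geneLen, seed = childSeed(seed, 7))
  genes <- sort(c(planted, bg))
  expr <- simulateExpression(genes, sim$truth, samples,
                             dosageEffect = dosageEffect,
                             noiseSdExpr = noiseSdExpr,
                             coupledGenes = mcols(planted)$gene_id,
                             seed = childSeed(seed, 8), genome = genome)
  list(genome = genome, probes = probes, cgh = sim$cgh, truth = sim$truth,
       events = sim$events, genes = genes, expr = expr,
       coupledGenes = mcols(planted)$gene_id)
}
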