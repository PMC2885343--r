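# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from disk.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

# A WindowCalls object built directly from a states matrix (windows x
# samples), bypassing simulation: one 1000-bp window per row, one probe per
# window. `chrom` assigns windows to chromosomes; `masked` flags windows.
callsFromStates <- function(states, chrom = rep("chr1", nrow(states)),
                            groups = NULL, masked = rep(FALSE, nrow(states)),
                            thresholds = cnThresholds()) {
  states <- as.matrix(states)
  nW <- nrow(states); nS <- ncol(states)
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("S%02d", seq_len(nS))
  states[masked, ] <- "MASKED"
  pos <- unlist(lapply(split(seq_len(nW), factor(chrom, unique(chrom))),
                       seq_along), use.names = FALSE)
  ord <- order(match(chrom, unique(chrom)))
  stopifnot(identical(ord, seq_len(nW)))  # windows given in genomic order
  within <- ave(seq_len(nW), chrom, FUN = seq_along)
  grid <- GRanges(chrom, IRanges((within - 1L) * 1000L + 1L, within * 1000L),
                  probe_first = seq_len(nW), probe_last = seq_len(nW),
                  n_probes = 1L, masked = masked,
                  mask_reason = ifelse(masked, "centromere", NA_character_))
  means <- matrix(0, nW, nS, dimnames = dimnames(states))
  means[states == "GAIN"] <- 0.3
  means[states == "LOSS"] <- -0.3
  if (is.null(groups)) {
    nm <- colnames(states)
    groups <- if (all(grepl("^[EL]", nm)))
      ifelse(grepl("^E", nm), "early", "late")
    else rep_len(c("early", "late"), nS)
  }
  cd <- DataFrame(sample_id = colnames(states), group = groups,
                  sex = NA_character_)
  rownames(cd) <- colnames(states)
  se <- SummarizedExperiment(assays = list(means = means, states = states),
                             rowRanges = grid, colData = cd)
  metadata(se)$thresholds <- thresholds
  metadata(se)$probesPerWindow <- 1L
  new("WindowCalls", se)
}

# States matrix with a planted carrier pattern: `carriersEarly` of the
# first nEarly samples and `carriersLate` of the rest aberrant (direction
# `state`) across windows `win`.
statesWithPattern <- function(nWindows, nEarly, nLate, win, state,
                              carriersEarly, carriersLate) {
  st <- matrix("NORMAL", nWindows, nEarly + nLate)
  colnames(st) <- c(sprintf("E%02d", seq_len(nEarly)),
                    sprintf("L%02d", seq_len(nLate)))
  st[win, seq_len(carriersEarly)] <- state
  if (carriersLate > 0)
    st[win, nEarly + seq_len(carriersLate)] <- state
  st
}

# Small genome + probe map used by several calling tests.
tinyScene <- function(chromLength = 2e6, spacing = 1000, pad = 20000,
                      seed = 11) {
  genome <- toyGenome(1, chromLength, seed = seed, telomerePad = pad)
  probes <- makeProbeMap(genome, spacing = spacing, jitterFrac = 0,
                         probeLength = 50, seed = seed)
  list(genome = genome, probes = probes)
}
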