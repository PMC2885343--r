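test_that("segments are maximal same-state runs per chromosome", {
  st <- cbind(S1 = c("GAIN", "GAIN", "NORMAL", "LOSS", "LOSS"))
  seg <- segmentsFromCalls(callsFromStates(st))
  expect_equal(nrow(seg), 2)
  expect_equal(seg$direction, c("gain", "loss"))
  expect_equal(seg$n_windows, c(2L, 2L))
  expect_equal(seg$window_first, c(1L, 4L))
  expect_equal(seg$window_last, c(2L, 5L))

  none <- segmentsFromCalls(callsFromStates(cbind(S1 = rep("NORMAL", 5))))
  expect_equal(nrow(none), 0)

  # runs never span a chromosome boundary
  st2 <- cbind(S1 = rep("GAIN", 4))
  seg2 <- segmentsFromCalls(callsFromStates(st2,
    chrom = c("chr1", "chr1", "chr2", "chr2")))
  expect_equal(nrow(seg2), 2)
})

test_that("masked gaps are bridged by default and split when bridging is off", {
  st <- cbind(S1 = c("GAIN", "NORMAL", "GAIN"))
  calls <- callsFromStates(st, masked = c(FALSE, TRUE, FALSE))
  on <- segmentsFromCalls(calls, bridgeMasked = TRUE)
  expect_equal(nrow(on), 1)
  expect_equal(on$window_first, 1L)
  expect_equal(on$window_last, 3L)
  off <- segmentsFromCalls(calls, bridgeMasked = FALSE)
  expect_equal(nrow(off), 2)

  # a masked gap between opposite states is never bridged
  st3 <- cbind(S1 = c("GAIN", "NORMAL", "LOSS"))
  calls3 <- callsFromStates(st3, masked = c(FALSE, TRUE, FALSE))
  expect_equal(nrow(segmentsFromCalls(calls3, bridgeMasked = TRUE)), 2)
})

test_that("aberration/breakpoint counting follows the whole/interior/one-end rule", {
  # whole chromosome: 1 aberration, 0 breakpoints
  whole <- segmentsFromCalls(callsFromStates(cbind(S1 = rep("GAIN", 6))))
  expect_equal(countAberrations(whole)[, c("n_aberrations", "n_breakpoints")],
               data.frame(n_aberrations = 1L, n_breakpoints = 0L))

  # interior: 1 aberration, 2 breakpoints
  interior <- segmentsFromCalls(callsFromStates(
    cbind(S1 = c("NORMAL", "LOSS", "LOSS", "NORMAL"))))
  expect_equal(countAberrations(interior)$n_breakpoints, 2L)

  # touching exactly one end: 1 aberration, 1 breakpoint
  oneEnd <- segmentsFromCalls(callsFromStates(
    cbind(S1 = c("GAIN", "GAIN", "NORMAL", "NORMAL"))))
  expect_equal(countAberrations(oneEnd)$n_breakpoints, 1L)

  # masked telomere windows do not stop a run from "touching" the end
  st <- cbind(S1 = c("MASKED", "GAIN", "GAIN", "MASKED"))
  calls <- callsFromStates(st, masked = c(TRUE, FALSE, FALSE, TRUE))
  seg <- segmentsFromCalls(calls)
  expect_true(seg$whole_chromosome)
  expect_equal(countAberrations(seg)$n_breakpoints, 0L)

  # breakpoint totals are order-invariant across chromosomes
  stMix <- cbind(S1 = c("GAIN", "NORMAL", "LOSS", "LOSS",
                        "NORMAL", "GAIN", "NORMAL"))
  callsMix <- callsFromStates(stMix,
    chrom = c(rep("chr1", 4), rep("chr2", 3)))
  cnt <- countAberrations(segmentsFromCalls(callsMix))
  expect_equal(cnt$n_aberrations, 3L)
  expect_equal(cnt$n_breakpoints, 1L + 1L + 2L)
})

test_that("genome fractions are computed over unmasked windows and sum to one", {
  st <- cbind(S1 = c("GAIN", "GAIN", "NORMAL", "NORMAL"),
              S2 = rep("NORMAL", 4))
  fr <- genomeFractions(callsFromStates(st), weightBy = "bp")
  expect_equal(fr$fraction_aberrant, c(0.5, 0))
  expect_equal(fr$fraction_aberrant + fr$pct_windows_normal, c(1, 1))

  # all NORMAL
  frN <- genomeFractions(callsFromStates(cbind(S1 = rep("NORMAL", 3))))
  expect_equal(frN$fraction_aberrant, 0)
  expect_equal(frN$pct_windows_normal, 1)

  # masked windows are excluded from the denominator
  stM <- cbind(S1 = c("GAIN", "NORMAL", "NORMAL"))
  frM <- genomeFractions(callsFromStates(stM,
    masked = c(FALSE, FALSE, TRUE)))
  expect_equal(frM$fraction_aberrant, 0.5)
})

test_that("replicate R2 is 1 for identical tracks, ~0 for independent noise, and errors without aberrations", {
  sc <- tinyScene(chromLength = 2e6, spacing = 1000, pad = 2e4)
  ev <- data.frame(chrom = "chr1", start = 500001, end = 900000,
                   direction = "gain", magnitude = 0.32,
                   pEarly = 1, pLate = 1, group_specific = FALSE)
  cfg <- cohortConfig(nEarly = 1, nLate = 1, noiseSd = 0.1, seed = 21)
  sim <- simulateCohort(sc$genome, sc$probes, cfg, events = ev)
  calls <- callCopyNumber(sim$cgh, sc$genome)
  lr <- lrMatrix(sim$cgh)
  st <- callStates(calls)
  grid <- windowRanges(calls)
  expect_equal(replicateR2(lr[, 1], lr[, 1], st[, 1], st[, 1], grid), 1)

  # independent pure-noise tracks with spurious calls: r2 near zero
  cfg0 <- cohortConfig(nEarly = 1, nLate = 1, noiseSd = 0.15, seed = 22)
  sim0 <- simulateCohort(sc$genome, sc$probes, cfg0,
                         events = ev[0, , drop = FALSE])
  calls0 <- callCopyNumber(sim0$cgh, sc$genome)
  lr0 <- lrMatrix(sim0$cgh)
  st0 <- callStates(calls0)
  if (any(st0[, 1] != "MASKED" & st0[, 1] != "NORMAL") ||
      any(st0[, 2] != "MASKED" & st0[, 2] != "NORMAL")) {
    r2 <- replicateR2(lr0[, 1], lr0[, 2], st0[, 1], st0[, 2],
                      windowRanges(calls0))
    expect_lt(r2, 0.3)
  }

  allN <- rep("NORMAL", length(grid))
  expect_error(replicateR2(lr[, 1], lr[, 2], allN, allN, grid),
               "no aberrant loci")
})

test_that("re-hybridized tumors at the default noise regime land in the replicate concordance band", {
  # one tumor's truth, two independent hybridizations
  genome <- toyGenome(4, 2e7, seed = 23, telomerePad = 1.2e5)
  probes <- makeProbeMap(genome, spacing = 6000, seed = 23)
  cfg <- cohortConfig(nEarly = 1, nLate = 1, nSharedLoci = 6,
                      nSpecificLoci = 0, sharedPenetrance = 1,
                      eventSizeBp = 3e6, seed = 23)
  sim <- simulateCohort(genome, probes, cfg)
  # same planted profile in both "replicates" (samples share all events)
  calls <- callCopyNumber(sim$cgh, genome)
  lr <- lrMatrix(sim$cgh)
  st <- callStates(calls)
  r2 <- replicateR2(lr[, 1], lr[, 2], st[, 1], st[, 2],
                    windowRanges(calls))
  expect_gt(r2, 0.7)
  expect_lt(r2, 0.9)
})

test_that("group metric comparison handles separation, identity and constants", {
  set.seed(99)
  m <- data.frame(
    sample_id = sprintf("s%02d", 1:40),
    group = rep(c("early", "late"), c(23, 17)),
    n_aberrations = c(31:53, 1:17),       # complete separation
    n_breakpoints = rep(c(10L, 10L), c(23, 17)),  # constant
    fraction_aberrant = c(rnorm(23, 0.3, 0.02), rnorm(17, 0.3, 0.02)))
  expect_warning(p <- compareGroupCounts(m), "constant")
  expect_lt(p[["n_aberrations"]], 0.001)
  expect_equal(p[["n_breakpoints"]], 1)
  expect_gt(p[["fraction_aberrant"]], 0.001)

  # equal group means under the t-test: p = 1 exactly (t = 0)
  m2 <- m
  m2$n_aberrations <- c(1:17, rep(9L, 6), 1:17)  # both groups mean 9
  expect_warning(p2 <- compareGroupCounts(m2, method = "t"), "constant")
  expect_equal(p2[["n_aberrations"]], 1)
  expect_error(compareGroupCounts(m[m$group == "early", ]), "both groups")
})
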