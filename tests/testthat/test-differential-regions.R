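test_that("fisherExact2x2 reproduces published carrier-table p-values", {
  # 14/23 vs 2/17 losses
  expect_equal(round(fisherExact2x2(14, 9, 2, 15), 3), 0.003)
  # 10/23 vs 1/17 losses
  expect_equal(round(fisherExact2x2(10, 13, 1, 16), 2), 0.01)
  # 8/23 vs 0/17 gains
  expect_equal(round(fisherExact2x2(8, 15, 0, 17), 2), 0.01)
})

test_that("fisherExact2x2 matches stats::fisher.test and obeys symmetries", {
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(1:23, 1); n2 <- sample(1:17, 1)
    a <- sample(0:n1, 1); c <- sample(0:n2, 1)
    b <- n1 - a; d <- n2 - c
    p <- fisherExact2x2(a, b, c, d)
    expect_equal(p, fisher.test(matrix(c(a, b, c, d), 2,
                                       byrow = TRUE))$p.value,
                 tolerance = 1e-9)
    expect_identical(p, fisherExact2x2(c, d, a, b))  # group exchange
    expect_identical(p, fisherExact2x2(b, a, d, c))  # outcome exchange
  }
  expect_equal(fisherExact2x2(5, 5, 5, 5), 1)
  expect_equal(fisherExact2x2(0, 0, 3, 4), 1)   # empty margin
  expect_equal(fisherExact2x2(3, 0, 4, 0), 1)   # empty outcome margin
  expect_error(fisherExact2x2(1.5, 1, 1, 1), "integer")
  expect_error(fisherExact2x2(-1, 1, 1, 1), "integer|negative")
})

test_that("fisherExact2x2 agrees with the enumeration oracle on small margins", {
  P <- pascalTriangle(24)
  for (r1 in c(0, 1, 5, 9, 12)) for (r2 in c(1, 4, 8, 12)) {
    for (a in 0:r1) for (c in 0:r2) {
      expect_equal(fisherExact2x2(a, r1 - a, c, r2 - c),
                   fisherOracle(a, r1 - a, c, r2 - c, P),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-window tests count carriers of each direction separately", {
  st <- statesWithPattern(8, 23, 17, win = 3:7, state = "LOSS",
                          carriersEarly = 14, carriersLate = 2)
  calls <- callsFromStates(st)
  tests <- testAllWindows(calls)
  lossW <- tests[tests$direction == "loss" & tests$window %in% 3:7, ]
  expect_equal(nrow(lossW), 5)
  expect_equal(unique(lossW$a_early), 14)
  expect_equal(unique(lossW$a_late), 2)
  expect_equal(unique(round(lossW$p, 3)), 0.003)
  gainW <- tests[tests$direction == "gain", ]
  expect_true(all(gainW$p == 1))
  # no aberrations anywhere -> all p = 1
  none <- testAllWindows(callsFromStates(
    matrix("NORMAL", 4, 6, dimnames = list(NULL, paste0("s", 1:6)))))
  expect_true(all(none$p == 1))
  # masked windows are skipped
  stM <- statesWithPattern(4, 3, 3, 1:2, "GAIN", 3, 0)
  callsM <- callsFromStates(stM, masked = c(TRUE, FALSE, FALSE, FALSE))
  expect_false(1 %in% testAllWindows(callsM)$window)
})

test_that("significant runs merge with arithmetic-mean p and centromere-spanning regions are dropped", {
  st <- statesWithPattern(12, 23, 17, win = 4:6, state = "LOSS",
                          carriersEarly = 14, carriersLate = 2)
  calls <- callsFromStates(st)
  tests <- testAllWindows(calls)
  tests$p[tests$direction == "loss" & tests$window %in% 4:6] <-
    c(0.01, 0.02, 0.03)
  reg <- mergeRegions(tests, calls)
  expect_length(reg, 1)
  expect_equal(mcols(reg)$avg_p, 0.02)
  expect_equal(mcols(reg)$n_windows, 3L)
  expect_equal(mcols(reg)$enriched_group, "early")

  # an isolated significant window is a single-window region
  st1 <- statesWithPattern(6, 23, 17, win = 2, state = "GAIN",
                           carriersEarly = 14, carriersLate = 2)
  reg1 <- mergeRegions(testAllWindows(callsFromStates(st1)),
                       callsFromStates(st1))
  expect_length(reg1, 1)
  expect_equal(mcols(reg1)$n_windows, 1L)

  # a run straddling a masked centromere window is bridged, then dropped
  stC <- statesWithPattern(7, 23, 17, win = c(2, 3, 5, 6), state = "LOSS",
                           carriersEarly = 14, carriersLate = 2)
  callsC <- callsFromStates(stC,
    masked = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  regC <- mergeRegions(testAllWindows(callsC), callsC)
  expect_length(regC, 0)
  regKeep <- mergeRegions(testAllWindows(callsC), callsC,
                          dropCentromereSpanning = FALSE)
  expect_length(regKeep, 1)
})

test_that("merged regions are disjoint and cover every significant window once", {
  set.seed(13)
  nW <- 60; nE <- 23; nL <- 17
  st <- matrix("NORMAL", nW, nE + nL,
               dimnames = list(NULL, c(sprintf("E%02d", 1:nE),
                                       sprintf("L%02d", 1:nL))))
  # random planted blocks
  for (b in list(5:9, 20:24, 40:44)) {
    st[b, 1:14] <- "LOSS"
    st[b, nE + 1:2] <- "LOSS"
  }
  st[30:31, 1:12] <- "GAIN"
  calls <- callsFromStates(st)
  tests <- testAllWindows(calls)
  reg <- mergeRegions(tests, calls)
  expect_false(is.unsorted(start(reg)))
  expect_true(all(width(IRanges::reduce(ranges(reg))) == width(ranges(reg))))
  sig <- tests[tests$p < 0.05, ]
  covered <- unlist(mapply(seq, mcols(reg)$window_first,
                           mcols(reg)$window_last, SIMPLIFY = FALSE))
  expect_setequal(sig$window, covered)
  expect_equal(sum(mcols(reg)$n_windows), nrow(sig))
})

test_that("label permutation yields a null rate of significant windows", {
  set.seed(17)
  nW <- 400; nE <- 23; nL <- 17
  # every sample carries aberrations at random windows (no group structure)
  st <- matrix(ifelse(runif(nW * (nE + nL)) < 0.3, "LOSS", "NORMAL"),
               nW, nE + nL, dimnames = list(NULL, sprintf("s%02d", 1:40)))
  calls <- callsFromStates(st)
  tests <- testAllWindows(calls)
  sigRate <- mean(tests$p[tests$direction == "loss"] < 0.05)
  # Fisher is conservative at these sizes: null rate at or below ~alpha
  expect_lt(sigRate, 0.07)
})

test_that("SRO maximizes enriched-group carrier overlap (brute-force checked)", {
  # all carriers share windows 3-5 of a 10-window region
  nE <- 23; nL <- 17
  st <- matrix("NORMAL", 10, nE + nL,
               dimnames = list(NULL, c(sprintf("E%02d", 1:nE),
                                       sprintf("L%02d", 1:nL))))
  st[3:5, 1:14] <- "LOSS"
  st[3:5, nE + 1:2] <- "LOSS"
  calls <- callsFromStates(st)
  tests <- testAllWindows(calls)
  reg <- mergeRegions(tests, calls)
  sro <- findSro(calls, reg[1])
  expect_equal(sro$window_first, 3L)
  expect_equal(sro$window_last, 5L)
  expect_equal(sro$carriers_early, 14L)
  expect_equal(sro$carriers_late, 2L)

  # nested events: long in 8 early samples, short core in 14 -> core wins
  st2 <- matrix("NORMAL", 10, nE + nL,
                dimnames = list(NULL, colnames(st)))
  st2[2:9, 1:8] <- "LOSS"       # long event, 8 carriers
  st2[5:6, 1:14] <- "LOSS"      # short core, 14 carriers
  st2[2:9, nE + 1:2] <- "LOSS"
  calls2 <- callsFromStates(st2)
  reg2 <- mergeRegions(testAllWindows(calls2), calls2)
  sro2 <- findSro(calls2, reg2[1])
  expect_equal(c(sro2$window_first, sro2$window_last), c(5L, 6L))

  # agreement with the brute-force oracle on random carrier matrices
  set.seed(31)
  grid <- windowRanges(calls2)
  for (rep in 1:5) {
    A <- matrix(runif(10 * 40) < 0.45, 10, 40)
    stR <- matrix(ifelse(A, "LOSS", "NORMAL"), 10, 40,
                  dimnames = list(NULL, colnames(st)))
    callsR <- callsFromStates(stR)
    regR <- GRanges("chr1", IRanges(1, 10000), direction = "loss",
                    window_first = 1L, window_last = 10L,
                    enriched_group = "early")
    sroR <- findSro(callsR, regR, minRun = 1)
    oracle <- sroOracle(A, enrIdx = 1:23,
                        starts = start(windowRanges(callsR)),
                        ends = end(windowRanges(callsR)))
    expect_equal(sroR$window_first, oracle$i)
    expect_equal(sroR$window_last, oracle$j)
    expect_equal(sroR$carriers_early, oracle$carriers)
  }

  # single-window region
  st3 <- statesWithPattern(4, 23, 17, 2, "GAIN", 14, 2)
  calls3 <- callsFromStates(st3)
  reg3 <- mergeRegions(testAllWindows(calls3), calls3)
  sro3 <- findSro(calls3, reg3[1])
  expect_equal(c(sro3$window_first, sro3$window_last), c(2L, 2L))
})

test_that("significant genome fraction is region bp over unmasked autosomal bp", {
  gb <- GenomeBuild(c("c1", "c2"), c(6e8, 6e8), c(2.9e8, 2.9e8),
                    c(3.3e8, 3.3e8), telomerePad = 1e7)
  # unmasked autosomal bp: 2 * (6e8 - 4e7 (cen) - 2e7 (tel)) = 1.08e9
  masks <- buildMasks(gb)
  unmasked <- sum(chromLengths(gb)) - sum(width(reduce(masks)))
  reg <- GRanges("c1", IRanges(1e7 + 1, 1e7 + 0.032 * unmasked),
                 direction = "loss", avg_p = 0.01)
  expect_equal(significantGenomeFraction(reg, gb), 3.2, tolerance = 1e-6)
  expect_equal(significantGenomeFraction(reg[0], gb), 0)
})
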