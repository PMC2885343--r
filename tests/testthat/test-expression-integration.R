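# A small deterministic scene shared by several integration tests:
# 6 windows on chr1, three samples per group.
integrationScene <- function() {
  st <- matrix("NORMAL", 6, 6,
               dimnames = list(NULL, c("E01", "E02", "E03",
                                       "L01", "L02", "L03")))
  st[2:3, c("E01", "E02", "E03")] <- "GAIN"
  st[5, c("E01", "E03", "L01")] <- "LOSS"
  calls <- callsFromStates(st)
  # windows are 1 kb each: genes at known positions
  genes <- GRanges("chr1",
                   IRanges(c(2100, 2900, 3301, 4200), width = 200),
                   gene_id = c("gInGain", "gBoundary", "gNormal", "gInLoss"))
  list(calls = calls, genes = genes)
}

test_that("gene states follow the window rule (agree / midpoint / masked)", {
  sc <- integrationScene()
  st <- geneStates(sc$genes, sc$calls)
  expect_equal(st["gInGain", "E01"], "GAIN")
  expect_equal(st["gInGain", "L01"], "NORMAL")
  expect_equal(st["gInLoss", "E03"], "LOSS")
  expect_equal(st["gNormal", "E01"], "NORMAL")
  # boundary gene spans windows 3 (GAIN for E01) and 4 (NORMAL); its
  # midpoint (3000) lies in window 3 -> GAIN for E01
  expect_equal(st["gBoundary", "E01"], "GAIN")

  # a gene spanning a GAIN|NORMAL boundary with midpoint in NORMAL
  genes2 <- GRanges("chr1", IRanges(2900, 3400), gene_id = "gMidNormal")
  st2 <- geneStates(genes2, sc$calls)
  expect_equal(st2["gMidNormal", "E01"], "NORMAL")

  # fully masked territory
  stM <- matrix("NORMAL", 3, 2, dimnames = list(NULL, c("E01", "L01")))
  callsM <- callsFromStates(stM, masked = c(FALSE, TRUE, FALSE))
  gM <- GRanges("chr1", IRanges(1200, 1800), gene_id = "gMasked")
  expect_equal(unname(geneStates(gM, callsM)[1, ]), c("MASKED", "MASKED"))

  gOut <- GRanges("chr2", IRanges(1, 100), gene_id = "gOff")
  expect_error(suppressWarnings(geneStates(gOut, sc$calls)),
               "overlapping no window")
})

test_that("median-expression ratios are computed per direction on the linear scale", {
  states <- rbind(gA = c("GAIN", "GAIN", "NORMAL", "NORMAL", "LOSS", "LOSS"))
  colnames(states) <- paste0("s", 1:6)
  lin <- rbind(gA = c(20, 24, 10, 12, 5, 6))
  colnames(lin) <- paste0("s", 1:6)
  r <- expressionRatios(states, ExpressionMatrix(lin))
  expect_equal(r$ratio_gain, 22 / 11)
  expect_equal(r$ratio_loss, 5.5 / 11)
  expect_equal(c(r$n_gain, r$n_loss, r$n_normal), c(2L, 2L, 2L))

  # all-equal expression: ratio 1 whatever the split
  linEq <- rbind(gA = rep(7, 6)); colnames(linEq) <- paste0("s", 1:6)
  expect_equal(expressionRatios(states, ExpressionMatrix(linEq))$ratio_gain, 1)

  # no carriers of a direction -> NA; no normal samples -> NA + warning
  statesG <- rbind(gA = c(rep("GAIN", 2), rep("NORMAL", 4)))
  colnames(statesG) <- paste0("s", 1:6)
  rG <- expressionRatios(statesG, ExpressionMatrix(lin))
  expect_true(is.na(rG$ratio_loss))
  statesAllG <- rbind(gA = rep("GAIN", 6))
  colnames(statesAllG) <- paste0("s", 1:6)
  expect_warning(rAll <- expressionRatios(statesAllG, ExpressionMatrix(lin)),
                 "no normal")
  expect_true(is.na(rAll$ratio_gain))
})

test_that("ratio statistic is scale-equivariant", {
  set.seed(5)
  states <- rbind(g = sample(c("GAIN", "NORMAL", "LOSS"), 12, TRUE))
  colnames(states) <- paste0("s", 1:12)
  lin <- rbind(g = 2^rnorm(12, 6)); colnames(lin) <- paste0("s", 1:12)
  r1 <- expressionRatios(states, ExpressionMatrix(lin))
  r2 <- expressionRatios(states, ExpressionMatrix(lin * 37.5))
  expect_equal(r1$ratio_gain, r2$ratio_gain)
  expect_equal(r1$ratio_loss, r2$ratio_loss)
})

test_that("concordance thresholds are inclusive for gain, strict for loss", {
  r <- data.frame(gene_id = paste0("g", 1:4),
                  ratio_gain = c(1.5, 1.49, NA, 2),
                  ratio_loss = c(NA, NA, 0.75, 0.5))
  f <- concordanceFlags(r)
  expect_equal(f$concordant_gain, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(f$concordant_loss, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("region restriction requires a direction match", {
  genes <- GRanges("chr1", IRanges(c(100, 300, 900), width = 50),
                   gene_id = c("gG", "gL", "gOut"))
  regions <- GRanges("chr1", IRanges(50, 400), direction = "gain",
                     avg_p = 0.01, enriched_group = "early")
  rec <- data.frame(gene_id = c("gG", "gL", "gOut"),
                    concordant_gain = c(TRUE, FALSE, TRUE),
                    concordant_loss = c(FALSE, TRUE, FALSE))
  out <- restrictToRegions(rec, genes, regions)
  expect_equal(out$in_significant_region, c(TRUE, FALSE, FALSE))
  # empty region set -> nothing flagged
  out0 <- restrictToRegions(rec, genes, regions[0])
  expect_false(any(out0$in_significant_region))
})

test_that("group expression t-test detects shifts and handles degenerate genes", {
  set.seed(11)
  groups <- rep(c("early", "late"), c(23, 17))
  names(groups) <- sprintf("s%02d", 1:40)
  base <- 2^matrix(rnorm(40 * 3, 7, 0.3), 3, 40,
                   dimnames = list(c("gShift", "gNull", "gConst"),
                                   names(groups)))
  # shift early group by 3 pooled log2 SDs
  base["gShift", groups == "early"] <-
    base["gShift", groups == "early"] * 2^(3 * 0.3)
  base["gConst", ] <- 100
  expect_warning(p <- groupExpressionTest(ExpressionMatrix(base), groups),
                 "zero variance")
  expect_lt(p[["gShift"]], 0.001)
  expect_gt(p[["gNull"]], 0.01)
  expect_equal(p[["gConst"]], 1)

  # permuted labels leave the test null: uniform-ish p across genes
  set.seed(12)
  nullMat <- 2^matrix(rnorm(40 * 200, 7, 0.3), 200, 40,
                      dimnames = list(paste0("g", 1:200), names(groups)))
  pNull <- groupExpressionTest(ExpressionMatrix(nullMat), groups)
  expect_gt(mean(pNull < 0.05), 0.0)
  expect_lt(mean(pNull < 0.05), 0.12)
  expect_gt(median(pNull), 0.3)
  expect_error(groupExpressionTest(ExpressionMatrix(nullMat),
                                   rep(c("early", "late"), c(1, 39))),
               "two samples")
})

test_that("the shortlist requires concordance, region membership and group significance", {
  sc <- integrationScene()
  # expression: gInGain dosage-coupled (x3 in its GAIN carriers, all
  # early); everything else flat
  lin <- matrix(100, 4, 6,
                dimnames = list(c("gInGain", "gBoundary", "gNormal",
                                  "gInLoss"),
                                colnames(callStates(sc$calls))))
  lin["gInGain", c("E01", "E02", "E03")] <- 300
  ## add tiny deterministic jitter so variances are nonzero
  lin <- lin * matrix(1 + 0.001 * sin(1:24), 4, 6)
  regions <- GRanges("chr1", IRanges(1500, 3500), direction = "gain",
                     avg_p = 0.01, enriched_group = "early")
  rec <- integrateExpression(sc$calls, ExpressionMatrix(lin), sc$genes,
                             regions)
  expect_true(rec$shortlisted[rec$gene_id == "gInGain"])
  expect_false(any(rec$shortlisted[rec$gene_id != "gInGain"]))

  # empty region list -> empty shortlist
  rec0 <- integrateExpression(sc$calls, ExpressionMatrix(lin), sc$genes,
                              regions[0])
  expect_false(any(rec0$shortlisted))
})

test_that("shortlist is monotone in alpha and in the concordance thresholds", {
  sc <- integrationScene()
  set.seed(21)
  lin <- matrix(2^rnorm(24, 7, 0.2), 4, 6,
                dimnames = list(c("gInGain", "gBoundary", "gNormal",
                                  "gInLoss"),
                                colnames(callStates(sc$calls))))
  lin["gInGain", c("E01", "E02")] <- lin["gInGain", c("E01", "E02")] * 3
  regions <- GRanges("chr1", IRanges(1500, 3500), direction = "gain",
                     avg_p = 0.01, enriched_group = "early")
  loose <- integrateExpression(sc$calls, ExpressionMatrix(lin), sc$genes,
                               regions, gainThreshold = 1.2, alpha = 0.2)
  strict <- integrateExpression(sc$calls, ExpressionMatrix(lin), sc$genes,
                                regions, gainThreshold = 2.5, alpha = 0.01)
  expect_true(all(strict$gene_id[strict$shortlisted] %in%
                    loose$gene_id[loose$shortlisted]))
})
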