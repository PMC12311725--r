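# Independent Welch oracle: the textbook formula, separate from the
# implementation's stats::t.test route.
welchSignificance <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  -10 * log10(p)
}

makeSe <- function(ctlLog2, trtLog2) {
  # rows are proteins; inputs are per-sample log2 values for one protein
  vals <- 2^rbind(p1 = c(ctlLog2, trtLog2))
  quantMatrix(vals, c(rep("control", length(ctlLog2)),
                      rep("treatment", length(trtLog2))))
}

test_that("identical groups give zero fold change and zero significance", {
  se <- makeSe(c(10, 10, 10), c(10, 10, 10))
  st <- proteinStats(se, pseudocount = 0)
  expect_equal(st$log2fc, 0)
  expect_equal(st$significance, 0)
})

test_that("Welch significance matches the independent formula", {
  ctl <- c(10.0, 10.1, 9.9); trt <- c(12.0, 12.1, 11.9)
  se <- makeSe(ctl, trt)
  st <- proteinStats(se, pseudocount = 0)
  expect_equal(st$log2fc, 2, tolerance = 1e-9)
  expect_equal(st$significance, welchSignificance(ctl, trt),
               tolerance = 1e-9)
  expect_gt(st$significance, 15)   # clears the enrichment cutoff
  expect_equal(st$significance, 47.8, tolerance = 0.01)
})

test_that("significance is invariant to global intensity rescaling", {
  cfg <- simConfig(seed = 8, quant = list(nProteins = 50, nPlantedUp = 5,
                                          plantedLog2fc = 1.5,
                                          noiseSd = 0.2,
                                          groupSizes = c(3L, 3L)))
  sim <- simulateQuant(cfg)
  st1 <- proteinStats(sim$se, pseudocount = 0)
  vals <- SummarizedExperiment::assay(sim$se) * 7.3
  se2 <- quantMatrix(vals, SummarizedExperiment::colData(sim$se)$group)
  st2 <- proteinStats(se2, pseudocount = 0)
  expect_equal(st2$significance, st1$significance, tolerance = 1e-8)
  expect_equal(st2$log2fc, st1$log2fc, tolerance = 1e-8)
})

test_that("proteins with too few finite values are reported untestable", {
  vals <- 2^rbind(p1 = c(10, 10.2, 9.8, 12, 12.1, 11.9),
                  p2 = c(10, NA, NA, 12, 12.1, 11.9))
  se <- quantMatrix(vals, rep(c("control", "treatment"), each = 3))
  expect_message(st <- proteinStats(se), "untestable")
  expect_equal(st$protein, "p1")
  expect_equal(attr(st, "untestable"), "p2")
})

test_that("volcano filter applies the 2-fold / significance-15 rule", {
  st <- data.frame(
    protein = c("up", "down", "lowfc", "lowsig"),
    log2fc = c(2, -2, 0.5, 3),
    pvalue = c(1e-5, 1e-5, 1e-5, 0.5),
    stringsAsFactors = FALSE)
  st$significance <- -10 * log10(st$pvalue)
  f <- volcanoFilter(st, minFc = 2, minSig = 15)
  expect_equal(f$enriched, "up")
  expect_equal(f$depleted, "down")
  expect_length(intersect(f$enriched, f$depleted), 0)
  expect_equal(f$stats$direction, c("up", "down", "ns", "ns"))

  # empty input
  e <- volcanoFilter(st[0, ], 2, 15)
  expect_length(e$enriched, 0)

  # monotonicity: tightening thresholds never adds members
  f2 <- volcanoFilter(st, minFc = 4, minSig = 15)
  expect_true(all(f2$enriched %in% f$enriched))
  f3 <- volcanoFilter(st, minFc = 2, minSig = 60)
  expect_true(all(f3$enriched %in% f$enriched))
})

test_that("contaminant exclusion is a reported set difference", {
  r <- excludeContaminants(c("A", "B", "C"), "B")
  expect_equal(r$kept, c("A", "C"))
  expect_equal(r$removed, "B")
  r2 <- excludeContaminants(c("A", "B"), character())
  expect_equal(r2$kept, c("A", "B"))
  expect_length(r2$removed, 0)
})

test_that("null-simulation pass rate matches the Welch test's true size", {
  # At n = 3 per group the Welch test is conservative: its true size at
  # alpha = 10^-1.5 is below the nominal 0.0316 because the
  # Welch-Satterthwaite df falls below the pooled df of 4. The reference
  # size comes from an independent direct simulation of the test.
  refOracle <- local({
    set.seed(424242)
    N <- 2e5
    a <- matrix(rnorm(3 * N), ncol = 3); b <- matrix(rnorm(3 * N), ncol = 3)
    va <- apply(a, 1, var) / 3; vb <- apply(b, 1, var) / 3
    t <- (rowMeans(b) - rowMeans(a)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
    mean(2 * pt(-abs(t), df) < 10^-1.5)
  })
  rates <- vapply(1:5, function(s) {
    cfg <- simConfig(seed = 100 + s, quant = list(
      nProteins = 1000, nPlantedUp = 0, plantedLog2fc = 0,
      noiseSd = 0.1, groupSizes = c(3L, 3L)))
    st <- proteinStats(simulateQuant(cfg)$se, pseudocount = 0)
    mean(st$significance > 15)
  }, numeric(1))
  # conservative relative to nominal, and centred on the oracle size
  expect_lt(mean(rates), 10^-1.5 + 0.005)
  expect_lt(abs(mean(rates) - refOracle), 0.008)  # ~3 MC sigma

  cfg <- simConfig(seed = 101, quant = list(
    nProteins = 1000, nPlantedUp = 0, plantedLog2fc = 0,
    noiseSd = 0.1, groupSizes = c(3L, 3L)))
  st <- proteinStats(simulateQuant(cfg)$se, pseudocount = 0)
  f <- volcanoFilter(st, minFc = 2, minSig = 15)
  expect_lte(length(f$enriched) + length(f$depleted),
             sum(st$significance > 15))
})

test_that("planted 4-fold enrichment at low noise is fully recovered", {
  cfg <- simConfig(seed = 102, quant = list(
    nProteins = 300, nPlantedUp = 30, plantedLog2fc = 2,
    noiseSd = 0.1, groupSizes = c(3L, 3L)))
  sim <- simulateQuant(cfg)
  st <- proteinStats(sim$se, pseudocount = 0)
  f <- volcanoFilter(st, minFc = 2, minSig = 15)
  planted <- sim$truth$protein[sim$truth$planted]
  expect_true(all(planted %in% f$enriched))
  # false positives stay near the null rate
  expect_lte(length(setdiff(f$enriched, planted)), 0.1 * 270)
})
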