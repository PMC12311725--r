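test_that("readPeakList parses delimited text and sorts by m/z", {
  f <- tempfile()
  writeLines(c("3369.1 1000", "2000.0 50"), f)
  pl <- readPeakList(f)
  expect_equal(peakCount(pl), 2)
  expect_equal(peaks(pl)$mz, c(2000.0, 3369.1))

  # comma-delimited with header and comments
  f2 <- tempfile()
  writeLines(c("mz,intensity", "# comment", "", "100.5,7", "99.1,3"), f2)
  pl2 <- readPeakList(f2)
  expect_equal(peaks(pl2)$mz, c(99.1, 100.5))

  # non-numeric body line reports its line number
  f3 <- tempfile()
  writeLines(c("100 5", "oops 3"), f3)
  expect_error(readPeakList(f3), "line 2")

  f4 <- tempfile()
  writeLines(character(), f4)
  expect_warning(e <- readPeakList(f4), "empty")
  expect_equal(peakCount(e), 0)
})

test_that("synthetic peak lists carry the generator's planted peak count", {
  cfg <- simConfig(seed = 21, nNoisePeaks = 10)
  sim <- simulatePeakList(tc1Sequence(), cfg)
  expect_equal(peakCount(sim$peaks), nrow(sim$truth))
  expect_equal(peakCount(sim$peaks), 12)  # base + 1-ox satellite + 10 noise
  f <- tempfile()
  writePeakList(sim$peaks, f)
  expect_equal(peaks(readPeakList(f))$mz, peaks(sim$peaks)$mz,
               tolerance = 1e-8)
})

test_that("oxoform enumeration spaces proteoforms by one oxygen", {
  forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4)
  expect_equal(nrow(forms), 4)  # 3 Met -> 0..3 oxidations
  expect_equal(diff(forms$mass), rep(15.99491, 3), tolerance = 1e-6)
  expect_true(all(diff(forms$mass) > 0))
  expect_equal(forms$mass[1], TC1_MASS_4SS, tolerance = 1e-4)

  expect_equal(nrow(enumerateOxoforms("GAGA", "x")), 1)  # Met-free
  expect_equal(nrow(enumerateOxoforms(TC1, "tC1", maxOx = 0)), 1)

  # alkylated ladder starts 464.23 Da above the native form
  alk <- enumerateOxoforms(TC1, "tC1", alkylated = TRUE)
  expect_equal(alk$mass[1] - forms$mass[1], 464.23, tolerance = 1e-2)
})

test_that("matchPeaks finds the nearest in-tolerance peak", {
  forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4, maxOx = 0)
  pl <- peakList(c(3369.14, 5000), c(100, 10))
  m <- matchPeaks(pl, forms, tolDa = 0.5, tolPpm = 200)
  expect_equal(nrow(m), 1)
  expect_equal(m$observedMz, 3369.14)
  expect_lt(abs(m$errorDa - (3369.14 - TC1_MH_4SS)), 1e-3)

  # nothing in tolerance -> empty
  none <- matchPeaks(peakList(1500, 5), forms, tolDa = 0.5, tolPpm = 200)
  expect_equal(nrow(none), 0)

  # equidistant tie goes to the higher-intensity peak
  target <- forms$mz[1]
  tie <- peakList(c(target - 0.2, target + 0.2), c(5, 50))
  mt <- matchPeaks(tie, forms, tolDa = 0.5, tolPpm = 200)
  expect_equal(mt$intensity, 50)
})

test_that("planted proteoforms are matched with no false assignments", {
  cfg <- simConfig(seed = 33, massNoisePpm = 30, nNoisePeaks = 20)
  sim <- simulatePeakList(tc1Sequence(), cfg)
  forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4, maxOx = 1)
  m <- matchPeaks(sim$peaks, forms)
  expect_equal(sort(m$nMetOx), c(0L, 1L))
  # matched peaks are exactly the planted (non-noise) ones
  planted <- sim$truth$mz[sim$truth$kind != "noise"]
  expect_setequal(round(m$observedMz, 6), round(planted, 6))
})

test_that("screenWindow keeps in-window peaks above the intensity floor", {
  pl <- peakList(c(1500, 3369, 6000) + 1.007276, c(10, 100, 50))
  kept <- screenWindow(pl, 2000, 5000)
  expect_equal(peaks(kept)$mz, 3369 + 1.007276)
  # minRelIntensity = 0 keeps everything in-window
  pl2 <- peakList(c(2500, 3000) + 1.007276, c(1, 100))
  expect_equal(peakCount(screenWindow(pl2, 2000, 5000, 0)), 2)
  expect_equal(peakCount(screenWindow(pl2, 2000, 5000, 0.05)), 1)
})

test_that("screening and matching commute on in-window proteoforms", {
  cfg <- simConfig(seed = 44, nNoisePeaks = 15)
  sim <- simulatePeakList(tc1Sequence(), cfg)
  forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4)
  a <- matchPeaks(screenWindow(sim$peaks, 2000, 5000), forms)
  b <- matchPeaks(sim$peaks, forms)
  b <- b[b$observedMz - 1.007276 >= 2000 & b$observedMz - 1.007276 <= 5000, ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("oxidation fractions are intensity shares summing to one", {
  forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4, maxOx = 1)
  pl <- peakList(forms$mz, c(73, 27))
  f <- oxidationFraction(matchPeaks(pl, forms))
  expect_equal(f$fraction[f$nMetOx == 1], 0.27)
  expect_equal(sum(f$fraction), 1)

  # a single matched form gets fraction 1
  one <- oxidationFraction(matchPeaks(peakList(forms$mz[1], 10),
                                      forms[1, ]))
  expect_equal(one$fraction, 1)
  expect_error(oxidationFraction(matchPeaks(peakList(), forms)),
               "no matches")
})

test_that("Monte-Carlo: planted 27% oxidation is recovered within 0.03", {
  errs <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = 1000 + s, oxFraction = 0.27,
                     massNoisePpm = 50, nNoisePeaks = 10)
    sim <- simulatePeakList(tc1Sequence(), cfg)
    forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4, maxOx = 1)
    f <- oxidationFraction(matchPeaks(sim$peaks, forms))
    f$fraction[f$nMetOx == 1] - 0.27
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.03)
})

test_that("noise-only spectra produce no tC1 matches at default tolerance", {
  hits <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = 2000 + s, nNoisePeaks = 30)
    sim <- simulatePeakList(character(), cfg)
    forms <- enumerateOxoforms(TC1, "tC1", nDisulfides = 4)
    nrow(matchPeaks(sim$peaks, forms))
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.1)
})
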