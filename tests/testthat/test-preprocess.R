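test_that("mass-channel unification interpolates linearly", {
  target <- c(1000, 1000.5, 1001, 1001.5, 1002)
  pd <- data.frame(pixel_id = "px1", core_id = "C1", patient_id = "P1",
                   roi_label = "UNKNOWN", x = 0, y = 0)
  ## hand case: (1000,1001,1002) -> (10,20,30) sampled at 1000.5 gives 15
  ds <- unifyMassChannels(list(list(mz = c(1000, 1001, 1002),
                                    intensity = c(10, 20, 30))),
                          target, pd)
  expect_equal(as.numeric(intensities(ds)), c(10, 15, 20, 25, 30))
  ## identity when already on the target axis
  ds2 <- unifyMassChannels(list(list(mz = target,
                                     intensity = c(1, 2, 3, 4, 5))),
                           target, pd)
  expect_equal(as.numeric(intensities(ds2)), c(1, 2, 3, 4, 5))
  ## outside the source axis -> 0
  ds3 <- unifyMassChannels(list(list(mz = c(1000.5, 1001),
                                     intensity = c(2, 2))), target, pd)
  expect_equal(as.numeric(intensities(ds3)), c(0, 2, 2, 0, 0))
  expect_error(unifyMassChannels(list(list(mz = c(2, 1), intensity = c(1, 1))),
                                 target, pd), "increasing")
})

test_that("baseline subtraction removes a constant offset and keeps peaks", {
  mz <- seq(1000, 1200, by = 0.5)
  peak <- 100 * exp(-(mz - 1100)^2 / (2 * 2^2))
  cc <- 20
  m <- cbind(peak + cc, peak + cc)
  ds <- tinySpectra(m, mz)
  out <- intensities(subtractBaseline(ds, windowDa = 50))
  flank <- abs(mz - 1100) > 10
  expect_lt(max(abs(out[flank, 1] - peak[flank])), 0.05 * cc)
  ## peak apex survives (within the same tolerance of the true height)
  expect_equal(max(out[, 1]), 100, tolerance = 0.05 * cc / 100)
  ## all-zero spectrum stays all-zero
  z <- tinySpectra(matrix(0, length(mz), 2), mz)
  expect_true(all(intensities(subtractBaseline(z, 50)) == 0))
  expect_error(subtractBaseline(ds, windowDa = 1000), "wider")
})

test_that("TIC outlier flagging uses medcouple-adjusted fences", {
  mz <- 1:101 + 999
  ## 101 pixels with TICs 1..100 and one at 1e6: single-channel spectra
  tics <- c(1:100, 1e6)
  m <- matrix(0, 101, 101)
  diag(m) <- tics
  ds <- tinySpectra(m, mz)
  out <- flagTICOutliers(ds)
  ## independent fence computation
  f <- stats::quantile(tics, c(0.25, 0.75))
  mc <- medcouple(tics)
  up <- f[2] + 1.5 * exp(3 * mc) * (f[2] - f[1])
  expect_true(isTICOutlier(out)[101])
  expect_equal(unname(which(isTICOutlier(out))),
               which(tics < f[1] - 1.5 * exp(-4 * mc) * (f[2] - f[1]) |
                       tics > up))
  ## all-equal TICs: nothing flagged
  eq <- tinySpectra(matrix(1, 20, 12), 1:20 + 999)
  expect_equal(sum(isTICOutlier(flagTICOutliers(eq))), 0)
  expect_error(flagTICOutliers(tinySpectra(matrix(1, 5, 5), 1:5 + 999)),
               "at least 10")
})

test_that("injected aberrant-TIC pixels are flagged at a plausible rate", {
  run <- memo("outlierRun", generateDataset(
    synthConfig(nPatientsPerROI = 2, coresPerPatient = 2, pixelsPerCore = 36,
                nChannels = 500, nPeaks = 40, nDiscriminative = 0,
                outlierFraction = 0.02, seed = 13)))
  ds <- flagTICOutliers(subtractBaseline(run$dataset))
  frac <- mean(isTICOutlier(ds))
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.06)
  ## the injected pixels themselves are caught
  expect_gte(mean(isTICOutlier(ds)[colnames(ds) %in% run$truth@outlierPixels]),
             0.9)
})

test_that("FFT alignment recovers planted shifts with the documented sign", {
  mz <- seq(1000, 1100, by = 0.25)
  ref <- 50 * exp(-(mz - 1030)^2 / 1.5) + 80 * exp(-(mz - 1070)^2 / 2)
  shift3 <- c(rep(0, 3), ref[1:(length(ref) - 3)])  # displaced by +3
  m <- cbind(matrix(ref, length(ref), 10), shift3)
  ds <- tinySpectra(m, mz)
  al <- alignToReference(ds, shiftMax = 10)
  sh <- preprocessReport(al)$applied_shift
  expect_equal(as.integer(sh), c(rep(0, 10), -3))
  expect_equal(intensities(al)[4:length(mz), 11], ref[4:length(mz)],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(alignToReference(ds, shiftMax = ceiling(length(mz) / 2)),
               "shiftMax")
})

test_that("planted per-core shifts are recovered on synthetic data", {
  run <- memo("shiftRun", generateDataset(
    synthConfig(nPatientsPerROI = 2, coresPerPatient = 3, pixelsPerCore = 20,
                nChannels = 2000, nPeaks = 100, nDiscriminative = 0,
                shiftChannelsMax = 5, seed = 17)))
  pp <- preprocess(run$dataset, alignBy = "core")
  md <- as.data.frame(pixelData(pp))
  sh <- preprocessReport(pp)$applied_shift
  coreSh <- tapply(sh, md$core_id, function(v) v[1])
  planted <- run$truth@shiftPerCore[names(coreSh)]
  expect_gte(mean(coreSh == -planted), 0.95)
})

test_that("TIC normalization equalizes totals and preserves proportions", {
  mz <- c(1000, 1001, 1002)
  m <- cbind(c(1, 1, 2), c(3, 3, 6))  # TICs 4 and 12, mean 8
  ds <- tinySpectra(m, mz)
  out <- intensities(normalizeTIC(ds))
  expect_equal(out[, 1], c(2, 2, 4), ignore_attr = TRUE)
  expect_equal(out[, 2], c(2, 2, 4), ignore_attr = TRUE)
  ## defining property on arbitrary data
  set.seed(3)
  m2 <- matrix(rexp(60), 6, 10)
  nd <- normalizeTIC(tinySpectra(m2, 1:6 + 999))
  tics <- ticValues(nd)
  expect_lt(diff(range(tics)) / mean(tics), 1e-9)
})

test_that("the preprocessing chain is idempotent on its own output", {
  run <- memo("outlierRun", generateDataset(
    synthConfig(nPatientsPerROI = 2, coresPerPatient = 2, pixelsPerCore = 36,
                nChannels = 500, nPeaks = 40, nDiscriminative = 0,
                outlierFraction = 0.02, seed = 13)))
  p1 <- preprocess(run$dataset, alignBy = "core")
  p2 <- preprocess(p1, alignBy = "core")
  expect_true(all(preprocessReport(p2)$applied_shift == 0))
  keep <- !isTICOutlier(p2)
  rel <- abs(intensities(p2)[, keep] - intensities(p1)[, keep])
  expect_lt(mean(rel) / mean(intensities(p1)[, keep]), 0.05)
  ## metadata and pixel order are untouched
  expect_identical(as.data.frame(pixelData(p2))$pixel_id,
                   as.data.frame(pixelData(run$dataset))$pixel_id)
})
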