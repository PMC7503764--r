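test_that("average spectrum is the mean over non-outlier pixels", {
  mz <- 1:4 + 999
  ds <- tinySpectra(cbind(c(0, 2, 0, 0), c(2, 0, 0, 0)), mz)
  expect_equal(averageSpectrum(ds), c(1, 1, 0, 0))
  one <- tinySpectra(matrix(c(5, 1, 0, 2), 4, 1), mz)
  expect_equal(averageSpectrum(one), c(5, 1, 0, 2))
  ## outliers excluded
  ds2 <- tinySpectra(cbind(c(0, 2, 0, 0), c(100, 100, 100, 100)), mz)
  cd <- SummarizedExperiment::colData(ds2)
  cd$tic_outlier <- c(FALSE, TRUE)
  SummarizedExperiment::colData(ds2) <- cd
  expect_equal(averageSpectrum(ds2), c(0, 2, 0, 0))
})

test_that("a planted single Gaussian peak is recovered accurately", {
  mz <- seq(980, 1020, by = 0.05)
  avg <- 100 * exp(-(mz - 1000)^2 / (2 * 0.5^2))
  raw <- fitSpectrumGMM(avg, mz)
  expect_equal(nrow(raw), 1)
  expect_lt(abs(raw$mu - 1000), 0.05)
  expect_lt(abs(raw$sigma - 0.5), 0.1)
  ## area ~ amplitude * sigma * sqrt(2*pi)
  expect_equal(raw$area, 100 * 0.5 * sqrt(2 * pi), tolerance = 0.05)
})

test_that("two well-separated peaks give two components at the right places", {
  mz <- seq(980, 1060, by = 0.05)
  avg <- 100 * exp(-(mz - 1000)^2 / (2 * 0.5^2)) +
    60 * exp(-(mz - 1040)^2 / (2 * 0.8^2))
  raw <- fitSpectrumGMM(avg, mz)
  expect_equal(nrow(raw), 2)
  expect_equal(sort(raw$mu), c(1000, 1040), tolerance = 1e-3)
})

test_that("zero regions produce no components and all-zero input errors", {
  mz <- seq(980, 1020, by = 0.05)
  avg <- 100 * exp(-(mz - 990)^2 / (2 * 0.5^2))
  raw <- fitSpectrumGMM(avg, mz)
  expect_true(all(raw$mu < 1000))  # nothing fitted in the empty half
  expect_error(fitSpectrumGMM(rep(0, length(mz)), mz), "all zero")
  expect_error(fitSpectrumGMM(avg[-1], mz), "lengths")
})

test_that("pruning applies amplitude and width thresholds", {
  raw <- data.frame(mu = c(1000, 1010, 1020), sigma = c(0.5, 0.6, 0.5),
                    amplitude = c(1, 100, 100), area = c(1, 90, 80),
                    segment = 1:3)
  kept <- pruneComponents(raw, ampQuantile = 0.34, sigmaMaxDa = Inf)
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$amplitude == 100))
  ## identity when thresholds are inactive
  expect_equal(nrow(pruneComponents(raw, ampQuantile = 0, sigmaMaxDa = Inf)), 3)
  ## broad background component removed
  raw2 <- rbind(raw, data.frame(mu = 1030, sigma = 50, amplitude = 100,
                                area = 1000, segment = 4))
  expect_false(any(pruneComponents(raw2, 0, sigmaMaxDa = 5)$sigma > 5))
  expect_error(pruneComponents(raw, ampQuantile = 1.5), "ampQuantile")
})

test_that("merging groups components of one peak at the dominant location", {
  two <- data.frame(mu = c(1000.0, 1000.2), sigma = c(0.5, 0.5),
                    amplitude = c(10, 30), area = c(10, 30), segment = 1)
  m <- mergeComponents(two)
  expect_equal(nComponents(m), 1)
  expect_equal(componentTable(m)$mu, 1000.2)   # dominant member wins
  expect_equal(componentTable(m)$area, 40)     # abundances sum
  ## well-separated components stay distinct
  far <- data.frame(mu = c(1000, 1010), sigma = c(0.5, 0.5),
                    amplitude = c(10, 30), area = c(10, 30), segment = 1:2)
  expect_equal(nComponents(mergeComponents(far)), 2)
  ## transitive closure merges a chain pairwise within the rule
  chain <- data.frame(mu = c(1000.0, 1000.3, 1000.6), sigma = rep(0.5, 3),
                      amplitude = c(5, 9, 7), area = c(5, 9, 7), segment = 1)
  mc <- mergeComponents(chain)
  expect_equal(nComponents(mc), 1)
  expect_equal(componentTable(mc)$mu, 1000.3)
  ## provenance partitions the members
  expect_equal(sort(unique(mc@members$group)), seq_len(nComponents(mc)))
})

test_that("abundance estimation matches the analytic Gaussian inner product", {
  mz <- seq(990, 1050, by = 0.05)
  A <- 120
  sigma <- 0.7
  spec <- A * dnorm(mz, 1005, sigma)  # exactly a unit-area peak of area A
  ds <- tinySpectra(cbind(spec, 0 * spec), mz)
  cmp <- data.frame(mu = c(1005, 1040), sigma = c(sigma, 0.6),
                    amplitude = c(1, 1), area = c(1, 1), segment = 1:2)
  model <- mergeComponents(cmp, mz = mz)
  ab <- estimateAbundances(ds, model)
  got <- abundances(ab)
  ## <A*phi, phi> dm = A / (2 sigma sqrt(pi))
  expect_equal(got[1, 1], A / (2 * sigma * sqrt(pi)), tolerance = 1e-3)
  expect_lt(got[2, 1] / got[1, 1], 1e-6)  # disjoint component ~ 0
  expect_true(all(got[, 2] == 0))         # all-zero pixel -> all-zero row
  expect_error(estimateAbundances(tinySpectra(cbind(spec), mz + 1), model),
               "different m/z axes")
})

test_that("component count contracts the channel dimension", {
  pl <- defaultPipeline()
  expect_lt(nComponents(pl$model), nrow(pl$dataset) / 2)
  ## model reconstruction captures >= 90% of total intensity
  avg <- averageSpectrum(pl$dataset)
  mz <- mzAxis(pl$dataset)
  mem <- pl$model@members
  recon <- numeric(length(mz))
  for (i in seq_len(nrow(mem))) {
    recon <- recon + mem$area[i] * dnorm(mz, mem$mu[i], mem$sigma[i])
  }
  expect_gte(1 - sum(abs(recon - avg)) / sum(avg), 0.90)
})

test_that("per-pixel abundance roughly partitions spectrum intensity", {
  pl <- defaultPipeline()
  tot <- colSums(abundances(pl$abundance))
  ## unit-area kernels integrate intensity; compare against the spectrum
  ## integral (sum * channel spacing)
  mz <- mzAxis(pl$dataset)
  specTot <- colSums(intensities(pl$dataset)) * (mz[2] - mz[1])
  expect_true(all(tot <= specTot * 1.1))
})

test_that("mean abundances track the generator's true peak areas", {
  pl <- defaultPipeline()
  tr <- defaultRun()$truth
  cmp <- componentTable(pl$model)
  near <- vapply(cmp$mu, function(m) which.min(abs(tr@peakMz - m)), 1L)
  ok <- abs(tr@peakMz[near] - cmp$mu) < 2
  ## convolution abundances are area / (2 sigma sqrt(pi)); rescale to areas
  ## and pool model components matched to the same true peak
  est <- rowMeans(abundances(pl$abundance)) * 2 * sqrt(pi) * cmp$sigma
  agg <- tapply(est[ok], near[ok], sum)
  trueMean <- colMeans(tr@abundance)[as.integer(names(agg))]
  expect_gte(length(agg), 150)
  expect_gt(cor(as.numeric(agg), trueMean), 0.95)
})

test_that("intensity classes recover planted abundance strata", {
  ## five well-separated log-normal modes
  set.seed(21)
  modes <- 10^(c(1, 2, 3, 4, 5))
  vals <- unlist(lapply(modes, function(m) m * exp(rnorm(60, 0, 0.15))))
  n <- length(vals)
  fake <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = matrix(rep(vals, 3), n, 3)),
    rowData = S4Vectors::DataFrame(mz = seq_len(n) + 999),
    colData = S4Vectors::DataFrame(
      pixel_id = paste0("px", 1:3), core_id = "C1", patient_id = "P1",
      roi_label = "NT", tic_outlier = FALSE))
  am <- new("AbundanceMatrix", fake)
  icm <- fitIntensityClasses(am, nClasses = 5)
  expect_equal(icm@nClasses, 5L)
  expect_equal(length(icm@thresholds), 4)
  ## thresholds sit between the true modes
  expect_true(all(icm@thresholds > modes[-5] & icm@thresholds < modes[-1]))
  ## class assignment matches the planted strata
  expect_equal(as.integer(intensityClass(icm)), rep(1:5, each = 60))
  expect_equal(length(topClassComponents(icm)), 60)
  am2 <- applyIntensityClasses(am, icm)
  expect_equal(SummarizedExperiment::rowData(am2)$intensity_class,
               icm@classes)
})

test_that("a single intensity class yields no thresholds", {
  pl <- defaultPipeline()
  icm <- fitIntensityClasses(pl$abundance, nClasses = 1)
  expect_equal(icm@nClasses, 1L)
  expect_equal(length(icm@thresholds), 0)
  expect_true(all(intensityClass(icm) == 1L))
})
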