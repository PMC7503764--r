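test_that("patient class is the majority ROI over cores, ties canonical", {
  meta <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P3", "P3"),
    core_id = c("P1_C1", "P1_C2", "P1_C3", "P2_C1", "P3_C1", "P3_C2"),
    roi_label = c("NT", "NT", "FA", "ATC", "FA", "NT"))
  got <- assignPatientClass(meta)
  expect_equal(got[["P1"]], "NT")    # majority
  expect_equal(got[["P2"]], "ATC")   # single core
  expect_equal(got[["P3"]], "NT")    # tie -> first in canonical order
})

test_that("fold plans are patient-disjoint, stratified and seeded", {
  ## 35 patients, 5 per class, k = 5: exactly one patient per class per fold
  lv <- roiLevels()
  meta <- do.call(rbind, lapply(seq_len(35), function(i) {
    data.frame(patient_id = sprintf("P%02d", i),
               core_id = sprintf("P%02d_C%d", i, 1:2),
               roi_label = lv[(i - 1) %% 7 + 1],
               tic_outlier = FALSE)
  }))
  plan <- makeFolds(meta, k = 5, seed = 1)
  tab <- table(plan@patientFold, plan@patientClass)
  expect_true(all(tab == 1))
  expect_identical(makeFolds(meta, k = 5, seed = 1)@patientFold,
                   plan@patientFold)
  ## leakage audit across all folds
  for (f in 1:5) {
    idx <- foldPixelIndices(plan, meta, f)
    expect_length(intersect(meta$patient_id[idx$train],
                            meta$patient_id[idx$validation]), 0)
  }
  expect_error(makeFolds(meta, k = 1), "k must be")
  expect_warning(makeFolds(meta[meta$patient_id %in%
                                  sprintf("P%02d", 1:7), ], k = 5),
                 "fewer than k")
})

test_that("the ensemble has C(7,2) binaries with each class in six", {
  set.seed(2)
  n <- 140
  lab <- rep(roiLevels(), each = 20)
  X <- matrix(rnorm(n * 10), n, 10)
  ens <- fitEnsemble(X, lab)
  expect_length(ens@models, 21)
  expect_true(all(table(as.vector(ens@pairs)) == 6))
  expect_error(fitEnsemble(X[1:40, ], lab[1:40], levels = roiLevels()),
               "no training samples")
})

test_that("a separable pair is classified perfectly and Z-scoring is train-only", {
  set.seed(5)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 8), 100, 2))
  lab <- rep(c("NT", "ATC"), each = 100)
  ens <- fitEnsemble(X, lab, levels = c("NT", "ATC"))
  got <- classifyPixels(X, ens)
  expect_equal(got$final, lab)
  expect_equal(unname(ens@center), colMeans(X))
  ## zero-variance feature is dropped, prediction still works
  X3 <- cbind(X, 1)
  ens3 <- fitEnsemble(X3, lab, levels = c("NT", "ATC"))
  expect_length(ens3@center, 2)
  expect_equal(classifyPixels(X3[, seq_along(ens3@center), drop = FALSE],
                              ens3)$final, lab)
})

test_that("permuted labels give near-chance binary validation accuracy", {
  set.seed(8)
  X <- matrix(rnorm(600 * 8), 600, 8)
  lab <- sample(rep(c("NT", "FA"), each = 300))
  tr <- 1:400
  ens <- fitEnsemble(X[tr, ], lab[tr], levels = c("NT", "FA"))
  Z <- sweep(sweep(X[-tr, ], 2, ens@center), 2, ens@scale, `/`)
  pred <- as.character(predict(ens@models[[1]], Z))
  acc <- mean(pred == lab[-tr])
  expect_gt(acc, 0.40)
  expect_lt(acc, 0.60)
})

test_that("the univocal rule assigns a class iff it wins all six matches", {
  lv <- roiLevels()
  pairs <- utils::combn(lv, 2)
  ## NT wins its six binaries; other votes arbitrary but fixed
  votes <- ifelse(pairs[1, ] == "NT" | pairs[2, ] == "NT", "NT", pairs[1, ])
  expect_equal(decideFromVotes(matrix(votes, 1), lv), "NT")
  ## rotational tournament: class i beats j iff (j - i) mod 7 in {1,2,3};
  ## every class has out-degree 3, so no univocal winner exists
  votes2 <- vapply(seq_len(21), function(b) {
    i <- match(pairs[1, b], lv)
    j <- match(pairs[2, b], lv)
    if (((j - i) %% 7) %in% 1:3) pairs[1, b] else pairs[2, b]
  }, character(1))
  expect_equal(decideFromVotes(matrix(votes2, 1), lv), "NOT_CLASSIFIED")
})

test_that("random vote patterns agree with the tournament oracle", {
  lv <- roiLevels()
  pairs <- utils::combn(lv, 2)
  set.seed(12)
  n <- 5000
  pick <- matrix(sample(c(1, 2), n * 21, replace = TRUE), n, 21)
  votes <- vapply(seq_len(21), function(b) pairs[pick[, b], b],
                  character(n))
  got <- decideFromVotes(votes, lv)
  ## oracle: direct definition, class assigned iff it wins every match it is in
  oracle <- vapply(seq_len(n), function(i) {
    winners <- lv[vapply(lv, function(cl) {
      inPair <- pairs[1, ] == cl | pairs[2, ] == cl
      all(votes[i, inPair] == cl)
    }, logical(1))]
    if (length(winners) == 1) winners else "NOT_CLASSIFIED"
  }, character(1))
  expect_equal(got, oracle)
})

test_that("core aggregation follows the eight-class majority with tie rules", {
  expect_equal(classifyCoreSinglePixel(c(rep("NT", 5), rep("FA", 3),
                                         rep("NOT_CLASSIFIED", 2))), "NT")
  expect_equal(classifyCoreSinglePixel(rep("NOT_CLASSIFIED", 4)),
               "NOT_DIAGNOSTIC")
  ## tie between an ROI and NOT_CLASSIFIED prefers the diagnosis
  expect_equal(classifyCoreSinglePixel(c(rep("NT", 4),
                                         rep("NOT_CLASSIFIED", 4))), "NT")
  ## tie between ROIs: canonical order
  expect_equal(classifyCoreSinglePixel(c("FA", "NT")), "NT")
  expect_error(classifyCoreSinglePixel(character(0)), "no pixels")
})

test_that("quality indices match hand-computed confusion arithmetic", {
  truth <- c(rep("NT", 4), rep("FA", 6))
  pred <- c("NT", "NT", "NT", "FA", rep("FA", 6))  # NT: TP=3 FN=1 FP=0 TN=6
  tab <- evaluateDecisions(pred, truth)
  m <- tab@metrics
  expect_equal(m$sensitivity[m$class == "NT"], 0.75)
  expect_equal(m$precision[m$class == "NT"], 1)
  expect_equal(m$accuracy[m$class == "NT"], 0.9)
  expect_equal(tab@overall$correct_fraction, 0.9)
  ## perfect decisions give unit sensitivity everywhere
  perf <- evaluateDecisions(truth, truth)
  expect_true(all(perf@metrics$sensitivity[perf@metrics$class %in%
                                             c("NT", "FA")] == 1))
  expect_equal(rowSums(tab@confusion)[["NT"]], 4)
  expect_error(evaluateDecisions(c("XX"), c("NT")), "unknown predicted")
})

test_that("single-core-pixel datasets collapse the three strategies", {
  run <- memo("onePixRun", generateDataset(
    synthConfig(nPatientsPerROI = 2, coresPerPatient = 3, pixelsPerCore = 1,
                nChannels = 400, nPeaks = 40, nDiscriminative = 21,
                targetD = 3, patientSd = 0, baselineAmp = 0, noiseSd = 0,
                ticCv = 0, shiftChannelsMax = 0, outlierFraction = 0,
                seed = 41)))
  tam <- truthAbundance(run)
  sp <- suppressWarnings(crossValidate(tam, "single-pixel", k = 2, seed = 3))
  hy <- suppressWarnings(crossValidate(tam, "hybrid", k = 2, seed = 3))
  d1 <- coreDecisions(sp)
  d2 <- coreDecisions(hy)
  ## a core's mean spectrum IS its single pixel: decisions must agree
  ## (modulo the NOT_CLASSIFIED -> NOT_DIAGNOSTIC relabeling)
  p1 <- ifelse(d1$predicted == "NOT_DIAGNOSTIC", "ND", d1$predicted)
  p2 <- ifelse(d2$predicted == "NOT_DIAGNOSTIC", "ND", d2$predicted)
  expect_equal(p1[order(d1$core_id)], p2[order(d2$core_id)])
})

test_that("strong planted effects give high single-pixel core accuracy", {
  pl <- defaultPipeline()
  cv <- suppressWarnings(crossValidate(pl$abundance, "single-pixel",
                                       seed = 7))
  expect_gte(overallAccuracy(cv), 0.80)
  ## chance + 3 sigma on 42 cores
  expect_gt(overallAccuracy(cv), 1 / 7 + 3 * sqrt((1 / 7) * (6 / 7) / 42))
  expect_equal(tab <- cv@overall$n_cores, 42)
  expect_true(all(rowSums(confusionMatrix(cv)) == 6))
})

test_that("the feature-set ablation runs on all and top components alike", {
  pl <- defaultPipeline()
  icm <- fitIntensityClasses(pl$abundance)
  cvTop <- suppressWarnings(crossValidate(pl$abundance, "single-pixel",
                                          features = "top", icm = icm,
                                          seed = 7))
  expect_equal(cvTop@featureSet, "top")
  expect_gte(overallAccuracy(cvTop), 0)
  expect_equal(cvTop@overall$n_cores, 42)
})
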