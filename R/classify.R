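#' @importFrom e1071 svm
#' @importFrom stats predict
NULL

#' Assign each patient to a tissue class
#'
#' A patient's class is the ROI type of the majority of that patient's
#' cores; ties are broken by the canonical ROI order (\code{roiLevels()}).
#'
#' @param meta Pixel metadata (data.frame/DataFrame with patient_id,
#'   core_id, roi_label) or an \linkS4class{MSISpectra} /
#'   \linkS4class{AbundanceMatrix}.
#' @return Named character vector: class per patient.
#' @export
assignPatientClass <- function(meta) {
  if (is(meta, "SummarizedExperiment")) meta <- colData(meta)
  meta <- as.data.frame(meta)
  cores <- unique(meta[, c("patient_id", "core_id", "roi_label")])
  lv <- roiLevels()
  vapply(split(cores$roi_label, cores$patient_id), function(rois) {
    tb <- table(factor(rois, levels = lv))
    lv[which.max(tb)]  # which.max takes the first maximum: canonical order
  }, character(1))
}

#' Build a patient-stratified k-fold plan
#'
#' Patients are stratified by patient-level class and dealt round-robin
#' (after a seeded shuffle within class) into k folds; every core and pixel
#' of a patient inherits its fold, so training and validation sets of any
#' fold share no patient.
#'
#' @param meta As in \code{\link{assignPatientClass}}.
#' @param k Number of folds (>= 2).
#' @param seed Seed for the within-class shuffles.
#' @return A \linkS4class{FoldPlan}.
#' @export
makeFolds <- function(meta, k = 5L, seed = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  pcls <- assignPatientClass(meta)
  if (any(table(pcls) < k))
    warning("some classes have fewer than k patients; fold sizes will be uneven")
  fold <- integer(length(pcls))
  names(fold) <- names(pcls)
  .withSeed(seed, {
    offset <- 0L
    for (cl in unique(pcls)) {
      ids <- names(pcls)[pcls == cl]
      ids <- sample(ids)
      fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- offset + length(ids)
    }
  })
  obj <- new("FoldPlan", k = k, patientFold = fold, patientClass = pcls)
  validObject(obj)
  obj
}

#' @rdname makeFolds
#' @param plan A FoldPlan.
#' @param fold Fold index in 1..k.
#' @return \code{foldPixelIndices}: list with integer vectors \code{train}
#'   and \code{validation} of non-outlier pixel column indices.
#' @export
foldPixelIndices <- function(plan, meta, fold) {
  if (is(meta, "SummarizedExperiment")) meta <- colData(meta)
  valPat <- names(plan@patientFold)[plan@patientFold == fold]
  keep <- !meta$tic_outlier
  list(train = which(keep & !(meta$patient_id %in% valPat)),
       validation = which(keep & meta$patient_id %in% valPat))
}

#' Fit the one-vs-one linear SVM ensemble
#'
#' Features are standardized with the Z-score method using means and SDs of
#' the training pixels only (zero-variance features are dropped and
#' recorded); one linear soft-margin SVM is then fitted per unordered pair
#' of classes on that pair's training pixels, with class weights inversely
#' proportional to class frequency.
#'
#' @param X Numeric matrix, samples x features (training pixels or core
#'   means).
#' @param labels Class label per row of X.
#' @param featureIdx Indices of X's columns in the source AbundanceMatrix
#'   (bookkeeping only).
#' @param featureSet Descriptor stored with the model ("all"/"top").
#' @param cost SVM regularization parameter C.
#' @param levels Class labels to model (default: canonical ROI order
#'   restricted to the labels present).
#' @return An \linkS4class{EnsembleModel} with choose(k, 2) binaries.
#' @export
fitEnsemble <- function(X, labels, featureIdx = seq_len(ncol(X)),
                        featureSet = "all", cost = 1,
                        levels = NULL) {
  if (is.null(levels)) levels <- intersect(roiLevels(), unique(labels))
  missing <- setdiff(levels, unique(labels))
  if (length(missing))
    stop("no training samples for class: ", paste(missing, collapse = ", "))
  small <- names(which(table(factor(labels, levels)) < 2))
  if (length(small))
    stop("fewer than 2 training samples for class: ",
         paste(small, collapse = ", "))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  usable <- scl > 0
  dropped <- colnames(X)[!usable]
  if (is.null(dropped)) dropped <- as.character(which(!usable))
  Z <- sweep(sweep(X[, usable, drop = FALSE], 2, ctr[usable]), 2,
             scl[usable], `/`)
  pairs <- utils::combn(levels, 2)
  models <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sel <- labels %in% c(a, b)
    y <- factor(labels[sel], levels = c(a, b))
    tb <- table(y)
    cw <- sum(tb) / (2 * tb)
    e1071::svm(x = Z[sel, , drop = FALSE], y = y, kernel = "linear",
               cost = cost, scale = FALSE,
               class.weights = stats::setNames(as.numeric(cw), names(cw)))
  })
  obj <- new("EnsembleModel",
             center = ctr[usable], scale = scl[usable],
             dropped = as.character(dropped),
             featureIdx = as.integer(featureIdx[usable]),
             featureSet = featureSet, levels = levels,
             pairs = pairs, models = models, cost = cost)
  validObject(obj)
  obj
}

#' Univocal decision from one-vs-one votes
#'
#' Given the 21 binary votes for each sample (7 classes), a sample is
#' assigned class C iff all 6 binaries featuring C voted C -- i.e. C has
#' out-degree 6 in the pairwise tournament. At most one class can satisfy
#' this (two such classes would both have to win their mutual match), so
#' the rule is well defined; otherwise the sample is NOT_CLASSIFIED.
#'
#' @param votes Character matrix, samples x binaries, each entry a class
#'   label.
#' @param levels The class labels (default canonical ROI order).
#' @return Character vector of final classes (ROI label or
#'   "NOT_CLASSIFIED").
#' @export
decideFromVotes <- function(votes, levels = roiLevels()) {
  votes <- as.matrix(votes)
  n <- nrow(votes)
  k <- length(levels)
  wins <- matrix(0L, n, k, dimnames = list(NULL, levels))
  for (b in seq_len(ncol(votes))) {
    w <- match(votes[, b], levels)
    wins[cbind(seq_len(n), w)] <- wins[cbind(seq_len(n), w)] + 1L
  }
  top <- max.col(wins, ties.method = "first")
  full <- wins[cbind(seq_len(n), top)] == (k - 1L)
  ifelse(full, levels[top], .NOT_CLASSIFIED)
}

#' Classify pixels (or core means) with the ensemble
#'
#' Standardizes the feature vectors with the ensemble's training
#' parameters, collects all one-vs-one votes and applies the univocal rule.
#'
#' @param X Samples x features matrix on the ensemble's feature set (raw
#'   abundances; standardization happens inside).
#' @param ensemble An \linkS4class{EnsembleModel}.
#' @return List: \code{final} (class or NOT_CLASSIFIED per sample),
#'   \code{votes} (samples x binaries character matrix).
#' @export
classifyPixels <- function(X, ensemble) {
  nm <- names(ensemble@center)
  if (!is.null(nm) && !is.null(colnames(X)) && all(nm %in% colnames(X))) {
    X <- X[, nm, drop = FALSE]
  } else if (ncol(X) != length(ensemble@center)) {
    stop("feature dimension does not match the ensemble")
  }
  Z <- sweep(sweep(X, 2, ensemble@center), 2, ensemble@scale, `/`)
  votes <- vapply(ensemble@models, function(m)
    as.character(predict(m, Z)), character(nrow(Z)))
  if (!is.matrix(votes)) votes <- matrix(votes, nrow = nrow(Z))
  list(final = decideFromVotes(votes, ensemble@levels), votes = votes)
}

#' Aggregate pixel decisions into a core decision
#'
#' The core label is the most frequent of eight classes over its pixels
#' (seven ROIs plus NOT_CLASSIFIED); a NOT_CLASSIFIED majority yields
#' NOT_DIAGNOSTIC. Ties prefer any ROI over NOT_CLASSIFIED, then the
#' canonical ROI order.
#'
#' @param pixelClasses Character vector of per-pixel decisions for one core.
#' @return Single core class (ROI label or "NOT_DIAGNOSTIC").
#' @export
classifyCoreSinglePixel <- function(pixelClasses) {
  if (!length(pixelClasses)) stop("core has no pixels")
  lv <- c(roiLevels(), .NOT_CLASSIFIED)  # ROIs first: ties prefer a diagnosis
  tb <- table(factor(pixelClasses, levels = lv))
  win <- lv[which.max(tb)]
  if (win == .NOT_CLASSIFIED) .NOT_DIAGNOSTIC else win
}

#' Cross-validated core classification
#'
#' Runs the full classification machinery under a patient-stratified k-fold
#' plan and pools validation decisions across folds into one core decision
#' table. Three strategies are supported: \code{"single-pixel"} (binaries
#' trained and applied on individual spectra, core = modal pixel class),
#' \code{"mean-spectrum"} (binaries trained and applied on per-core mean
#' abundance vectors) and \code{"hybrid"} (binaries trained on pixels,
#' applied to core means). Outlier-flagged pixels take part in neither
#' training nor classification.
#'
#' @param abund An \linkS4class{AbundanceMatrix}.
#' @param approach One of "single-pixel", "mean-spectrum", "hybrid".
#' @param features "all", "top" or index vector.
#' @param icm Optional \linkS4class{IntensityClassModel} for "top".
#' @param k Folds.
#' @param seed Seed for the fold plan.
#' @param cost SVM regularization parameter.
#' @return A \linkS4class{CoreDecisionTable}; for the single-pixel approach
#'   \code{x@overall$pixel_not_classified_fraction} additionally reports the
#'   fraction of validation pixels left NOT_CLASSIFIED by the univocal rule.
#' @export
crossValidate <- function(abund, approach = c("single-pixel", "mean-spectrum",
                                              "hybrid"),
                          features = "all", icm = NULL, k = 5L, seed = NULL,
                          cost = 1) {
  approach <- match.arg(approach)
  featIdx <- .resolveFeatures(abund, features, icm)
  meta <- as.data.frame(colData(abund))
  plan <- makeFolds(meta, k = k, seed = seed)
  A <- t(abundances(abund)[featIdx, , drop = FALSE])  # pixels x features
  colnames(A) <- paste0("c", featIdx)
  lv <- intersect(roiLevels(), unique(meta$roi_label[!meta$tic_outlier]))

  coreMeta <- unique(meta[, c("core_id", "patient_id", "roi_label")])
  rownames(coreMeta) <- coreMeta$core_id
  coreMean <- function(cols) {
    res <- t(vapply(split(cols, meta$core_id[cols]), function(ii)
      colMeans(A[ii, , drop = FALSE]), numeric(ncol(A))))
    colnames(res) <- colnames(A)
    res
  }

  corePred <- stats::setNames(rep(NA_character_, nrow(coreMeta)),
                              coreMeta$core_id)
  nPixTot <- 0L
  nPixNC <- 0L
  for (f in seq_len(plan@k)) {
    idx <- foldPixelIndices(plan, meta, f)
    if (!length(idx$validation)) next
    if (approach == "mean-spectrum") {
      Mtr <- coreMean(idx$train)
      ens <- fitEnsemble(Mtr, coreMeta[rownames(Mtr), "roi_label"],
                         featureIdx = featIdx, cost = cost,
                         featureSet = if (is.character(features)) features
                         else "custom",
                         levels = lv)
    } else {
      ens <- fitEnsemble(A[idx$train, , drop = FALSE],
                         meta$roi_label[idx$train],
                         featureIdx = featIdx, cost = cost,
                         featureSet = if (is.character(features)) features
                         else "custom",
                         levels = lv)
    }
    if (approach == "single-pixel") {
      dec <- classifyPixels(A[idx$validation, , drop = FALSE], ens)
      nPixTot <- nPixTot + length(idx$validation)
      nPixNC <- nPixNC + sum(dec$final == .NOT_CLASSIFIED)
      byCore <- split(dec$final, meta$core_id[idx$validation])
      corePred[names(byCore)] <- vapply(byCore, classifyCoreSinglePixel,
                                        character(1))
    } else {
      Mva <- coreMean(idx$validation)
      dec <- classifyPixels(Mva, ens)
      pred <- ifelse(dec$final == .NOT_CLASSIFIED, .NOT_DIAGNOSTIC, dec$final)
      corePred[rownames(Mva)] <- pred
    }
  }
  done <- !is.na(corePred)
  tab <- evaluateDecisions(corePred[done],
                           coreMeta[names(corePred)[done], "roi_label"],
                           levels = lv)
  tab@approach <- approach
  tab@featureSet <- if (is.character(features)) features else "custom"
  tab@decisions$patient_id <- coreMeta[tab@decisions$core_id, "patient_id"]
  if (approach == "single-pixel" && nPixTot > 0)
    tab@overall$pixel_not_classified_fraction <- nPixNC / nPixTot
  tab
}

#' One-vs-rest quality indices for core decisions
#'
#' Builds the true-by-predicted confusion matrix (true ROI classes in rows;
#' predicted classes plus NOT_DIAGNOSTIC in columns) and per-class
#' one-vs-rest sensitivity, precision and accuracy, the overall correct
#' fraction, the correct fraction among diagnosed cores and the
#' not-diagnostic fraction.
#'
#' @param predicted Character vector of predicted core classes (ROI or
#'   NOT_DIAGNOSTIC), named by core id if available.
#' @param truth True ROI per core, same order.
#' @param levels ROI labels to tabulate (default canonical order).
#' @return A \linkS4class{CoreDecisionTable}.
#' @export
evaluateDecisions <- function(predicted, truth, levels = roiLevels()) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length")
  bad <- setdiff(unique(truth), levels)
  if (length(bad)) stop("unknown true label(s): ", paste(bad, collapse = ", "))
  badp <- setdiff(unique(predicted), c(levels, .NOT_DIAGNOSTIC))
  if (length(badp))
    stop("unknown predicted label(s): ", paste(badp, collapse = ", "))
  predLv <- c(levels, .NOT_DIAGNOSTIC)
  conf <- table(factor(truth, levels), factor(predicted, predLv))
  conf <- unclass(conf)
  n <- length(truth)
  metrics <- do.call(rbind, lapply(levels, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    tn <- n - tp - fp - fn
    data.frame(class = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               accuracy = (tp + tn) / n,
               stringsAsFactors = FALSE)
  }))
  correct <- sum(predicted == truth)
  diagnosed <- predicted != .NOT_DIAGNOSTIC
  dec <- data.frame(core_id = if (!is.null(names(predicted)))
    names(predicted) else seq_along(predicted),
    patient_id = NA_character_,
    true_roi = truth, predicted = predicted,
    stringsAsFactors = FALSE)
  new("CoreDecisionTable",
      decisions = dec, confusion = conf, metrics = metrics,
      overall = list(
        n_cores = n,
        correct_fraction = correct / n,
        diagnosed_correct_fraction = if (any(diagnosed))
          sum(predicted == truth & diagnosed) / sum(diagnosed) else NA_real_,
        not_diagnostic_fraction = mean(!diagnosed)),
      approach = "unspecified", featureSet = "unspecified")
}
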