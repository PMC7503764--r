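#' @importFrom methods new validObject is show setValidity slot callNextMethod
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData colData<- rowData<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MSISpectra: pixel-level mass spectra on a unified m/z axis
#'
#' Container for a mass spectrometry imaging dataset: an intensity matrix
#' (m/z channels in rows, pixels in columns) extending
#' \link[SummarizedExperiment]{SummarizedExperiment}. The m/z axis lives in
#' \code{rowData(x)$mz}; pixel metadata (\code{pixel_id}, \code{core_id},
#' \code{patient_id}, \code{roi_label}, \code{x}, \code{y},
#' \code{tic_outlier}, \code{applied_shift}) live in \code{colData(x)}.
#' Every pixel belongs to exactly one core and every core to one patient.
#'
#' @export
setClass("MSISpectra", contains = "SummarizedExperiment")

setValidity("MSISpectra", function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'intensity' is missing")
  if (!"mz" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain 'mz'")
  else {
    mz <- rowData(object)$mz
    if (any(diff(mz) <= 0)) msg <- c(msg, "m/z axis must be strictly increasing")
  }
  need <- c("pixel_id", "core_id", "patient_id", "roi_label", "tic_outlier")
  miss <- setdiff(need, names(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing column(s):", paste(miss, collapse = ", ")))
  if ("intensity" %in% names(assays(object)) &&
      anyNA(assay(object, "intensity")))
    msg <- c(msg, "intensities must not contain NA/NaN")
  if (all(c("core_id", "patient_id") %in% names(colData(object)))) {
    cd <- colData(object)
    pc <- unique(data.frame(core = cd$core_id, pat = cd$patient_id))
    if (anyDuplicated(pc$core))
      msg <- c(msg, "a core maps to more than one patient")
  }
  if ("roi_label" %in% names(colData(object))) {
    bad <- setdiff(unique(colData(object)$roi_label), c(roiLevels(), "UNKNOWN"))
    if (length(bad))
      msg <- c(msg, paste("unknown roi_label value(s):", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MSISpectra object
#'
#' @param intensity Numeric matrix, channels x pixels, non-negative.
#' @param mz Strictly increasing numeric m/z axis (Da), one value per row.
#' @param pixelData data.frame or DataFrame with one row per pixel and at
#'   least columns \code{pixel_id}, \code{core_id}, \code{patient_id},
#'   \code{roi_label}; coordinates \code{x}, \code{y} optional.
#' @return An \linkS4class{MSISpectra} object.
#' @export
MSISpectra <- function(intensity, mz, pixelData) {
  pixelData <- DataFrame(pixelData)
  if (is.null(pixelData$tic_outlier)) pixelData$tic_outlier <- FALSE
  if (is.null(pixelData$applied_shift)) pixelData$applied_shift <- 0L
  intensity <- as.matrix(intensity)
  colnames(intensity) <- pixelData$pixel_id
  rownames(pixelData) <- pixelData$pixel_id
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(mz = as.numeric(mz)),
    colData = pixelData)
  new("MSISpectra", se)
}

#' @describeIn MSISpectra The m/z axis (Da).
#' @param x An MSISpectra object.
#' @export
mzAxis <- function(x) rowData(x)$mz

#' @describeIn MSISpectra Intensity matrix, channels x pixels.
#' @export
intensities <- function(x) assay(x, "intensity")

#' @describeIn MSISpectra Pixel metadata table.
#' @export
pixelData <- function(x) colData(x)

#' @describeIn MSISpectra Per-pixel total ion current (sum of intensities).
#' @export
ticValues <- function(x) colSums(assay(x, "intensity"))

#' @describeIn MSISpectra Logical vector: pixel flagged as TIC outlier?
#' @export
isTICOutlier <- function(x) colData(x)$tic_outlier

#' @describeIn MSISpectra Per-pixel ROI labels.
#' @export
roiLabels <- function(x) colData(x)$roi_label

setMethod("show", "MSISpectra", function(object) {
  cat(sprintf("MSISpectra: %d channels x %d pixels\n",
              nrow(object), ncol(object)))
  mz <- mzAxis(object)
  cat(sprintf("  m/z range %.1f-%.1f Da | %d cores | %d patients | %d outlier pixels\n",
              min(mz), max(mz),
              length(unique(colData(object)$core_id)),
              length(unique(colData(object)$patient_id)),
              sum(colData(object)$tic_outlier)))
  tb <- table(colData(object)$roi_label)
  cat("  pixels per ROI:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})

#' SynthConfig: parameters of the synthetic MSI generator
#'
#' Describes a simulated tissue-microarray MSI study: a patient -> core ->
#' pixel hierarchy over the seven thyroid ROI classes, Gaussian peptide
#' peaks on a common m/z axis, planted between-class effect sizes on peak
#' areas, per-patient molecular profiles, per-ROI heterogeneity, and the
#' instrumental artifacts (baseline, noise, TIC variation, per-core m/z
#' shift, aberrant-TIC pixels) that preprocessing must undo.
#'
#' @slot nPatientsPerROI patients simulated per ROI class.
#' @slot coresPerPatient cores (tissue cylinders) per patient.
#' @slot pixelsPerCore spectra per core.
#' @slot mzRange acquisition range in Da.
#' @slot nChannels channels of the common m/z axis.
#' @slot nPeaks number of true peptide peaks.
#' @slot peakSigmaDa Gaussian peak width (Da) at m/z 2000; widths scale
#'   linearly with m/z as in TOF data.
#' @slot nDiscriminative peaks given ROI-specific abundance (split evenly
#'   across the 7 ROIs as "signature" peaks, up in one ROI vs all others).
#' @slot targetD planted Cohen's d per signature peak against other ROIs.
#' @slot patientSd SD (log scale) of the per-(patient, peak) multiplicative
#'   random effect emulating inter-individual profile differences.
#' @slot pixelCv baseline per-pixel coefficient of variation of peak areas.
#' @slot roiHeterogeneity named per-ROI multiplier of pixelCv (NT lowest,
#'   ATC highest by default).
#' @slot baselineAmp amplitude (a.u.) of the smooth chemical baseline.
#' @slot noiseSd SD of additive detector noise (a.u.).
#' @slot ticCv coefficient of variation of the per-pixel TIC factor.
#' @slot shiftChannelsMax maximal per-core integer channel shift.
#' @slot outlierFraction fraction of pixels given an aberrant TIC.
#' @slot seed integer RNG seed; the generator is fully reproducible.
#' @export
setClass("SynthConfig", representation(
  nPatientsPerROI = "integer", coresPerPatient = "integer",
  pixelsPerCore = "integer", mzRange = "numeric", nChannels = "integer",
  nPeaks = "integer", peakSigmaDa = "numeric", nDiscriminative = "integer",
  targetD = "numeric", patientSd = "numeric", pixelCv = "numeric",
  roiHeterogeneity = "numeric", baselineAmp = "numeric", noiseSd = "numeric",
  ticCv = "numeric", shiftChannelsMax = "integer", outlierFraction = "numeric",
  seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  cnt <- c(nPatientsPerROI = object@nPatientsPerROI,
           coresPerPatient = object@coresPerPatient,
           pixelsPerCore = object@pixelsPerCore,
           nChannels = object@nChannels, nPeaks = object@nPeaks)
  if (any(cnt < 1)) msg <- c(msg, "all counts must be >= 1")
  if (length(object@mzRange) != 2 || object@mzRange[1] >= object@mzRange[2])
    msg <- c(msg, "mzRange must be (low, high) with low < high")
  if (object@targetD < 0) msg <- c(msg, "targetD must be >= 0")
  if (object@outlierFraction < 0 || object@outlierFraction >= 1)
    msg <- c(msg, "outlierFraction must be in [0, 1)")
  if (object@nDiscriminative > object@nPeaks)
    msg <- c(msg, "nDiscriminative cannot exceed nPeaks")
  if (!all(roiLevels() %in% names(object@roiHeterogeneity)))
    msg <- c(msg, "roiHeterogeneity must name all 7 ROIs")
  if (length(msg)) msg else TRUE
})

#' @rdname SynthConfig-class
#' @param nPatientsPerROI,coresPerPatient,pixelsPerCore,mzRange,nChannels
#'   see slots.
#' @param nPeaks,peakSigmaDa,nDiscriminative,targetD,patientSd,pixelCv see slots.
#' @param roiHeterogeneity,baselineAmp,noiseSd,ticCv see slots.
#' @param shiftChannelsMax,outlierFraction,seed see slots.
#' @return A validated \code{SynthConfig}.
#' @export
synthConfig <- function(nPatientsPerROI = 2L, coresPerPatient = 3L,
                        pixelsPerCore = 50L, mzRange = c(700, 3700),
                        nChannels = 4000L, nPeaks = 200L, peakSigmaDa = 2,
                        nDiscriminative = 70L, targetD = 1.5,
                        patientSd = 0.15, pixelCv = 0.30,
                        roiHeterogeneity = c(NT = 0.6, FA = 0.8,
                                             `PTC-CV` = 1.0, `PTC-FV` = 1.0,
                                             FTC = 1.1, ATC = 1.6, MTC = 0.9),
                        baselineAmp = 30, noiseSd = 3,
                        ticCv = 0.2, shiftChannelsMax = 3L,
                        outlierFraction = 0.01, seed = 1L) {
  obj <- new("SynthConfig",
             nPatientsPerROI = as.integer(nPatientsPerROI),
             coresPerPatient = as.integer(coresPerPatient),
             pixelsPerCore = as.integer(pixelsPerCore),
             mzRange = as.numeric(mzRange), nChannels = as.integer(nChannels),
             nPeaks = as.integer(nPeaks), peakSigmaDa = peakSigmaDa,
             nDiscriminative = as.integer(nDiscriminative), targetD = targetD,
             patientSd = patientSd, pixelCv = pixelCv,
             roiHeterogeneity = roiHeterogeneity, baselineAmp = baselineAmp,
             noiseSd = noiseSd, ticCv = ticCv,
             shiftChannelsMax = as.integer(shiftChannelsMax),
             outlierFraction = outlierFraction, seed = as.integer(seed))
  validObject(obj)
  obj
}

#' GroundTruth of a simulated dataset
#'
#' Everything the generator knows that the analysis must recover: true peak
#' locations/widths, per-ROI mean peak areas, the analytically planted
#' Cohen's d per peak and ROI pair, the noise-free per-pixel peak areas,
#' injected TIC-outlier pixels and per-core channel shifts.
#'
#' @slot peakMz,peakSigma true peak locations and widths (Da).
#' @slot baseAmplitude base (non-ROI) mean peak area per peak.
#' @slot roiAmplitude nPeaks x 7 matrix of mean peak areas per ROI.
#' @slot plantedD nPeaks x 21 matrix of planted Cohen's d per ROI pair
#'   (0 for non-discriminative peaks).
#' @slot signatureROI per-peak ROI whose signature the peak is (NA if none).
#' @slot abundance pixels x nPeaks matrix of true per-pixel peak areas.
#' @slot outlierPixels pixel ids injected with aberrant TIC.
#' @slot shiftPerCore named integer, planted channel shift per core.
#' @slot config the generating \linkS4class{SynthConfig}.
#' @export
setClass("GroundTruth", representation(
  peakMz = "numeric", peakSigma = "numeric", baseAmplitude = "numeric",
  roiAmplitude = "matrix", plantedD = "matrix", signatureROI = "character",
  abundance = "matrix", outlierPixels = "character",
  shiftPerCore = "integer", config = "SynthConfig"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d peaks (%d discriminative), %d pixels, %d cores shifted, %d outlier pixels\n",
              length(object@peakMz), sum(!is.na(object@signatureROI)),
              nrow(object@abundance), sum(object@shiftPerCore != 0),
              length(object@outlierPixels)))
})

#' ComponentModel: the pruned, merged Gaussian mixture of the average spectrum
#'
#' Each retained spectral component is one Gaussian (or a merged group of
#' Gaussians modeling the same peak) and stands for one peptide ion species.
#' \code{components} holds the final components ordered by m/z with the
#' dominant member's location; \code{members} holds the retained raw
#' Gaussians with their group index (the provenance partition).
#'
#' @slot components data.frame: mu, sigma, amplitude, area, n_members.
#' @slot members data.frame of raw Gaussians: mu, sigma, amplitude, area, group.
#' @slot mzAxis the m/z axis the model was fitted on.
#' @export
setClass("ComponentModel", representation(
  components = "data.frame", members = "data.frame", mzAxis = "numeric"))

setValidity("ComponentModel", function(object) {
  msg <- character()
  cmp <- object@components
  if (nrow(cmp) > 1 && any(diff(cmp$mu) <= 0))
    msg <- c(msg, "component locations must be strictly increasing")
  g <- object@members$group
  if (!setequal(unique(g), seq_len(nrow(cmp))))
    msg <- c(msg, "member groups must partition 1..n_components")
  if (any(object@members$sigma <= 0)) msg <- c(msg, "sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ComponentModel Number of final components.
#' @param x A ComponentModel.
#' @export
nComponents <- function(x) nrow(x@components)

#' @describeIn ComponentModel Final component table (mu, sigma, amplitude,
#'   area, n_members).
#' @export
componentTable <- function(x) x@components

setMethod("show", "ComponentModel", function(object) {
  cmp <- object@components
  cat(sprintf("ComponentModel: %d components (%d raw Gaussians) in m/z %.1f-%.1f\n",
              nrow(cmp), nrow(object@members),
              min(cmp$mu), max(cmp$mu)))
})

#' AbundanceMatrix: pixels-by-components feature space
#'
#' Component abundances (peak-area scale) per pixel, stored components x
#' pixels as a \link[SummarizedExperiment]{SummarizedExperiment} (assay
#' \code{"abundance"}); component m/z, width and (after
#' \code{\link{fitIntensityClasses}}) intensity class in \code{rowData},
#' pixel metadata in \code{colData}.
#'
#' @export
setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "assay 'abundance' is missing")
  else if (anyNA(assay(object, "abundance")))
    msg <- c(msg, "abundances must not contain NA")
  if (!"mz" %in% names(rowData(object)))
    msg <- c(msg, "rowData must contain component 'mz'")
  if (length(msg)) msg else TRUE
})

#' @describeIn AbundanceMatrix Abundance matrix, components x pixels.
#' @param x An AbundanceMatrix.
#' @export
abundances <- function(x) assay(x, "abundance")

#' @describeIn AbundanceMatrix Component m/z labels.
#' @export
componentMz <- function(x) rowData(x)$mz

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d components x %d pixels\n",
              nrow(object), ncol(object)))
  if ("intensity_class" %in% names(rowData(object))) {
    tb <- table(rowData(object)$intensity_class)
    cat("  intensity classes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

#' IntensityClassModel: abundance strata of spectral components
#'
#' One-dimensional Gaussian mixture over log10 mean component abundances;
#' thresholds sit at posterior-equality crossings between adjacent mixture
#' classes, mirroring the stratification of components into intensity
#' classes with the top class holding the most abundant species.
#'
#' @slot thresholds ascending abundance cut points (a.u., linear scale).
#' @slot classes integer class (1 = dimmest) per component.
#' @slot nClasses number of classes fitted.
#' @slot mixture list with the fitted 1-D mixture parameters.
#' @export
setClass("IntensityClassModel", representation(
  thresholds = "numeric", classes = "integer", nClasses = "integer",
  mixture = "list"))

setValidity("IntensityClassModel", function(object) {
  msg <- character()
  if (length(object@thresholds) &&
      any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be strictly ascending")
  if (length(object@thresholds) != object@nClasses - 1L)
    msg <- c(msg, "need nClasses - 1 thresholds")
  if (length(msg)) msg else TRUE
})

#' @describeIn IntensityClassModel Indices of components in the top
#'   (most abundant) class.
#' @param x An IntensityClassModel.
#' @export
topClassComponents <- function(x) which(x@classes == x@nClasses)

#' @describeIn IntensityClassModel Per-component class assignment.
#' @export
intensityClass <- function(x) x@classes

setMethod("show", "IntensityClassModel", function(object) {
  cat(sprintf("IntensityClassModel: %d classes, thresholds > %s a.u.\n",
              object@nClasses,
              paste(signif(object@thresholds, 4), collapse = ", > ")))
  tb <- table(object@classes)
  cat("  components per class:", paste(tb, collapse = ", "), "\n")
})

#' EnsembleModel: one-vs-one linear SVM ensemble
#'
#' Z-score standardization parameters learned from training pixels plus one
#' linear soft-margin SVM per unordered pair of tissue classes (21 binaries
#' for 7 classes; each class sits in exactly 6 of them).
#'
#' @slot center,scale per-feature training mean and SD (zero-variance
#'   features are dropped and recorded).
#' @slot dropped names/indices of dropped zero-variance features.
#' @slot featureIdx integer indices of the features used (into the
#'   AbundanceMatrix rows).
#' @slot featureSet descriptor: "all" or "top".
#' @slot levels class labels covered.
#' @slot pairs 2 x n matrix of class pairs.
#' @slot models list of fitted \link[e1071]{svm} binaries.
#' @slot cost SVM regularization parameter.
#' @export
setClass("EnsembleModel", representation(
  center = "numeric", scale = "numeric", dropped = "character",
  featureIdx = "integer", featureSet = "character", levels = "character",
  pairs = "matrix", models = "list", cost = "numeric"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  k <- length(object@levels)
  if (ncol(object@pairs) != choose(k, 2))
    msg <- c(msg, "need choose(k, 2) binary classifiers")
  cnt <- table(as.vector(object@pairs))
  if (length(cnt) && any(cnt != k - 1))
    msg <- c(msg, "each class must appear in exactly k-1 binaries")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d one-vs-one linear SVMs over %d classes, %d features (%s)\n",
              length(object@models), length(object@levels),
              length(object@center), object@featureSet))
})

#' FoldPlan: patient-stratified cross-validation partition
#'
#' Patients (not pixels) are partitioned into k folds, stratified by
#' patient-level class; all cores and pixels of a patient inherit its fold,
#' which guarantees patient-disjoint training and validation sets.
#'
#' @slot k number of folds.
#' @slot patientFold named integer: fold per patient.
#' @slot patientClass named character: class per patient.
#' @export
setClass("FoldPlan", representation(
  k = "integer", patientFold = "integer", patientClass = "character"))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (object@k < 2) msg <- c(msg, "k must be >= 2")
  if (is.null(names(object@patientFold)))
    msg <- c(msg, "patientFold must be named by patient id")
  if (any(object@patientFold < 1 | object@patientFold > object@k))
    msg <- c(msg, "fold indices out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d patients in %d patient-stratified folds\n",
              length(object@patientFold), object@k))
  print(table(fold = object@patientFold, class = object@patientClass))
})

#' CoreDecisionTable: core-level classification outcome
#'
#' Per-core predicted class among the 7 ROIs or NOT_DIAGNOSTIC, the
#' true-by-predicted confusion matrix, and one-vs-rest quality indices.
#'
#' @slot decisions data.frame: core_id, patient_id, true_roi, predicted,
#'   n_pixels, n_classified.
#' @slot confusion 7 x 8 matrix, true ROI x (7 ROIs + NOT_DIAGNOSTIC).
#' @slot metrics data.frame of per-class one-vs-rest sensitivity, precision,
#'   accuracy.
#' @slot overall list: correct fraction, diagnosed-only correct fraction,
#'   not-diagnostic fraction, n cores.
#' @slot approach "single-pixel", "mean-spectrum" or "hybrid".
#' @slot featureSet feature set descriptor.
#' @export
setClass("CoreDecisionTable", representation(
  decisions = "data.frame", confusion = "matrix", metrics = "data.frame",
  overall = "list", approach = "character", featureSet = "character"))

#' @describeIn CoreDecisionTable Per-core decisions.
#' @param x A CoreDecisionTable.
#' @export
coreDecisions <- function(x) x@decisions

#' @describeIn CoreDecisionTable Confusion matrix (true x predicted).
#' @export
confusionMatrix <- function(x) x@confusion

#' @describeIn CoreDecisionTable Overall quality summary.
#' @export
overallAccuracy <- function(x) x@overall$correct_fraction

setMethod("show", "CoreDecisionTable", function(object) {
  cat(sprintf("CoreDecisionTable (%s, features=%s): %d cores, %.1f%% correct, %.1f%% not diagnostic\n",
              object@approach, object@featureSet, object@overall$n_cores,
              100 * object@overall$correct_fraction,
              100 * object@overall$not_diagnostic_fraction))
})

#' SimilaritySummary: pairwise spectrum similarity within/between groups
#'
#' Normalized dot-product similarities for (a subsample of) all spectrum
#' pairs of one group pair, with empirical CDF and median.
#'
#' @slot groupA,groupB compared ROI labels (equal for intra-ROI).
#' @slot values similarity values in \[0, 1\].
#' @slot nPairs number of pairs evaluated.
#' @slot totalPairs size of the full pair population.
#' @slot median median similarity (the CDF = 0.5 point).
#' @slot featureSet feature set descriptor.
#' @export
setClass("SimilaritySummary", representation(
  groupA = "character", groupB = "character", values = "numeric",
  nPairs = "integer", totalPairs = "numeric", median = "numeric",
  featureSet = "character"))

#' @describeIn SimilaritySummary Empirical CDF of the similarity values.
#' @param x A SimilaritySummary.
#' @export
similarityCDF <- function(x) stats::ecdf(x@values)

#' @describeIn SimilaritySummary Similarity values.
#' @export
similarityValues <- function(x) x@values

setMethod("show", "SimilaritySummary", function(object) {
  cat(sprintf("SimilaritySummary %s vs %s (%s): median %.3f over %d/%g pairs\n",
              object@groupA, object@groupB, object@featureSet,
              object@median, object@nPairs, object@totalPairs))
})
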