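## Shared fixtures, built lazily once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## The study-conditions dataset: 7 ROIs x 2 patients x 3 cores x 50 pixels,
## signature peaks planted at d = 1.5 against every other ROI.
defaultRun <- function() {
  memo("defaultRun", generateDataset(synthConfig()))
}

## Full pipeline (preprocessing + GMM + abundances) on the default dataset.
defaultPipeline <- function() {
  memo("defaultPipeline",
       suppressWarnings(msiPipeline(defaultRun()$dataset, alignBy = "core")))
}

## Zero-effect control: no planted differences, equal heterogeneity.
zeroEffectRun <- function() {
  memo("zeroEffectRun", generateDataset(
    synthConfig(targetD = 0,
                roiHeterogeneity = stats::setNames(rep(1, 7), roiLevels()),
                seed = 11)))
}

zeroEffectPipeline <- function() {
  memo("zeroEffectPipeline",
       suppressWarnings(msiPipeline(zeroEffectRun()$dataset, alignBy = "core")))
}

## High-heterogeneity variant: within-class spread doubled everywhere.
highHetRun <- function() {
  memo("highHetRun", generateDataset(
    synthConfig(roiHeterogeneity = 2 * c(NT = 0.6, FA = 0.8, `PTC-CV` = 1.0,
                                         `PTC-FV` = 1.0, FTC = 1.1, ATC = 1.6,
                                         MTC = 0.9),
                seed = 23)))
}

highHetPipeline <- function() {
  memo("highHetPipeline",
       suppressWarnings(msiPipeline(highHetRun()$dataset, alignBy = "core")))
}

## Cheap abundance-only generation: tiny channel count (spectra are not
## used), no patient effect, many pixels per ROI for effect-size checks.
abundanceOnlyRun <- function(targetD = 1.5, heterogeneity = NULL,
                             pixelsPerROI = 500, seed = 5) {
  key <- paste0("ab_", targetD, "_", pixelsPerROI, "_", seed, "_",
                paste(heterogeneity, collapse = "-"))
  memo(key, {
    het <- if (is.null(heterogeneity))
      c(NT = 0.6, FA = 0.8, `PTC-CV` = 1.0, `PTC-FV` = 1.0, FTC = 1.1,
        ATC = 1.6, MTC = 0.9) else heterogeneity
    generateDataset(synthConfig(
      nPatientsPerROI = 2L, coresPerPatient = 2L,
      pixelsPerCore = as.integer(ceiling(pixelsPerROI / 4)),
      nChannels = 400L, nPeaks = 80L, nDiscriminative = 35L,
      targetD = targetD, patientSd = 0, roiHeterogeneity = het,
      baselineAmp = 0, noiseSd = 0, ticCv = 0, shiftChannelsMax = 0L,
      outlierFraction = 0, seed = seed))
  })
}

## Wrap ground-truth per-pixel peak areas as an AbundanceMatrix so the
## similarity / effect-size machinery can run on noiseless features.
truthAbundance <- function(run) {
  tr <- run$truth
  ds <- run$dataset
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(tr@abundance)),
    rowData = S4Vectors::DataFrame(mz = tr@peakMz),
    colData = SummarizedExperiment::colData(ds))
  new("AbundanceMatrix", se)
}

## Minimal hand-built MSISpectra for unit tests.
tinySpectra <- function(intensity, mz = seq_len(nrow(intensity)) + 999,
                        nCorePixels = ncol(intensity)) {
  n <- ncol(intensity)
  pd <- data.frame(
    pixel_id = sprintf("px%02d", seq_len(n)),
    core_id = sprintf("C%d", ((seq_len(n) - 1) %/% nCorePixels) + 1),
    patient_id = sprintf("P%d", ((seq_len(n) - 1) %/% nCorePixels) + 1),
    roi_label = "UNKNOWN", x = seq_len(n), y = 0L)
  MSISpectra(intensity, mz, pd)
}
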