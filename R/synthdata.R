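#' Simulate a tissue-microarray MSI dataset with known ground truth
#'
#' Generates pixel-level MALDI-type spectra with the hierarchical structure
#' of a multi-patient tissue-microarray study: for each of the seven ROI
#' classes, \code{nPatientsPerROI} patients contribute \code{coresPerPatient}
#' cores of \code{pixelsPerCore} spectra each. Spectra are sums of Gaussian
#' peptide peaks whose areas combine (i) a log-normal base amplitude per
#' peak, (ii) a planted ROI effect on "signature" peaks calibrated so that
#' the between-ROI Cohen's d on peak areas equals \code{targetD}, (iii) a
#' per-(patient, peak) log-normal random effect, and (iv) per-pixel noise
#' whose coefficient of variation is scaled by the per-ROI heterogeneity
#' multiplier. A smooth baseline (sum of wide Gaussians), additive truncated
#' Gaussian noise, a per-pixel TIC factor, aberrant-TIC outlier pixels and a
#' per-core integer channel shift are then applied.
#'
#' The planted effect on a signature peak of ROI r is a multiplicative
#' offset 1 + delta on its mean area in r, with delta solved from the
#' analytic within-class variance of the area model so that the pooled-SD
#' standardized mean difference is \code{targetD} against the noisiest
#' opposing ROI (and therefore at least \code{targetD} against every other
#' ROI); the exact per-pair analytic d values are stored in the ground
#' truth (zero for all non-signature peaks).
#'
#' @param config A \code{\link{synthConfig}} object.
#' @return A list with elements \code{dataset} (\linkS4class{MSISpectra})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
#' @examples
#' res <- generateDataset(synthConfig(nPatientsPerROI = 1, pixelsPerCore = 5,
#'                                    nChannels = 500, nPeaks = 30,
#'                                    nDiscriminative = 7))
#' res$dataset
generateDataset <- function(config) {
  if (!is(config, "SynthConfig")) stop("config must be a SynthConfig")
  validObject(config)
  .withSeed(config@seed, .generateDatasetImpl(config))
}

.generateDatasetImpl <- function(cfg) {
  lv <- roiLevels()
  mz <- seq(cfg@mzRange[1], cfg@mzRange[2], length.out = cfg@nChannels)
  dmz <- mz[2] - mz[1]

  ## --- true peaks: jittered grid keeps peaks resolvable ------------------
  margin <- 0.01 * diff(cfg@mzRange) + 10
  centers <- seq(cfg@mzRange[1] + margin, cfg@mzRange[2] - margin,
                 length.out = cfg@nPeaks)
  gap <- if (cfg@nPeaks > 1) centers[2] - centers[1] else diff(cfg@mzRange)
  peakMz <- centers + stats::runif(cfg@nPeaks, -0.3 * gap, 0.3 * gap)
  peakSigma <- cfg@peakSigmaDa * peakMz / 2000
  baseAmp <- stats::rlnorm(cfg@nPeaks, meanlog = log(400), sdlog = 1.0)

  ## --- signature peaks and analytically planted effect sizes -------------
  sigROI <- rep(NA_character_, cfg@nPeaks)
  if (cfg@nDiscriminative > 0) {
    discIdx <- sort(sample.int(cfg@nPeaks, cfg@nDiscriminative))
    sigROI[discIdx] <- rep_len(lv, cfg@nDiscriminative)
  }
  sp2 <- cfg@patientSd^2
  e1 <- exp(sp2 / 2)
  cvROI <- cfg@pixelCv * cfg@roiHeterogeneity[lv]
  ## relative within-class variance of area = base * P * (1 + eps):
  relVar <- exp(2 * sp2) * (1 + cvROI^2) - exp(sp2)
  names(relVar) <- lv

  mult <- matrix(1, cfg@nPeaks, 7, dimnames = list(NULL, lv))
  pairKeys <- .allPairKeys(lv)
  plantedD <- matrix(0, cfg@nPeaks, length(pairKeys),
                     dimnames = list(NULL, pairKeys))
  if (cfg@targetD > 0 && cfg@nDiscriminative > 0) {
    for (j in which(!is.na(sigROI))) {
      r <- sigROI[j]
      vr <- relVar[r]
      ## calibrate against the noisiest opposing ROI so the planted d is at
      ## least targetD for every pair featuring this signature peak
      vbar <- max(relVar[setdiff(lv, r)])
      d <- cfg@targetD
      ## solve e1 * delta / sqrt((vr (1+delta)^2 + vbar) / 2) = d
      A <- e1^2 - d^2 * vr / 2
      B <- -d^2 * vr
      C <- -d^2 * (vr + vbar) / 2
      delta <- if (A > 0) {
        (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
      } else {
        2 * d * sqrt((vr + vbar) / 2) / e1  # fallback for extreme d
      }
      mult[j, r] <- 1 + delta
      for (s in setdiff(lv, r)) {
        dImpl <- e1 * delta /
          sqrt((relVar[r] * (1 + delta)^2 + relVar[s]) / 2)
        plantedD[j, .pairKey(r, s)] <- if (match(r, lv) < match(s, lv))
          dImpl else -dImpl
      }
    }
  }
  roiAmp <- baseAmp * mult  # nPeaks x 7 mean areas (up to the e1 factor)

  ## --- hierarchy and pixel metadata --------------------------------------
  nPat <- cfg@nPatientsPerROI * 7L
  patients <- sprintf("P%03d", seq_len(nPat))
  patientROI <- rep(lv, each = cfg@nPatientsPerROI)
  meta <- do.call(rbind, lapply(seq_len(nPat), function(i) {
    cores <- sprintf("%s_C%d", patients[i], seq_len(cfg@coresPerPatient))
    data.frame(patient_id = patients[i], roi_label = patientROI[i],
               core_id = rep(cores, each = cfg@pixelsPerCore),
               stringsAsFactors = FALSE)
  }))
  nPix <- nrow(meta)
  meta$pixel_id <- sprintf("%s_px%03d", meta$core_id,
                           stats::ave(seq_len(nPix), meta$core_id,
                                      FUN = seq_along))
  ## raster coordinates: square grid per core, cores tiled along x
  side <- ceiling(sqrt(cfg@pixelsPerCore))
  within <- stats::ave(seq_len(nPix), meta$core_id, FUN = seq_along) - 1L
  coreIdx <- as.integer(factor(meta$core_id, levels = unique(meta$core_id)))
  meta$x <- (coreIdx - 1L) * (side + 2L) + within %% side
  meta$y <- within %/% side

  ## --- true per-pixel peak areas -----------------------------------------
  patEff <- matrix(stats::rlnorm(nPat * cfg@nPeaks, 0, cfg@patientSd),
                   nPat, cfg@nPeaks, dimnames = list(patients, NULL))
  patIdx <- match(meta$patient_id, patients)
  roiIdx <- match(meta$roi_label, lv)
  eps <- matrix(stats::rnorm(nPix * cfg@nPeaks), nPix, cfg@nPeaks)
  cvPix <- cvROI[roiIdx]
  meanArea <- t(roiAmp[, roiIdx, drop = FALSE])  # nPix x nPeaks... see below
  ## roiAmp is nPeaks x 7; index columns by pixel ROI then transpose
  abund <- meanArea * patEff[patIdx, , drop = FALSE] *
    pmax(0, 1 + eps * cvPix)
  rownames(abund) <- meta$pixel_id

  ## --- render spectra -----------------------------------------------------
  K <- matrix(0, cfg@nChannels, cfg@nPeaks)
  for (j in seq_len(cfg@nPeaks)) {
    K[, j] <- stats::dnorm(mz, peakMz[j], peakSigma[j])
  }
  signal <- K %*% t(abund)  # channels x pixels

  ## smooth chemical baseline: wide Gaussians, stronger at low m/z
  if (cfg@baselineAmp > 0) {
    bCenters <- seq(cfg@mzRange[1], cfg@mzRange[2], length.out = 4)
    bSigma <- diff(cfg@mzRange) / 4
    B <- vapply(bCenters, function(c0) exp(-(mz - c0)^2 / (2 * bSigma^2)),
                numeric(cfg@nChannels))
    bShape <- B %*% c(1, 0.6, 0.35, 0.2)
    bW <- cfg@baselineAmp * stats::runif(nPix, 0.8, 1.2)
    signal <- signal + bShape %*% t(bW)
  }

  ## per-core integer channel shift
  cores <- unique(meta$core_id)
  shiftPerCore <- stats::setNames(integer(length(cores)), cores)
  if (cfg@shiftChannelsMax > 0) {
    ## balanced multiset of shifts: drift is centered on the calibrated axis
    vals <- rep(seq(-cfg@shiftChannelsMax, cfg@shiftChannelsMax),
                length.out = length(cores))
    shiftPerCore[] <- sample(vals)
    for (cid in cores[shiftPerCore != 0]) {
      cols <- which(meta$core_id == cid)
      s <- shiftPerCore[cid]
      shifted <- matrix(0, cfg@nChannels, length(cols))
      if (s > 0) {
        shifted[(s + 1):cfg@nChannels, ] <-
          signal[1:(cfg@nChannels - s), cols]
      } else {
        shifted[1:(cfg@nChannels + s), ] <-
          signal[(1 - s):cfg@nChannels, cols]
      }
      signal[, cols] <- shifted
    }
  }

  ## per-pixel TIC factor and injected aberrant-TIC outliers
  ticFac <- if (cfg@ticCv > 0) {
    stats::rlnorm(nPix, 0, sqrt(log(1 + cfg@ticCv^2)))
  } else rep(1, nPix)
  nOut <- floor(cfg@outlierFraction * nPix)
  outlierPixels <- character()
  if (nOut > 0) {
    oIdx <- sample.int(nPix, nOut)
    ticFac[oIdx] <- ticFac[oIdx] * stats::runif(nOut, 6, 12)
    outlierPixels <- meta$pixel_id[oIdx]
  }
  signal <- sweep(signal, 2, ticFac, `*`)

  if (cfg@noiseSd > 0) {
    signal <- signal + matrix(stats::rnorm(length(signal), 0, cfg@noiseSd),
                              nrow(signal), ncol(signal))
  }
  signal <- pmax(signal, 0)

  dataset <- MSISpectra(signal, mz,
                        meta[, c("pixel_id", "core_id", "patient_id",
                                 "roi_label", "x", "y")])
  truth <- new("GroundTruth",
               peakMz = peakMz, peakSigma = peakSigma,
               baseAmplitude = baseAmp, roiAmplitude = roiAmp,
               plantedD = plantedD, signatureROI = sigROI,
               abundance = abund, outlierPixels = outlierPixels,
               shiftPerCore = shiftPerCore, config = cfg)
  list(dataset = dataset, truth = truth)
}
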