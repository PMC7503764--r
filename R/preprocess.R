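#' Unify per-spectrum m/z axes onto a common target axis
#'
#' Linearly interpolates each spectrum onto \code{targetMz}; channels of the
#' target axis outside a source axis are set to 0. Spectra already on the
#' target axis pass through unchanged.
#'
#' @param spectra List of spectra, each a list/data.frame with elements
#'   \code{mz} (monotone increasing) and \code{intensity}.
#' @param targetMz Strictly increasing numeric target axis.
#' @param pixelData Pixel metadata table, one row per spectrum (see
#'   \code{\link{MSISpectra}}).
#' @return An \linkS4class{MSISpectra} on the target axis.
#' @export
unifyMassChannels <- function(spectra, targetMz, pixelData) {
  if (any(diff(targetMz) <= 0)) stop("target axis must be strictly increasing")
  m <- vapply(spectra, function(sp) {
    mzi <- sp$mz
    if (any(diff(mzi) <= 0))
      stop("per-spectrum m/z axis must be strictly increasing")
    y <- stats::approx(mzi, sp$intensity, xout = targetMz,
                       method = "linear", rule = 1)$y
    y[is.na(y)] <- 0
    y
  }, numeric(length(targetMz)))
  MSISpectra(m, targetMz, pixelData)
}

#' Subtract the chemical baseline from every spectrum
#'
#' The baseline is estimated per spectrum as a smoothed rolling minimum: the
#' minimum over a centered window of \code{windowDa} Daltons, smoothed with
#' a moving average of the same width. The estimate is subtracted and the
#' result clipped at zero. The window must be wider than the broadest peak
#' (so the minimum reaches the baseline between peaks) and narrower than the
#' axis span.
#'
#' @param x An \linkS4class{MSISpectra}.
#' @param windowDa Window width in Da (default 50, suited to the tryptic
#'   peptide m/z range).
#' @return The dataset with baseline-subtracted intensities.
#' @export
subtractBaseline <- function(x, windowDa = 50) {
  if (windowDa <= 0) stop("windowDa must be > 0")
  mz <- mzAxis(x)
  dmz <- mz[2] - mz[1]
  if (windowDa >= (max(mz) - min(mz)))
    stop("baseline window (", windowDa, " Da) is wider than the m/z axis span")
  L <- max(3L, as.integer(round(windowDa / dmz)))
  if (L %% 2L == 0L) L <- L + 1L
  m <- intensities(x)
  base <- .rollMean(.rollMin(m, L), L)
  out <- pmax(m - base, 0)
  SummarizedExperiment::assay(x, "intensity") <- out
  md <- metadata(x)
  md$preprocess$baseline_window_da <- windowDa
  metadata(x) <- md
  x
}

#' Flag pixels with outlying total ion current
#'
#' A pixel is flagged iff its TIC falls outside the medcouple-adjusted
#' boxplot fences (skewness-adjusted Tukey fences with exponent
#' coefficients -4 and 3; see \code{\link{medcouple}}), the standard outlier
#' criterion for skewed and heavy-tailed distributions. Flags are OR-ed with
#' any existing flags; flagged pixels are retained in the container but
#' excluded from all downstream model fitting.
#'
#' @param x An \linkS4class{MSISpectra} with at least 10 pixels.
#' @return The dataset with updated \code{tic_outlier} flags; the fences and
#'   flag count are recorded in \code{metadata(x)$preprocess}.
#' @export
flagTICOutliers <- function(x) {
  if (ncol(x) < 10) stop("need at least 10 pixels to estimate TIC fences")
  tic <- ticValues(x)
  f <- .adjustedFences(tic)
  flag <- tic < f["lower"] | tic > f["upper"]
  cd <- colData(x)
  cd$tic_outlier <- cd$tic_outlier | flag
  colData(x) <- cd
  md <- metadata(x)
  md$preprocess$tic_fences <- f
  md$preprocess$n_outliers_flagged <- sum(flag)
  metadata(x) <- md
  x
}

#' Align spectra to the reference average spectrum
#'
#' The reference is the channel-wise mean spectrum over non-outlier pixels.
#' For each spectrum (or each core's mean spectrum, with
#' \code{by = "core"}), the integer channel shift within \code{\%+-\%
#' shiftMax} maximizing the FFT cross-correlation with the reference is
#' found and applied; vacated channels are zero-filled. The applied shift is
#' the correction: a spectrum displaced by +3 channels receives shift -3.
#' Ties are resolved toward the smallest absolute shift.
#'
#' @param x An \linkS4class{MSISpectra}.
#' @param shiftMax Maximal absolute shift searched, in channels.
#' @param by \code{"spectrum"} for an independent shift per pixel,
#'   \code{"core"} for one shift per core estimated from the core mean.
#' @return The realigned dataset; applied shifts are stored in
#'   \code{colData(x)$applied_shift} and \code{metadata(x)$preprocess}.
#' @export
alignToReference <- function(x, shiftMax = 10, by = c("spectrum", "core")) {
  by <- match.arg(by)
  n <- nrow(x)
  shiftMax <- as.integer(shiftMax)
  if (shiftMax >= n / 2)
    stop("shiftMax must be smaller than half the number of channels")
  m <- intensities(x)
  keep <- !isTICOutlier(x)
  if (!any(keep)) stop("all pixels are flagged as outliers; no reference")
  ref <- rowMeans(m[, keep, drop = FALSE])
  lags <- seq.int(-shiftMax, shiftMax)
  ## cross-correlation c[a] = sum_m ref[m] * x[m - a] via FFT
  fr <- stats::fft(ref)
  bestLag <- function(X) {
    ## X: channels x k
    FX <- stats::mvfft(X)
    cc <- Re(stats::mvfft(fr * Conj(FX), inverse = TRUE)) / n
    idx <- ifelse(lags >= 0, lags + 1L, n + lags + 1L)
    sc <- cc[idx, , drop = FALSE]
    ## prefer the smallest |lag| on ties
    ord <- order(abs(lags), lags)
    sc <- sc[ord, , drop = FALSE]
    lagOrd <- lags[ord]
    lagOrd[apply(sc, 2, which.max)]
  }
  applyShift <- function(v, s) {
    out <- numeric(length(v))
    if (s == 0) return(v)
    if (s > 0) out[(s + 1):length(v)] <- v[1:(length(v) - s)]
    else out[1:(length(v) + s)] <- v[(1 - s):length(v)]
    out
  }
  ## a global translation of the whole dataset is unidentifiable (the
  ## reference is built from the data); remove the median lag so alignment
  ## never shifts the dataset as a whole
  center <- function(lagVec) lagVec - as.integer(round(stats::median(lagVec)))
  cd <- colData(x)
  if (by == "spectrum") {
    sh <- center(bestLag(m))
    for (i in which(sh != 0)) m[, i] <- applyShift(m[, i], sh[i])
  } else {
    cores <- cd$core_id
    uc <- unique(cores)
    coreMeans <- vapply(uc, function(cid) {
      cols <- which(cores == cid & keep)
      if (!length(cols)) cols <- which(cores == cid)
      rowMeans(m[, cols, drop = FALSE])
    }, numeric(n))
    coreSh <- stats::setNames(center(bestLag(coreMeans)), uc)
    sh <- coreSh[cores]
    for (cid in uc[coreSh != 0]) {
      cols <- which(cores == cid)
      s <- coreSh[cid]
      for (i in cols) m[, i] <- applyShift(m[, i], s)
    }
  }
  SummarizedExperiment::assay(x, "intensity") <- m
  cd$applied_shift <- as.integer(cd$applied_shift + sh)
  colData(x) <- cd
  md <- metadata(x)
  md$preprocess$shift_max <- shiftMax
  md$preprocess$align_by <- by
  md$preprocess$applied_shift <- stats::setNames(as.integer(sh), cd$pixel_id)
  metadata(x) <- md
  x
}

#' Normalize spectra to a common total ion current
#'
#' Scales every spectrum so that its TIC equals the mean pre-normalization
#' TIC of non-outlier pixels (relative channel proportions are unchanged;
#' the choice of the common constant is immaterial after downstream
#' Z-scoring). Pixels with zero TIC are flagged as outliers with a warning
#' and left unscaled.
#'
#' @param x An \linkS4class{MSISpectra}.
#' @return The TIC-normalized dataset.
#' @export
normalizeTIC <- function(x) {
  tic <- ticValues(x)
  keep <- !isTICOutlier(x)
  zero <- tic <= 0
  if (any(zero & keep)) {
    warning(sum(zero & keep), " pixel(s) with zero TIC flagged and skipped")
    cd <- colData(x)
    cd$tic_outlier <- cd$tic_outlier | zero
    colData(x) <- cd
    keep <- !isTICOutlier(x)
  }
  if (!any(keep)) stop("no non-outlier pixel with positive TIC")
  target <- mean(tic[keep])
  fac <- ifelse(tic > 0, target / tic, 1)
  m <- sweep(intensities(x), 2, fac, `*`)
  SummarizedExperiment::assay(x, "intensity") <- m
  md <- metadata(x)
  md$preprocess$tic_target <- target
  md$preprocess$tic_before <- tic
  metadata(x) <- md
  x
}

#' Run the full preprocessing chain
#'
#' Fixed order: baseline subtraction, TIC outlier flagging, FFT alignment to
#' the reference average spectrum, TIC normalization (mass-channel
#' unification is assumed done at import; see
#' \code{\link{unifyMassChannels}}). The chain is idempotent on its own
#' output up to floating point: a second pass estimates near-zero baseline,
#' flags nothing new and applies zero shifts.
#'
#' @param x An \linkS4class{MSISpectra}.
#' @param baselineWindow Baseline window in Da.
#' @param shiftMax Alignment search window in channels.
#' @param alignBy "spectrum" or "core".
#' @return The preprocessed dataset; \code{preprocessReport(x)} summarizes
#'   what was done.
#' @export
preprocess <- function(x, baselineWindow = 50, shiftMax = 10,
                       alignBy = "spectrum") {
  x <- subtractBaseline(x, baselineWindow)
  x <- flagTICOutliers(x)
  x <- alignToReference(x, shiftMax, by = alignBy)
  x <- normalizeTIC(x)
  md <- metadata(x)
  md$preprocess$tic_after <- ticValues(x)
  metadata(x) <- md
  x
}

#' @rdname preprocess
#' @export
preprocessReport <- function(x) metadata(x)$preprocess
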