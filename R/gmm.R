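#' Average spectrum over non-outlier pixels
#'
#' @param x An \linkS4class{MSISpectra}.
#' @return Numeric vector, channel-wise arithmetic mean intensity.
#' @export
averageSpectrum <- function(x) {
  keep <- !isTICOutlier(x)
  if (!any(keep)) stop("all pixels are flagged as outliers")
  rowMeans(intensities(x)[, keep, drop = FALSE])
}

## Weighted EM for a 1-D Gaussian mixture where the "sample" is a spectrum:
## channel positions x weighted by intensities w, treated as pseudo-counts
## (TIC normalization upstream standardizes their scale).
.emSegment <- function(x, w, G, sigmaFloor, tol, maxIter) {
  W <- sum(w)
  ## initialize means at weighted quantiles, common sigma from spread
  cw <- cumsum(w) / W
  probs <- (seq_len(G) - 0.5) / G
  mu <- x[pmax(1L, findInterval(probs, cw) + 1L)]
  mu <- pmin(pmax(mu, min(x)), max(x))
  xbar <- sum(w * x) / W
  s0 <- sqrt(sum(w * (x - xbar)^2) / W)
  sigma <- rep(max(s0 / G, sigmaFloor), G)
  pi_ <- rep(1 / G, G)
  ll0 <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(G), function(g)
      pi_[g] * stats::dnorm(x, mu[g], sigma[g]), numeric(length(x)))
    if (!is.matrix(dens)) dens <- matrix(dens, nrow = length(x))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    r <- dens / tot
    wr <- r * w
    ng <- colSums(wr)
    dead <- ng <= 1e-10 * W
    pi_ <- ng / W
    for (g in seq_len(G)) {
      if (dead[g]) next
      mu[g] <- sum(wr[, g] * x) / ng[g]
      sigma[g] <- sqrt(sum(wr[, g] * (x - mu[g])^2) / ng[g])
      if (!is.finite(sigma[g]) || sigma[g] < sigmaFloor) sigma[g] <- sigmaFloor
    }
    if (is.finite(ll0) && abs(ll - ll0) < tol * (abs(ll0) + 1)) {
      converged <- TRUE
      break
    }
    ll0 <- ll
  }
  keep <- pi_ > 1e-8
  list(pi = pi_[keep], mu = mu[keep], sigma = sigma[keep],
       loglik = ll, G = sum(keep), converged = converged)
}

#' Fit a Gaussian mixture model to the average spectrum
#'
#' The spectrum is split at near-zero valleys into independent segments;
#' within each segment, expectation-maximization fits a Gaussian mixture to
#' the spectrum treated as an unnormalized density (channels weighted by
#' intensity). The number of components per segment is chosen by a Bayesian
#' information criterion sweep up to \code{maxComponentsPerSegment}, with
#' the effective sample size taken as the segment's total intensity mass.
#' Each fitted Gaussian is one raw spectral component.
#'
#' @param avg Non-negative average spectrum (one value per channel).
#' @param mz The m/z axis.
#' @param maxComponentsPerSegment BIC sweep upper bound per segment.
#' @param emTol Relative log-likelihood convergence tolerance.
#' @param maxIter Maximal EM iterations per fit.
#' @param valleyFrac Channels below \code{valleyFrac * max(avg)} delimit
#'   segments.
#' @param maxSegLen Segments longer than this many channels are split
#'   recursively at their lowest internal valley before fitting, keeping
#'   the per-segment mixture small and the BIC sweep tractable.
#' @param reconTol Warn if the model's integrated absolute reconstruction
#'   error exceeds this fraction of total intensity.
#' @return data.frame of raw components: mu, sigma, amplitude (height),
#'   area, segment.
#' @export
fitSpectrumGMM <- function(avg, mz, maxComponentsPerSegment = 8L,
                           emTol = 1e-6, maxIter = 200L,
                           valleyFrac = 0.005, maxSegLen = 80L,
                           reconTol = 0.05) {
  if (length(avg) != length(mz)) stop("avg and mz lengths differ")
  if (any(avg < 0)) stop("average spectrum must be non-negative")
  if (all(avg == 0)) stop("average spectrum is all zero")
  dmz <- mz[2] - mz[1]
  thr <- valleyFrac * max(avg)
  above <- avg > thr
  ## runs of above-threshold channels are candidate segments
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values & r$lengths >= 3L)
  out <- list()
  segId <- 0L
  sigmaFloor <- 0.8 * dmz  # narrower than a channel is unidentifiable
  ## extend each segment a few channels into the valleys so peak tails are
  ## not truncated, never crossing half-way to a neighboring segment
  margin <- 4L
  segStart <- starts[segs]
  segEnd <- ends[segs]
  nseg <- length(segs)
  ## recursive valley split of over-long intervals; a cut is only accepted
  ## at a genuine internal valley (clearly below both flanking maxima), so
  ## a single wide peak is never sliced through its flank
  splitLong <- function(i0, i1) {
    if (i1 - i0 + 1L <= maxSegLen) return(list(c(i0, i1)))
    w <- max(3L, as.integer(ceiling((i1 - i0 + 1L) * 0.1)))
    inner <- (i0 + w):(i1 - w)
    cut <- inner[which.min(avg[inner])]
    if (avg[cut] > 0.5 * min(max(avg[i0:cut]), max(avg[(cut + 1L):i1])))
      return(list(c(i0, i1)))
    c(splitLong(i0, cut), splitLong(cut + 1L, i1))
  }
  intervals <- list()
  for (si in seq_len(nseg)) {
    s <- segs[si]
    gapL <- if (si == 1L) segStart[si] - 1L
    else segStart[si] - segEnd[si - 1L] - 1L
    gapR <- if (si == nseg) length(mz) - segEnd[si]
    else segStart[si + 1L] - segEnd[si] - 1L
    i0 <- max(1L, starts[s] - min(margin, gapL %/% 2L + gapL %% 2L))
    i1 <- min(length(mz), ends[s] + min(margin, gapR %/% 2L))
    intervals <- c(intervals, splitLong(i0, i1))
  }
  for (iv in intervals) {
    xs <- mz[iv[1]:iv[2]]
    ws <- avg[iv[1]:iv[2]]
    Wmass <- sum(ws)
    if (Wmass <= 0) next
    segId <- segId + 1L
    best <- NULL
    bestBIC <- Inf
    rises <- 0L
    anyConv <- FALSE
    for (G in seq_len(min(maxComponentsPerSegment,
                          max(1L, floor(length(xs) / 3))))) {
      fit <- .emSegment(xs, ws, G, sigmaFloor, emTol, maxIter)
      anyConv <- anyConv || fit$converged
      bic <- -2 * fit$loglik + (3 * fit$G - 1) * log(Wmass)
      if (bic < bestBIC) {
        bestBIC <- bic
        best <- fit
        rises <- 0L
      } else {
        rises <- rises + 1L
        if (rises >= 2L) break
      }
    }
    if (!anyConv)
      warning("EM did not fully converge in segment ", segId,
              "; keeping best model found")
    area <- best$pi * Wmass * dmz
    out[[segId]] <- data.frame(
      mu = best$mu, sigma = best$sigma,
      amplitude = area / (best$sigma * sqrt(2 * pi)),
      area = area, segment = segId)
  }
  if (!length(out)) stop("no segments above the valley threshold")
  raw <- do.call(rbind, out)
  raw <- raw[order(raw$mu), , drop = FALSE]
  rownames(raw) <- NULL
  ## reconstruction quality of the mixture
  recon <- numeric(length(mz))
  for (i in seq_len(nrow(raw))) {
    recon <- recon + raw$area[i] * stats::dnorm(mz, raw$mu[i], raw$sigma[i])
  }
  relErr <- sum(abs(recon - avg)) / sum(avg)
  attr(raw, "reconstruction_error") <- relErr
  if (relErr > reconTol)
    warning(sprintf("GMM reconstruction error %.1f%% exceeds %.1f%%",
                    100 * relErr, 100 * reconTol))
  raw
}

#' Prune low-amplitude and overly broad components
#'
#' Removes raw components whose amplitude falls below the
#' \code{ampQuantile} quantile of amplitudes, or whose width exceeds
#' \code{sigmaMaxDa} (broad Gaussians model baseline remnants, not peptide
#' peaks).
#'
#' @param raw data.frame from \code{\link{fitSpectrumGMM}}.
#' @param ampQuantile Quantile of the amplitude distribution below which
#'   components are dropped (0 keeps all).
#' @param sigmaMaxDa Maximal allowed sigma in Da (Inf keeps all).
#' @return The surviving components (same columns).
#' @export
pruneComponents <- function(raw, ampQuantile = 0.05, sigmaMaxDa = 10) {
  if (ampQuantile < 0 || ampQuantile >= 1) stop("ampQuantile must be in [0, 1)")
  ampThr <- if (ampQuantile > 0)
    stats::quantile(raw$amplitude, ampQuantile, names = FALSE) else -Inf
  keep <- raw$amplitude >= ampThr & raw$sigma <= sigmaMaxDa
  if (!any(keep)) stop("pruning removed all components")
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge components modeling the same spectral peak
#'
#' Components closer in location than \code{mergeFactor} times the larger of
#' their widths are grouped by transitive closure; each group becomes one
#' final component located at its dominant (highest-amplitude) member's m/z,
#' and downstream abundance of a merged component is the sum over members.
#'
#' @param components Pruned raw components, sorted by mu.
#' @param mergeFactor Threshold multiplier on max(sigma_i, sigma_j).
#' @param mz The m/z axis the model was fitted on (stored for downstream
#'   axis checks).
#' @return A \linkS4class{ComponentModel}.
#' @export
mergeComponents <- function(components, mergeFactor = 1.0, mz = numeric()) {
  cmp <- components[order(components$mu), , drop = FALSE]
  n <- nrow(cmp)
  if (n == 0) stop("no components to merge")
  ## transitive closure of |mu_i - mu_j| < mergeFactor * max(sigma_i, sigma_j);
  ## on a sorted axis the closure groups are contiguous index intervals
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  maxSig <- max(cmp$sigma)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gap <- cmp$mu[j] - cmp$mu[i]
        if (gap >= mergeFactor * maxSig) break
        if (gap < mergeFactor * max(cmp$sigma[i], cmp$sigma[j])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ## groups become contiguous intervals: merge any interval overlaps so the
  ## final components stay strictly ordered in m/z
  span <- do.call(rbind, lapply(split(seq_len(n), roots), range))
  span <- span[order(span[, 1]), , drop = FALSE]
  group <- integer(n)
  g <- 0L
  hi <- -1L
  for (r in seq_len(nrow(span))) {
    if (span[r, 1] > hi) {
      g <- g + 1L
      hi <- span[r, 2]
    } else {
      hi <- max(hi, span[r, 2])
    }
    group[span[r, 1]:span[r, 2]] <- g
  }
  cmp$group <- group
  agg <- lapply(split(seq_len(n), group), function(ii) {
    dom <- ii[which.max(cmp$amplitude[ii])]
    data.frame(mu = cmp$mu[dom], sigma = cmp$sigma[dom],
               amplitude = sum(cmp$amplitude[ii]),
               area = sum(cmp$area[ii]), n_members = length(ii))
  })
  final <- do.call(rbind, agg)
  rownames(final) <- NULL
  new("ComponentModel", components = final,
      members = cmp[, c("mu", "sigma", "amplitude", "area", "group")],
      mzAxis = as.numeric(mz))
}

#' Estimate per-pixel component abundances by convolution
#'
#' The abundance of component k in pixel p is the inner product of the
#' pixel's spectrum with the component's unit-area Gaussian profile,
#' \eqn{\sum_m s_p(m) g_k(m) \Delta m}, so abundances live on a peak-area
#' scale. Members of a merged component contribute the sum of their
#' integrals.
#'
#' @param x A preprocessed \linkS4class{MSISpectra}.
#' @param model A \linkS4class{ComponentModel} fitted on the same m/z axis.
#' @return An \linkS4class{AbundanceMatrix} (components x pixels).
#' @export
estimateAbundances <- function(x, model) {
  mz <- mzAxis(x)
  if (length(model@mzAxis) &&
      (length(model@mzAxis) != length(mz) ||
       max(abs(model@mzAxis - mz)) > 1e-8))
    stop("dataset and component model are on different m/z axes")
  dmz <- mz[2] - mz[1]
  mem <- model@members
  G <- vapply(seq_len(nrow(mem)), function(i)
    stats::dnorm(mz, mem$mu[i], mem$sigma[i]) * dmz, numeric(length(mz)))
  Amem <- crossprod(intensities(x), G)  # pixels x members
  ## sum member integrals within each merged group
  grp <- factor(mem$group, levels = seq_len(nComponents(model)))
  M <- stats::model.matrix(~ 0 + grp)
  A <- Amem %*% M  # pixels x components
  A[A < 0] <- 0
  cmp <- model@components
  se <- SummarizedExperiment(
    assays = list(abundance = t(A)),
    rowData = DataFrame(mz = cmp$mu, sigma = cmp$sigma,
                        n_members = cmp$n_members),
    colData = colData(x))
  new("AbundanceMatrix", se)
}

#' Stratify components into intensity classes
#'
#' Fits a one-dimensional Gaussian mixture (EM via \pkg{mclust}, unequal
#' variances) to the log10 mean component abundances over non-outlier
#' pixels, and places class thresholds at the posterior-equality crossings
#' between adjacent (mean-ordered) mixture components. The top class
#' contains the most abundant molecular species and can serve as a reduced
#' feature set.
#'
#' @param abund An \linkS4class{AbundanceMatrix}.
#' @param nClasses Number of classes (default 5).
#' @return An \linkS4class{IntensityClassModel}. Assign the classes into
#'   the matrix with \code{\link{applyIntensityClasses}}.
#' @export
fitIntensityClasses <- function(abund, nClasses = 5L) {
  if (nrow(abund) < nClasses)
    stop("need at least nClasses components")
  keep <- !colData(abund)$tic_outlier
  mAb <- rowMeans(abundances(abund)[, keep, drop = FALSE])
  y <- log10(pmax(mAb, .Machine$double.eps))
  G <- as.integer(nClasses)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  fit <- NULL
  while (G >= 1L) {
    fit <- tryCatch(
      mclust::Mclust(y, G = G, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && fit$G == G &&
        all(is.finite(fit$parameters$variance$sigmasq))) break
    warning("degenerate ", G, "-class mixture; reducing the class count")
    G <- G - 1L
    fit <- NULL
  }
  if (is.null(fit)) stop("could not fit any intensity-class mixture")
  par <- fit$parameters
  ord <- order(par$mean)
  mu <- par$mean[ord]
  sig <- sqrt(par$variance$sigmasq)
  if (length(sig) == 1L) sig <- rep(sig, G)
  sig <- sig[ord]
  pro <- par$pro[ord]
  thr <- numeric(0)
  if (G > 1L) {
    thr <- vapply(seq_len(G - 1L), function(k) {
      grid <- seq(mu[k], mu[k + 1], length.out = 2001)
      dk <- pro[k] * stats::dnorm(grid, mu[k], sig[k])
      dk1 <- pro[k + 1] * stats::dnorm(grid, mu[k + 1], sig[k + 1])
      cross <- which(dk1 >= dk)
      if (length(cross)) grid[cross[1]] else mean(mu[k:(k + 1)])
    }, numeric(1))
    ## enforce strict ascent in pathological overlaps
    thr <- cummax(thr + seq_along(thr) * 1e-12)
  }
  classes <- as.integer(findInterval(y, thr) + 1L)
  obj <- new("IntensityClassModel",
             thresholds = 10^thr, classes = classes, nClasses = G,
             mixture = list(mean = mu, sigma = sig, pro = pro,
                            log_thresholds = thr))
  validObject(obj)
  obj
}

#' @rdname fitIntensityClasses
#' @param icm An IntensityClassModel fitted on \code{abund}.
#' @export
applyIntensityClasses <- function(abund, icm) {
  if (length(icm@classes) != nrow(abund))
    stop("class model does not match the abundance matrix")
  rd <- rowData(abund)
  rd$intensity_class <- icm@classes
  rowData(abund) <- rd
  abund
}
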