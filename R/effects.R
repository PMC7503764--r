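#' Cohen's d standardized effect size
#'
#' The difference between sample means divided by the pooled standard
#' deviation \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2)/(n_a+n_b-2)}}.
#' Unlike a t statistic, d does not grow with sample size, which makes it
#' suited to screening differences across very large spectrum collections.
#' Absolute values of at least 0.5, 0.8 and 1.2 are categorized as medium,
#' large and very large effects (below 0.5 is small).
#'
#' @param a,b Numeric samples of size >= 2 each.
#' @return Signed d (positive when mean(a) > mean(b)).
#' @export
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5))  # -2
cohensD <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 values per sample")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("Cohen's d is undefined: pooled standard deviation is 0")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' @rdname cohensD
#' @param d Numeric vector of (signed) effect sizes.
#' @return \code{effectCategory}: factor with levels small, medium, large,
#'   very large; thresholds 0.5/0.8/1.2 on |d|, boundary values entering the
#'   higher class.
#' @export
effectCategory <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.5, 0.8, 1.2, Inf),
      labels = c("small", "medium", "large", "very large"),
      right = FALSE)
}

#' Effect-size screening of components between ROI pairs
#'
#' For every unordered pair of ROI classes present, computes the signed
#' Cohen's d of each component's abundance (pooling all non-outlier pixels
#' per ROI) and the percentage of components per effect category,
#' per feature set.
#'
#' @param abund An \linkS4class{AbundanceMatrix}.
#' @param features \code{"all"}, \code{"top"} or index vector (see
#'   \code{\link{groupSimilarity}}).
#' @param icm Optional \linkS4class{IntensityClassModel} for
#'   \code{features = "top"}.
#' @return List with \code{records} (data.frame: component, mz, pair, d,
#'   category) and \code{summary} (data.frame of per-pair category
#'   percentages, summing to 100 within each pair).
#' @export
effectTable <- function(abund, features = "all", icm = NULL) {
  featIdx <- .resolveFeatures(abund, features, icm)
  keep <- !colData(abund)$tic_outlier
  roi <- colData(abund)$roi_label
  present <- intersect(roiLevels(), unique(roi[keep]))
  if (length(present) < 2) stop("need at least 2 ROI classes")
  X <- abundances(abund)[featIdx, , drop = FALSE]
  mzs <- rowData(abund)$mz[featIdx]
  stats_ <- lapply(present, function(r) {
    cols <- which(keep & roi == r)
    xs <- X[, cols, drop = FALSE]
    n <- length(cols)
    m <- rowMeans(xs)
    v <- (rowSums(xs^2) - n * m^2) / (n - 1)
    list(n = n, m = m, v = v)
  })
  names(stats_) <- present
  cmb <- utils::combn(present, 2)
  rec <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- stats_[[cmb[1, k]]]
    b <- stats_[[cmb[2, k]]]
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / (a$n + b$n - 2)
    d <- ifelse(sp2 > 0, (a$m - b$m) / sqrt(sp2), NA_real_)
    data.frame(component = featIdx, mz = mzs,
               pair = .pairKey(cmb[1, k], cmb[2, k]),
               d = d, category = effectCategory(d),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  tab <- table(records$pair, records$category)
  summary <- as.data.frame(100 * prop.table(tab, 1))
  names(summary) <- c("pair", "category", "percent")
  list(records = records, summary = summary)
}

#' Pseudo-logarithmic principal component embedding
#'
#' Scales abundances with the pseudo-logarithm \eqn{\log_{10}(x + 1)}
#' (accommodating the wide dynamic range without dropping covariance
#' information), centers per feature, and computes a singular value
#' decomposition PCA. Optionally subsamples a fixed number of pixels per
#' core first, as used for visual overviews of class separability.
#'
#' @param abund An \linkS4class{AbundanceMatrix} (non-negative).
#' @param nComponents Number of principal components to return.
#' @param perCoreSample If not NULL, randomly keep this many pixels per core.
#' @param seed Seed for the per-core subsample.
#' @return List: \code{scores} (pixels x nComponents), \code{varFrac}
#'   (explained-variance fractions), \code{pixels} (pixel ids used).
#' @export
pcaEmbed <- function(abund, nComponents = 3L, perCoreSample = NULL,
                     seed = NULL) {
  keep <- which(!colData(abund)$tic_outlier)
  if (!is.null(perCoreSample)) {
    cores <- colData(abund)$core_id[keep]
    keep <- .withSeed(seed, {
      unlist(lapply(split(keep, cores), function(ii) {
        if (length(ii) <= perCoreSample) ii
        else sort(sample(ii, perCoreSample))
      }), use.names = FALSE)
    })
  }
  if (length(keep) < nComponents)
    stop("fewer pixels than requested components")
  Y <- log10(t(abundances(abund)[, keep, drop = FALSE]) + 1)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$x))
  list(scores = pc$x[, seq_len(nc), drop = FALSE],
       varFrac = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nc)],
       pixels = colData(abund)$pixel_id[keep])
}
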