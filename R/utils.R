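#' Canonical tissue class (ROI) labels
#'
#' The seven region-of-interest labels used throughout the package, in the
#' canonical order used for deterministic tie-breaking: normal thyroid (NT),
#' follicular adenoma (FA), classical and follicular-variant papillary
#' carcinoma (PTC-CV, PTC-FV), follicular carcinoma (FTC), anaplastic
#' carcinoma (ATC) and medullary carcinoma (MTC).
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' roiLevels()
roiLevels <- function() {
  c("NT", "FA", "PTC-CV", "PTC-FV", "FTC", "ATC", "MTC")
}

.NOT_CLASSIFIED <- "NOT_CLASSIFIED"
.NOT_DIAGNOSTIC <- "NOT_DIAGNOSTIC"

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. seed = NULL uses the
## current stream untouched.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a child seed from a master seed; stays below .Machine$integer.max.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 100000L) * 20011 + offset * 7919 + 1) %% 2147483629L
}

## Forward running minimum over rows: out[i, ] = min(m[i:(i+L-1), ]),
## truncated at the bottom edge. Doubling trick keeps it O(n log L).
.runMinForward <- function(m, L) {
  n <- nrow(m)
  g <- m
  span <- 1L
  while (span < L) {
    step <- min(span, L - span)
    if (step >= n) break
    shifted <- g[c((step + 1L):n, rep.int(n, step)), , drop = FALSE]
    ## rows sliding past the end must not wrap: pad with +Inf
    shifted[(n - step + 1L):n, ] <- Inf
    g <- pmin(g, shifted)
    span <- span + step
  }
  g
}

## Centered rolling minimum over a window of L rows (edges truncated).
.rollMin <- function(m, L) {
  h <- (L - 1L) %/% 2L
  f <- .runMinForward(m, L)
  f[pmax(1L, seq_len(nrow(m)) - h), , drop = FALSE]
}

## Centered rolling mean over L rows with exact truncated edge windows.
.rollMean <- function(m, L) {
  n <- nrow(m)
  h <- (L - 1L) %/% 2L
  cs <- apply(m, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / (hi - lo)
}

#' Medcouple, a robust measure of distribution skewness
#'
#' Computes the medcouple MC of a sample: the median of the kernel
#' h(x_i, x_j) = ((x_j - med) - (med - x_i)) / (x_j - x_i) over all pairs
#' with x_i <= med <= x_j, with the standard sign kernel for ties at the
#' median. MC is 0 for symmetric samples and approaches +1 (-1) for strong
#' right (left) skewness. Used to adjust boxplot fences for skewed,
#' heavy-tailed total-ion-current distributions.
#'
#' @param x Numeric vector; non-finite values are dropped.
#' @return Scalar in \[-1, 1\].
#' @references Brys, Hubert and Struyf (2004) J Comput Graph Stat 13:996-1017.
#' @export
#' @examples
#' medcouple(rexp(100))   # right-skewed, positive
medcouple <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 3) return(0)
  med <- stats::median(x)
  z <- x - med
  zp <- z[z >= 0]  # ascending, zeros first
  zm <- z[z <= 0]  # ascending, zeros last
  p <- length(zp)
  q <- length(zm)
  h <- outer(zp, zm, function(a, b) (a + b) / (a - b))
  k <- sum(z == 0)
  if (k > 0) {
    ## tie kernel: antisymmetric sign matrix over the zero block
    rp <- matrix(1, k, k) - diag(k)
    rp <- rp - 2 * (upper.tri(rp) * rp)
    rp <- rp[, k:1, drop = FALSE]
    h[seq_len(k), (q - k + 1L):q] <- rp
  }
  stats::median(h)
}

## Skewness-adjusted (medcouple) boxplot fences of Hubert & Vandervieren:
## exponent coefficients (-4, 3) for MC >= 0 and (-3, 4) for MC < 0.
.adjustedFences <- function(x) {
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  mc <- medcouple(x)
  if (mc >= 0) {
    c(lower = qs[1] - 1.5 * exp(-4 * mc) * iqr,
      upper = qs[2] + 1.5 * exp(3 * mc) * iqr,
      mc = mc)
  } else {
    c(lower = qs[1] - 1.5 * exp(-3 * mc) * iqr,
      upper = qs[2] + 1.5 * exp(4 * mc) * iqr,
      mc = mc)
  }
}

## Unordered ROI pair key, canonical order first.
.pairKey <- function(a, b) {
  lv <- roiLevels()
  ia <- match(a, lv)
  ib <- match(b, lv)
  paste(ifelse(ia <= ib, a, b), ifelse(ia <= ib, b, a), sep = "|")
}

.allPairKeys <- function(levels = roiLevels()) {
  cmb <- utils::combn(levels, 2)
  paste(cmb[1, ], cmb[2, ], sep = "|")
}
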