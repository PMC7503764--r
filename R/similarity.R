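#' Normalized dot-product similarity of two spectra
#'
#' The pairwise similarity index \eqn{\langle a,b\rangle / (\|a\| \|b\|)}:
#' 1 for identically oriented abundance vectors, 0 for disjoint (orthogonal)
#' ones; symmetric and invariant to positive rescaling of either argument.
#' (The spectral contrast angle is its arccosine; both orderings are
#' equivalent.)
#'
#' @param a,b Numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return Scalar in \[0, 1\] for nonnegative inputs.
#' @export
#' @examples
#' similarityIndex(c(1, 2, 2), c(2, 1, 2))  # 8/9
similarityIndex <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("similarity index is undefined for an all-zero spectrum")
  sum(a * b) / (na * nb)
}

## Uniform subsample of distinct pairs; intra-group pairs are unordered
## (i < j), inter-group pairs cross the two index sets.
.samplePairs <- function(nA, nB, intra, maxPairs) {
  total <- if (intra) nA * (nA - 1) / 2 else as.numeric(nA) * nB
  if (total <= maxPairs) {
    if (intra) {
      idx <- utils::combn(nA, 2)
      return(list(i = idx[1, ], j = idx[2, ], total = total))
    }
    g <- expand.grid(i = seq_len(nA), j = seq_len(nB))
    return(list(i = g$i, j = g$j, total = total))
  }
  ## rejection sampling of distinct pairs
  pick <- function(m) {
    i <- sample.int(nA, m, replace = TRUE)
    j <- if (intra) sample.int(nA, m, replace = TRUE)
    else sample.int(nB, m, replace = TRUE)
    if (intra) {
      sw <- i > j
      tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
      ok <- i < j
      i <- i[ok]; j <- j[ok]
    }
    cbind(i, j)
  }
  acc <- unique(pick(ceiling(1.3 * maxPairs)))
  while (nrow(acc) < maxPairs) {
    acc <- unique(rbind(acc, pick(maxPairs)))
  }
  acc <- acc[seq_len(maxPairs), , drop = FALSE]
  list(i = acc[, 1], j = acc[, 2], total = total)
}

#' Intra- or inter-group spectrum similarity distribution
#'
#' Computes the similarity index over all pairs of spectra between two
#' pixel groups (or all unordered distinct pairs within one group), or a
#' seeded uniform subsample of \code{maxPairs} pairs when the pair
#' population is larger. Outlier-flagged pixels are excluded. The feature
#' set can be all components or the top intensity class, mirroring
#' full-profile versus most-abundant-component analyses.
#'
#' @param abund An \linkS4class{AbundanceMatrix}.
#' @param groupA,groupB ROI labels; equal labels give the intra-ROI
#'   distribution.
#' @param features \code{"all"}, \code{"top"} (requires \code{icm}), or an
#'   integer vector of component indices.
#' @param icm \linkS4class{IntensityClassModel}, needed for
#'   \code{features = "top"}.
#' @param maxPairs Pair budget before subsampling kicks in.
#' @param seed Seed for the pair subsample (ignored when exhaustive).
#' @return A \linkS4class{SimilaritySummary}.
#' @export
groupSimilarity <- function(abund, groupA, groupB = groupA,
                            features = "all", icm = NULL,
                            maxPairs = 1e6, seed = NULL) {
  featIdx <- .resolveFeatures(abund, features, icm)
  keep <- !colData(abund)$tic_outlier
  roi <- colData(abund)$roi_label
  ia <- which(keep & roi == groupA)
  ib <- which(keep & roi == groupB)
  if (!length(ia)) stop("no pixels in group ", groupA)
  if (!length(ib)) stop("no pixels in group ", groupB)
  intra <- identical(groupA, groupB)
  X <- abundances(abund)[featIdx, , drop = FALSE]
  prs <- .withSeed(seed, .samplePairs(length(ia), length(ib), intra, maxPairs))
  ## normalize the needed columns once, then block-wise dot products
  cols <- sort(unique(c(ia, ib)))
  Xn <- X[, cols, drop = FALSE]
  nrm <- sqrt(colSums(Xn^2))
  if (any(nrm == 0))
    stop("all-zero abundance vector in group ", groupA, "/", groupB)
  Xn <- sweep(Xn, 2, nrm, `/`)
  ci <- match(ia[prs$i], cols)
  cj <- match(ib[prs$j], cols)
  np <- length(ci)
  vals <- numeric(np)
  bs <- 100000L
  for (b in seq.int(1L, np, by = bs)) {
    e <- min(np, b + bs - 1L)
    vals[b:e] <- colSums(Xn[, ci[b:e], drop = FALSE] *
                           Xn[, cj[b:e], drop = FALSE])
  }
  new("SimilaritySummary",
      groupA = groupA, groupB = groupB, values = vals,
      nPairs = np, totalPairs = prs$total,
      median = stats::median(vals),
      featureSet = if (is.character(features)) features else "custom")
}

## shared feature-set resolver ("all" | "top" | integer indices)
.resolveFeatures <- function(abund, features, icm = NULL) {
  if (is.numeric(features)) return(as.integer(features))
  if (identical(features, "all")) return(seq_len(nrow(abund)))
  if (identical(features, "top")) {
    if (is.null(icm)) {
      cls <- rowData(abund)$intensity_class
      if (is.null(cls))
        stop("features = 'top' needs an IntensityClassModel (icm) or ",
             "intensity classes applied to the matrix")
      return(which(cls == max(cls)))
    }
    return(topClassComponents(icm))
  }
  stop("features must be 'all', 'top' or an index vector")
}
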