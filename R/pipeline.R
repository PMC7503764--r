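#' Run preprocessing and component quantification end to end
#'
#' Convenience wrapper chaining \code{\link{preprocess}},
#' \code{\link{averageSpectrum}}, \code{\link{fitSpectrumGMM}},
#' \code{\link{pruneComponents}}, \code{\link{mergeComponents}} and
#' \code{\link{estimateAbundances}} with the package defaults.
#'
#' @param dataset An \linkS4class{MSISpectra} (raw).
#' @param baselineWindow,shiftMax,alignBy Preprocessing parameters, see
#'   \code{\link{preprocess}}.
#' @param ampQuantile,sigmaMaxDa Pruning parameters, see
#'   \code{\link{pruneComponents}}.
#' @param mergeFactor Merge threshold, see \code{\link{mergeComponents}}.
#' @param ... Further arguments to \code{\link{fitSpectrumGMM}}.
#' @return List: \code{dataset} (preprocessed), \code{model}
#'   (\linkS4class{ComponentModel}), \code{abundance}
#'   (\linkS4class{AbundanceMatrix}).
#' @export
msiPipeline <- function(dataset, baselineWindow = 50, shiftMax = 10,
                        alignBy = "spectrum", ampQuantile = 0.05,
                        sigmaMaxDa = 10, mergeFactor = 1.0, ...) {
  pp <- preprocess(dataset, baselineWindow = baselineWindow,
                   shiftMax = shiftMax, alignBy = alignBy)
  avg <- averageSpectrum(pp)
  raw <- fitSpectrumGMM(avg, mzAxis(pp), ...)
  pruned <- pruneComponents(raw, ampQuantile = ampQuantile,
                            sigmaMaxDa = sigmaMaxDa)
  model <- mergeComponents(pruned, mergeFactor = mergeFactor, mz = mzAxis(pp))
  abund <- estimateAbundances(pp, model)
  list(dataset = pp, model = model, abundance = abund)
}
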