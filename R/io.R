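#' Write / read an MSI dataset as a plain-text directory container
#'
#' The container holds \code{mz_axis.txt} (one m/z per line),
#' \code{intensities.tsv} (pixels in rows, channels in columns) and
#' \code{pixel_metadata.csv}; an optional ground truth is stored as
#' \code{ground_truth.json}. The round trip is lossless for metadata and
#' lossless to full double precision for intensities.
#'
#' @param dataset An \linkS4class{MSISpectra} object.
#' @param path Directory to create/fill.
#' @param truth Optional \linkS4class{GroundTruth} to store alongside.
#' @return \code{writeDataset}: the path, invisibly. \code{readDataset}: a
#'   list with \code{dataset} and (if present on disk) \code{truth}.
#' @export
writeDataset <- function(dataset, path, truth = NULL) {
  stopifnot(is(dataset, "MSISpectra"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(format(mzAxis(dataset), digits = 17),
             file.path(path, "mz_axis.txt"))
  m <- t(intensities(dataset))
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, paste0("ch", seq_len(ncol(m))))
  data.table::fwrite(dt, file.path(path, "intensities.tsv"), sep = "\t")
  md <- as.data.frame(pixelData(dataset))
  data.table::fwrite(md, file.path(path, "pixel_metadata.csv"))
  if (!is.null(truth)) writeGroundTruth(truth, file.path(path, "ground_truth.json"))
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  need <- c("mz_axis.txt", "intensities.tsv", "pixel_metadata.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("dataset container is missing file: ", file.path(path, f))
  }
  mz <- as.numeric(readLines(file.path(path, "mz_axis.txt")))
  if (anyNA(mz)) stop("corrupt m/z axis in ", file.path(path, "mz_axis.txt"))
  ints <- data.table::fread(file.path(path, "intensities.tsv"))
  md <- data.table::fread(file.path(path, "pixel_metadata.csv"),
                          data.table = FALSE)
  if (nrow(ints) != nrow(md))
    stop("corrupt container: ", nrow(ints), " spectra but ",
         nrow(md), " metadata rows in ", path)
  if (ncol(ints) != length(mz))
    stop("corrupt container: ", ncol(ints), " channels but ",
         length(mz), " m/z values in ", path)
  m <- t(as.matrix(ints))
  ds <- MSISpectra(m, mz, md)
  out <- list(dataset = ds)
  tf <- file.path(path, "ground_truth.json")
  if (file.exists(tf)) out$truth <- readGroundTruth(tf)
  out
}

#' Serialize ground truth to JSON (and back)
#'
#' @param truth A \linkS4class{GroundTruth}.
#' @param file JSON file path.
#' @export
writeGroundTruth <- function(truth, file) {
  cfg <- truth@config
  cfgList <- lapply(methods::slotNames("SynthConfig"),
                    function(s) methods::slot(cfg, s))
  names(cfgList) <- methods::slotNames("SynthConfig")
  cfgList$roiHeterogeneity <- as.list(cfgList$roiHeterogeneity)
  obj <- list(
    peak_mz = truth@peakMz, peak_sigma = truth@peakSigma,
    base_amplitude = truth@baseAmplitude,
    roi_amplitude = truth@roiAmplitude,
    planted_d = truth@plantedD,
    planted_d_pairs = colnames(truth@plantedD),
    signature_roi = truth@signatureROI,
    abundance = truth@abundance,
    pixel_ids = rownames(truth@abundance),
    outlier_pixels = truth@outlierPixels,
    shift_per_core = as.list(truth@shiftPerCore),
    config = cfgList)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  o <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(synthConfig, c(
    o$config[setdiff(names(o$config), "roiHeterogeneity")],
    list(roiHeterogeneity = unlist(o$config$roiHeterogeneity))))
  ab <- as.matrix(o$abundance)
  rownames(ab) <- o$pixel_ids
  pd <- as.matrix(o$planted_d)
  colnames(pd) <- o$planted_d_pairs
  new("GroundTruth",
      peakMz = o$peak_mz, peakSigma = o$peak_sigma,
      baseAmplitude = o$base_amplitude,
      roiAmplitude = as.matrix(o$roi_amplitude),
      plantedD = pd,
      signatureROI = as.character(o$signature_roi),
      abundance = ab,
      outlierPixels = as.character(o$outlier_pixels),
      shiftPerCore = {
        sh <- unlist(o$shift_per_core)
        storage.mode(sh) <- "integer"
        sh
      },
      config = cfg)
}

#' Read a peptide identification list
#'
#' Reads a CSV of identified tryptic peptides with columns \code{mass}
#' (the measured mass on the scale compared to MSI component m/z, i.e.
#' singly-protonated \[M+H\]+ values for MALDI spectra), \code{sequence},
#' \code{protein} and optionally \code{source} (tissue class of the
#' lysate).
#'
#' @param file CSV path.
#' @return data.frame with those columns.
#' @export
readPeptideList <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  pep <- data.table::fread(file, data.table = FALSE)
  need <- c("mass", "sequence", "protein")
  miss <- setdiff(need, names(pep))
  if (length(miss))
    stop("peptide list is missing column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(pep)) pep$source <- NA_character_
  if (any(pep$mass <= 0)) stop("peptide masses must be > 0")
  if (any(!nzchar(pep$sequence))) stop("empty peptide sequence in list")
  pep
}
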