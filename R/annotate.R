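#' Annotate spectral components with identified peptides
#'
#' Attributes putative peptide identities to spectral components by mass
#' matching: a component at m/z m matches every peptide whose measured mass
#' lies within \code{tol * m} of m (default +-0.05\% relative tolerance).
#' Matching is not unique -- several peptides may fall inside one
#' component's window and all are returned, ordered by absolute relative
#' error. Components without any match are listed with NA peptide fields.
#'
#' @param model A \linkS4class{ComponentModel} (or a numeric vector of
#'   component m/z values).
#' @param peptides data.frame from \code{\link{readPeptideList}}: columns
#'   \code{mass}, \code{sequence}, \code{protein}, \code{source}. Masses
#'   must already be on the scale compared to MSI m/z (singly protonated
#'   \[M+H\]+ for MALDI).
#' @param tol Relative mass tolerance (0.0005 = 0.05\%).
#' @return data.frame: component, component_mz, mass, sequence, protein,
#'   source, rel_error; one row per match (or one NA row per unmatched
#'   component).
#' @export
matchComponents <- function(model, peptides, tol = 5e-4) {
  if (tol <= 0) stop("tol must be > 0")
  if (!nrow(peptides)) stop("peptide list is empty")
  mzs <- if (is(model, "ComponentModel")) componentTable(model)$mu
  else as.numeric(model)
  out <- lapply(seq_along(mzs), function(k) {
    m <- mzs[k]
    err <- (peptides$mass - m) / m
    hit <- which(abs(err) <= tol)
    if (!length(hit)) {
      return(data.frame(component = k, component_mz = m,
                        mass = NA_real_, sequence = NA_character_,
                        protein = NA_character_, source = NA_character_,
                        rel_error = NA_real_, stringsAsFactors = FALSE))
    }
    hit <- hit[order(abs(err[hit]))]
    data.frame(component = k, component_mz = m,
               mass = peptides$mass[hit],
               sequence = peptides$sequence[hit],
               protein = peptides$protein[hit],
               source = peptides$source[hit],
               rel_error = err[hit], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
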