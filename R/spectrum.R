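# Deconvoluted spectra: neutral precursor mass, charge, and neutral-mass
# fragment peaks (Xtract-style).  Charge exists only at I/O boundaries.

#' Construct a deconvoluted MS/MS spectrum
#'
#' @param id Text identifier.
#' @param precursor_neutral_mass Neutral precursor monoisotopic mass in Da.
#' @param peaks Data frame (or 2-column matrix) of neutral fragment masses
#'   and non-negative intensities; stored sorted by mass.
#' @param precursor_charge Integer charge state at acquisition (default 8+,
#'   the charge selected for histone-tail ETD).
#' @param retention_time Optional retention time in seconds.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(id, precursor_neutral_mass, peaks,
                     precursor_charge = 8L, retention_time = NA_real_) {
  peaks <- as.data.frame(peaks)
  names(peaks)[1:2] <- c("mass", "intensity")
  stopifnot(precursor_neutral_mass > 0, precursor_charge >= 1)
  if (nrow(peaks) && any(peaks$intensity < 0))
    stop("peak intensities must be >= 0")
  peaks <- peaks[order(peaks$mass), 1:2, drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(id = as.character(id),
                 precursor_neutral_mass = precursor_neutral_mass,
                 precursor_charge = as.integer(precursor_charge),
                 peaks = peaks, retention_time = retention_time),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$id, ": M = ", format(x$precursor_neutral_mass),
      " Da (", x$precursor_charge, "+), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}
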