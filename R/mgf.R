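# MGF dialect for deconvoluted spectra.  A block-level NEUTRAL=1 flag marks
# fragment masses as already-deconvoluted neutral monoisotopic masses (the
# dialect the simulator writes); without it fragment values are read as
# singly protonated m/z.  PEPMASS is always precursor m/z and requires
# CHARGE to recover the neutral mass.

#' Write spectra to an MGF file
#'
#' Deterministic formatting (6 dp masses, LF line endings, stable ordering):
#' identical input yields a byte-identical file.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  emit <- function(...) writeLines(paste0(...), con, sep = "\n")
  emit("# middlemarks MGF dialect; fragment masses are neutral (NEUTRAL=1)")
  for (s in spectra) {
    emit("BEGIN IONS")
    emit("TITLE=", s$id)
    emit("PEPMASS=", sprintf("%.6f", mz(s$precursor_neutral_mass,
                                        s$precursor_charge)))
    emit("CHARGE=", s$precursor_charge, "+")
    emit("NEUTRAL=1")
    if (!is.na(s$retention_time))
      emit("RTINSECONDS=", sprintf("%.3f", s$retention_time))
    if (nrow(s$peaks))
      emit(sprintf("%.6f %.6f", s$peaks$mass, s$peaks$intensity))
    emit("END IONS")
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks, tolerant of blank lines and `#`
#' comments.  `PEPMASS` is interpreted as precursor m/z and converted to a
#' neutral mass using `CHARGE`; `NEUTRAL=1` marks fragment masses as neutral
#' (otherwise they are taken as singly protonated m/z and deprotonated).
#'
#' @param path Input path.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    if (ln != "BEGIN IONS")
      stop("line ", i, ": expected BEGIN IONS, got '", ln, "'")
    hdr <- list(); pk_m <- numeric(); pk_i <- numeric()
    begin_line <- i
    i <- i + 1L
    closed <- FALSE
    while (i <= n) {
      ln <- trimws(lines[i])
      if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
      if (ln == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1L]]
        hdr[[kv[1L]]] <- kv[2L]
      } else {
        parts <- strsplit(ln, "[ \t]+")[[1L]]
        v <- suppressWarnings(as.numeric(parts))
        if (length(v) < 2L || anyNA(v[1:2]))
          stop("line ", i, ": malformed peak line '", ln, "'")
        pk_m <- c(pk_m, v[1L]); pk_i <- c(pk_i, v[2L])
      }
      i <- i + 1L
    }
    if (!closed) stop("line ", begin_line, ": BEGIN IONS without END IONS")
    if (is.null(hdr$PEPMASS))
      stop("line ", begin_line, ": block lacks PEPMASS")
    if (is.null(hdr$CHARGE))
      stop("line ", begin_line, ": PEPMASS is m/z but block lacks CHARGE")
    z <- as.integer(sub("\\+$", "", hdr$CHARGE))
    if (is.na(z) || z < 1L)
      stop("line ", begin_line, ": bad CHARGE '", hdr$CHARGE, "'")
    pmz <- as.numeric(strsplit(hdr$PEPMASS, "[ \t]+")[[1L]][1L])
    if (is.na(pmz)) stop("line ", begin_line, ": bad PEPMASS")
    neutral <- !is.null(hdr$NEUTRAL) && hdr$NEUTRAL == "1"
    if (!neutral && length(pk_m)) pk_m <- pk_m - MASS_PROTON
    rt <- if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS)
          else NA_real_
    out[[length(out) + 1L]] <- spectrum(
      id = hdr$TITLE %||% sprintf("spectrum_%d", length(out) + 1L),
      precursor_neutral_mass = neutral_mass(pmz, z),
      peaks = data.frame(mass = pk_m, intensity = pk_i),
      precursor_charge = z, retention_time = rt)
  }
  out
}

#' Write a data frame as a deterministic TSV
#'
#' Tab-separated, UTF-8, '.' decimal separator, LF line endings, no quoting
#' or row names -- the exchange format of all pipeline tables.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n", dec = ".")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "")
}
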