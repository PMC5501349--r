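# FIRR quantification: split the summed MS/MS ion intensity of a mixed
# spectrum among co-isolated isobaric proteoforms in proportion to their
# site-determining fragment ion intensities, then normalize to relative
# abundances within (tail, channel, sample).

#' Build an isobaric group for intensity splitting
#'
#' @param members List of isobaric `proteoform` objects co-isolated in one
#'   spectrum.
#' @param s The mixed [spectrum()].
#' @param total_intensity Total intensity to distribute; default is the
#'   summed intensity of all spectrum peaks matched by any member's ladder.
#' @param scheme A [label_scheme()].
#' @param fragment_tol Da tolerance for matching class masses to peaks.
#' @return An object of class `isobaric_group`.
#' @export
isobaric_group <- function(members, s, total_intensity = NULL,
                           scheme = label_scheme(), fragment_tol = 0.01) {
  stopifnot(length(members) >= 1L)
  if (is.null(total_intensity)) {
    matched_any <- unique(unlist(lapply(members, function(p) {
      m <- match_fragments(s, ion_ladder(p, scheme), fragment_tol, "da")
      m$peak_mass
    })))
    total_intensity <- sum(s$peaks$intensity[s$peaks$mass %in% matched_any])
  }
  structure(list(members = members, spectrum = s,
                 total_intensity = total_intensity, scheme = scheme,
                 fragment_tol = fragment_tol),
            class = "isobaric_group")
}

# Non-negative least squares by active-set elimination: fit, drop the most
# negative coefficient from the support, refit until all remaining
# coefficients are non-negative.  Keeps absent isobaric members pinned at 0
# instead of letting them absorb noise.
nnls_fit <- function(A, b) {
  active <- seq_len(ncol(A))
  x <- numeric(ncol(A))
  while (length(active)) {
    fit <- stats::lm.fit(A[, active, drop = FALSE], b)$coefficients
    fit[is.na(fit)] <- 0
    if (all(fit >= 0)) {
      x[active] <- fit
      return(x)
    }
    active <- active[-which.min(fit)]
  }
  x
}

# At every ladder coordinate where the members' theoretical masses are not
# all equal, partition members into mass classes.  Each observed class
# intensity is (sum of member intensities in the class) x (per-ion base), so
# the observations form a linear system in the member intensities.
fragment_mass_classes <- function(members, scheme, sep = 0.005) {
  ladders <- lapply(members, ion_ladder, scheme = scheme)
  nion <- nrow(ladders[[1L]])
  out <- list()
  for (i in seq_len(nion)) {
    m <- vapply(ladders, function(l) l$neutral_mass[i], numeric(1))
    o <- order(m)
    cls <- cumsum(c(1L, diff(m[o]) > sep))
    if (max(cls) == 1L) next
    for (cl in seq_len(max(cls))) {
      mem <- o[cls == cl]
      out[[length(out) + 1L]] <- list(
        series = ladders[[1L]]$series[i], index = ladders[[1L]]$index[i],
        mass = mean(m[o[cls == cl]]), members = mem)
    }
  }
  out
}

#' Split shared intensity among co-isolated isobaric proteoforms (FIRR)
#'
#' At each fragment coordinate where the members' theoretical masses differ,
#' the observed peak intensity of each mass class estimates the summed
#' intensity of the members in that class.  These class observations form a
#' linear system in the per-member intensities, solved by least squares,
#' clamped at zero and rescaled so the shares conserve the group's total
#' intensity.  For two members this reduces to the classical ratio of their
#' unique fragment-ion intensities; at zero noise the split is exact for any
#' number of members.
#'
#' @param group An [isobaric_group()].
#' @return Named numeric vector of intensity shares (names are proteoform
#'   notations suffixed with the channel when ambiguous); sums to the group
#'   total.  A member with no site-determining signal receives share 0 with
#'   a warning.
#' @export
firr_split <- function(group) {
  members <- group$members
  nm <- vapply(members, notation, "")
  ch <- vapply(members, function(p) p$channel, "")
  if (anyDuplicated(nm)) nm <- paste0(nm, "|", ch)
  if (length(members) == 1L)
    return(stats::setNames(group$total_intensity, nm))
  classes <- fragment_mass_classes(members, group$scheme)
  if (!length(classes)) {
    warning("isobaric members are indistinguishable by fragments; ",
            "splitting equally")
    return(stats::setNames(rep(group$total_intensity / length(members),
                               length(members)), nm))
  }
  pk <- group$spectrum$peaks
  A <- matrix(0, nrow = length(classes), ncol = length(members))
  b <- numeric(length(classes))
  for (r in seq_along(classes)) {
    cl <- classes[[r]]
    A[r, cl$members] <- 1
    j <- which(abs(pk$mass - cl$mass) <= group$fragment_tol)
    b[r] <- if (length(j)) max(pk$intensity[j]) else 0
  }
  x <- nnls_fit(A, b)
  if (sum(x) == 0) {
    warning("no site-determining signal for any member; splitting equally")
    x <- rep(1, length(members))
  }
  if (any(x == 0))
    warning("member(s) with no site-determining signal received share 0: ",
            paste(nm[x == 0], collapse = ", "))
  stats::setNames(x / sum(x) * group$total_intensity, nm)
}

#' Quantify searched spectra into a table of intensities and abundances
#'
#' Accepted PSMs contribute their spectrum's summed matched MS/MS intensity;
#' spectra whose isobaric rivals carry site-determining signal are split by
#' [firr_split()] among the top proteoform and those rivals.  Intensities of
#' repeated identifications of the same proteoform are summed, then
#' normalized per (tail, channel, sample) by [relative_abundance()].
#'
#' @param psms List of `psm` objects from [search_spectra()].
#' @param tail The searched [tail_sequence].
#' @param cfg The [search_config()] used.
#' @param sample Sample identifier recorded in the table.
#' @param min_share Shares below this fraction of a group's total are set to
#'   0 (background suppression for enumerated-but-absent rivals).
#' @return Quantification data frame: `tail`, `proteoform`, `channel`,
#'   `sample`, `intensity`, `relative_abundance`.
#' @export
quantify_psms <- function(psms, tail, cfg = search_config(), sample = "s1",
                          min_share = 0.005) {
  rows <- list()
  for (x in psms) {
    if (x$status != "accepted") next
    members <- c(list(x$proteoform), x$rival_proteoforms)
    if (is.null(x$spectrum))
      stop("psm carries no spectrum; run search_spectra() first")
    grp <- isobaric_group(members, x$spectrum, scheme = cfg$scheme,
                          fragment_tol = cfg$fragment_tol)
    shares <- suppressWarnings(firr_split(grp))
    shares[shares < min_share * sum(shares)] <- 0
    if (sum(shares) > 0) shares <- shares / sum(shares) * grp$total_intensity
    for (i in seq_along(members)) {
      if (shares[i] <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        tail = tail$name, proteoform = notation(members[[i]]),
        channel = members[[i]]$channel, sample = sample,
        intensity = unname(shares[i]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tail = character(), proteoform = character(),
                      channel = character(), sample = character(),
                      intensity = numeric(), relative_abundance = numeric(),
                      stringsAsFactors = FALSE))
  relative_abundance(do.call(rbind, rows))
}

#' Normalize intensities to relative abundances
#'
#' The relative abundance of a combinatorial form is its summed intensity
#' divided by the summed intensity of all modified and unmodified forms
#' sharing the same tail sequence; light and heavy-KR tails are distinct
#' sequences, so normalization is per channel by default (`pooled = TRUE`
#' normalizes light and heavy together).
#'
#' @param records Data frame with columns `tail`, `proteoform`, `channel`,
#'   `sample`, `intensity`.
#' @param pooled Normalize across channels jointly.
#' @return The records aggregated per (tail, proteoform, channel, sample)
#'   with a `relative_abundance` column; abundances sum to 1 within each
#'   normalization group.
#' @export
relative_abundance <- function(records, pooled = FALSE) {
  need <- c("tail", "proteoform", "channel", "sample", "intensity")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  agg <- stats::aggregate(intensity ~ tail + proteoform + channel + sample,
                          data = records, FUN = sum)
  grp <- if (pooled) interaction(agg$tail, agg$sample, drop = TRUE)
         else interaction(agg$tail, agg$channel, agg$sample, drop = TRUE)
  tot <- tapply(agg$intensity, grp, sum)[grp]
  if (any(tot <= 0)) stop("zero total intensity in a normalization group")
  agg$relative_abundance <- agg$intensity / as.numeric(tot)
  agg <- agg[order(agg$tail, agg$channel, agg$sample, agg$proteoform), ]
  rownames(agg) <- NULL
  agg[, c("tail", "proteoform", "channel", "sample", "intensity",
          "relative_abundance")]
}

#' Heavy/light channel ratios per proteoform
#'
#' Raw (pre-normalization) heavy over light intensity for proteoforms
#' quantified in both sequence channels of the same sample.
#'
#' @param quant Quantification table from [quantify_psms()] or
#'   [relative_abundance()].
#' @return Data frame: `tail`, `proteoform`, `sample`, `light`, `heavy`,
#'   `ratio`, `defined`; `ratio` is `NA` with `defined = FALSE` when the
#'   light intensity is 0 or the form is missing from a channel.
#' @export
channel_ratios <- function(quant) {
  li <- quant[quant$channel == "light", ]
  he <- quant[quant$channel == "heavy_KR", ]
  m <- merge(li[, c("tail", "proteoform", "sample", "intensity")],
             he[, c("tail", "proteoform", "sample", "intensity")],
             by = c("tail", "proteoform", "sample"),
             suffixes = c("_light", "_heavy"), all = TRUE)
  m$light <- m$intensity_light
  m$heavy <- m$intensity_heavy
  m$defined <- !is.na(m$light) & !is.na(m$heavy) & m$light > 0
  m$ratio <- ifelse(m$defined, m$heavy / m$light, NA_real_)
  m[, c("tail", "proteoform", "sample", "light", "heavy", "ratio", "defined")]
}
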