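# Spectrum-to-proteoform search: candidate enumeration within a precursor
# window, greedy fragment matching, scoring, and site-localization filtering
# on site-determining ions (the step the original pipeline delegates to a
# database search engine followed by isoScale-style filtering).

#' Search configuration
#'
#' Defaults follow routine middle-down practice: a wide 2.1 Da precursor
#' window (absorbing deconvolution/isotope errors), a 0.01 Da fragment
#' tolerance -- below the 0.0364 Da trimethyl/acetyl difference, so the two
#' are never confused -- and a 30 ppm tolerance for the localization filter.
#'
#' @param precursor_tol Precursor mass tolerance in Da.
#' @param fragment_tol Fragment matching tolerance in Da.
#' @param filter_ppm Localization-filter tolerance in ppm.
#' @param isobaric_window Da window within which candidates are treated as
#'   co-isolated isobaric rivals.
#' @param mod_rules Modification rule set, see [default_mod_rules()].
#' @param sites Integer positions allowed to carry modifications; default is
#'   every K/R in the tail (for the H3 tail use [h3_mod_sites()]).
#' @param max_mods Cap on modifications per proteoform.
#' @param scheme A [label_scheme()].
#' @param max_candidates Hard cap on enumerated candidates; exceeding it is
#'   an error (never silent truncation).
#' @param min_score Minimum score for acceptance.
#' @return An object of class `search_config`.
#' @export
search_config <- function(precursor_tol = 2.1, fragment_tol = 0.01,
                          filter_ppm = 30, isobaric_window = 0.05,
                          mod_rules = default_mod_rules(), sites = NULL,
                          max_mods = Inf, scheme = label_scheme(),
                          max_candidates = 50000L, min_score = 0) {
  stopifnot(precursor_tol > 0, fragment_tol > 0, filter_ppm > 0,
            isobaric_window > 0)
  if (!is.null(mod_rules$me3) && !is.null(mod_rules$ac) &&
      fragment_tol >= 3 * MASS_CH2 - MASS_AC)
    warning("fragment_tol >= the trimethyl/acetyl mass difference (",
            format(3 * MASS_CH2 - MASS_AC), " Da); the two kinds may be ",
            "confused")
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 filter_ppm = filter_ppm, isobaric_window = isobaric_window,
                 mod_rules = mod_rules, sites = sites, max_mods = max_mods,
                 scheme = scheme, max_candidates = max_candidates,
                 min_score = min_score),
            class = "search_config")
}

default_mod_sites <- function(tail, rules = default_mod_rules()) {
  letters <- tail_letters(tail)
  modifiable <- unique(unlist(rules, use.names = FALSE))
  tail_positions(tail)[letters %in% modifiable]
}

# state encoding per site: 0 none, 1..3 me1..me3, 4 ac
site_state_options <- function(residue, rules) {
  st <- 0L
  if (residue %in% rules$me1) st <- c(st, 1L)
  if (residue %in% rules$me2) st <- c(st, 2L)
  if (residue %in% rules$me3) st <- c(st, 3L)
  if (residue %in% rules$ac)  st <- c(st, 4L)
  st
}

# All site-state assignments with a given total methyl count and acetyl
# count, DFS with suffix-capacity pruning.
place_marks <- function(site_options, n_me, n_ac, max_mods) {
  ns <- length(site_options)
  maxme <- vapply(site_options, function(s) max(c(0L, s[s <= 3L])), integer(1))
  acok <- vapply(site_options, function(s) 4L %in% s, logical(1))
  sufme <- rev(cumsum(rev(maxme)))
  sufac <- rev(cumsum(rev(as.integer(acok))))
  out <- list(); n_out <- 0L
  rec <- function(i, cur, me_left, ac_left, mods_left) {
    if (i > ns) {
      if (me_left == 0L && ac_left == 0L) {
        n_out <<- n_out + 1L
        out[[n_out]] <<- cur
      }
      return()
    }
    if (me_left > sufme[i] || ac_left > sufac[i]) return()
    for (st in site_options[[i]]) {
      uses <- as.integer(st != 0L)
      if (uses > mods_left) next
      me_use <- if (st >= 1L && st <= 3L) st else 0L
      ac_use <- if (st == 4L) 1L else 0L
      if (me_use > me_left || ac_use > ac_left) next
      cur[i] <- st
      rec(i + 1L, cur, me_left - me_use, ac_left - ac_use, mods_left - uses)
    }
  }
  rec(1L, integer(ns), n_me, n_ac, max_mods)
  out[seq_len(n_out)]
}

# All ways to distribute H heavy methyls over methyl marks of degrees ks,
# with 0 <= h_i <= k_i.
distribute_heavy <- function(ks, H) {
  if (H == 0L) return(list(integer(length(ks))))
  if (!length(ks)) return(list())
  out <- list()
  rec <- function(i, left, cur) {
    if (i > length(ks)) {
      if (left == 0L) out[[length(out) + 1L]] <<- cur
      return()
    }
    if (left > sum(ks[i:length(ks)])) return()
    for (h in 0:min(ks[i], left)) {
      cur[i] <- h
      rec(i + 1L, left - h, cur)
    }
  }
  rec(1L, H, integer(length(ks)))
  out
}

#' Enumerate candidate proteoforms within a precursor window
#'
#' Composition-first enumeration: first solve for the total acetyl count,
#' methyl-unit count and heavy-methyl count compatible with the precursor
#' mass, then place the marks on the allowed sites and distribute the heavy
#' methyls over them.  Deterministic order (fewest modifications first, then
#' notation, then channel).
#'
#' @param precursor_mass Neutral precursor mass in Da.
#' @param cfg A [search_config()].
#' @param tail A [tail_sequence].
#' @return List of `proteoform` objects with
#'   `|mass - precursor_mass| <= precursor_tol`.
#' @export
enumerate_candidates <- function(precursor_mass, cfg, tail) {
  stopifnot(precursor_mass > 0)
  rules <- cfg$mod_rules
  scheme <- cfg$scheme
  sites <- cfg$sites %||% default_mod_sites(tail, rules)
  site_res <- tail_letters(tail)[match(sites, tail_positions(tail))]
  if (anyNA(site_res)) stop("modifiable sites outside the tail")
  opts <- lapply(site_res, site_state_options, rules = rules)
  maxM <- sum(vapply(opts, function(s) max(c(0L, s[s <= 3L])), integer(1)))
  maxA <- sum(vapply(opts, function(s) 4L %in% s, logical(1)))
  maxH <- if (scheme$methyl_channel) maxM else 0L
  channels <- if (scheme$sequence_channel) c("light", "heavy_KR") else "light"
  out <- list()
  for (ch in channels) {
    base <- proteoform_mass(proteoform(tail, channel = ch, rules = rules),
                            scheme)
    target <- precursor_mass - base
    for (a in 0:maxA) for (H in 0:maxH) {
      rem <- target - a * MASS_AC - H * scheme$heavy_methyl_delta
      lo <- max(0, ceiling((rem - cfg$precursor_tol) / MASS_CH2))
      hi <- min(maxM, floor((rem + cfg$precursor_tol) / MASS_CH2))
      if (hi < lo) next
      for (M in lo:hi) {
        if (H > M) next
        if (abs(a * MASS_AC + M * MASS_CH2 +
                H * scheme$heavy_methyl_delta - target) > cfg$precursor_tol)
          next
        placements <- place_marks(opts, n_me = M, n_ac = a,
                                  max_mods = min(cfg$max_mods, length(sites)))
        for (pl in placements) {
          on <- which(pl != 0L)
          kind <- c("me1", "me2", "me3", "ac")[pl[on]]
          ks <- ifelse(pl[on] <= 3L, pl[on], 0L)
          me_idx <- which(ks > 0L)
          for (hv in distribute_heavy(ks[me_idx], H)) {
            heavy <- integer(length(on))
            heavy[me_idx] <- hv
            mods <- data.frame(site = sites[on], residue = site_res[on],
                               kind = kind, heavy = heavy,
                               stringsAsFactors = FALSE)
            out[[length(out) + 1L]] <-
              proteoform(tail, mods, channel = ch, rules = rules)
            if (length(out) > cfg$max_candidates)
              stop("candidate cap (", cfg$max_candidates, ") exceeded; ",
                   "restrict mod_rules, sites or max_mods")
          }
        }
      }
    }
  }
  if (!length(out)) return(out)
  key <- vapply(out, function(p)
    sprintf("%02d|%s|%s", nrow(p$mods), notation(p), p$channel), "")
  out[order(key, method = "radix")]
}

#' Match spectrum peaks to a theoretical fragment ladder
#'
#' Greedy assignment: ions are visited in ladder order and take the most
#' intense unused peak within tolerance; each peak is used at most once per
#' ion series.
#'
#' @param s A [spectrum()].
#' @param ladder Theoretical ladder from [ion_ladder()], or a `proteoform`
#'   (ladder computed with `scheme`).
#' @param tol Tolerance value.
#' @param unit `"da"` or `"ppm"`.
#' @param scheme [label_scheme()] used when `ladder` is a proteoform.
#' @return Data frame: `series`, `index`, `ion_mass`, `peak_mass`,
#'   `intensity`, `error_da`, `error_ppm`.
#' @export
match_fragments <- function(s, ladder, tol = 0.01, unit = c("da", "ppm"),
                            scheme = label_scheme()) {
  unit <- match.arg(unit)
  if (inherits(ladder, "proteoform")) ladder <- ion_ladder(ladder, scheme)
  pm <- s$peaks$mass
  pi <- s$peaks$intensity
  n <- nrow(ladder)
  hit <- integer(n)
  used <- list(c = logical(length(pm)), z = logical(length(pm)))
  masses <- ladder$neutral_mass
  sers <- ladder$series
  for (i in seq_len(n)) {
    m <- masses[i]
    tol_da <- if (unit == "da") tol else tol * 1e-6 * m
    # peaks are sorted: restrict to the tolerance window by binary search
    loidx <- findInterval(m - tol_da, pm) + 1L
    hiidx <- findInterval(m + tol_da, pm)
    if (hiidx < loidx) next
    cand <- loidx:hiidx
    cand <- cand[!used[[sers[i]]][cand]]
    if (!length(cand)) next
    j <- cand[which.max(pi[cand])]
    used[[sers[i]]][j] <- TRUE
    hit[i] <- j
  }
  keep <- which(hit > 0L)
  j <- hit[keep]
  data.frame(series = sers[keep], index = ladder$index[keep],
             ion_mass = masses[keep], peak_mass = pm[j], intensity = pi[j],
             error_da = pm[j] - masses[keep],
             error_ppm = (pm[j] - masses[keep]) / masses[keep] * 1e6,
             stringsAsFactors = FALSE)
}

#' Score a proteoform-spectrum match
#'
#' Deterministic score in `[0, 1]`: the average of the fraction of
#' theoretical ions matched and the fraction of total spectrum intensity
#' carried by the matched peaks.
#'
#' @param matched Matched set from [match_fragments()].
#' @param ladder The theoretical ladder that was matched.
#' @param s The spectrum.
#' @return Score in `[0, 1]`.
#' @export
score_psm <- function(matched, ladder, s) {
  if (inherits(ladder, "proteoform")) ladder <- ion_ladder(ladder)
  total <- sum(s$peaks$intensity)
  if (!nrow(matched) || total <= 0 || !nrow(ladder)) return(0)
  0.5 * (nrow(matched) / nrow(ladder) + sum(matched$intensity) / total)
}

# Coordinates (series, index) at which the theoretical ladders of p and r
# differ by more than twice the Da matching tolerance -- i.e. the ions whose
# peaks can only be assigned to one of the two placements.  The smallest
# such difference in practice is trimethyl vs acetyl (0.0364 Da), separated
# at the default 0.01 Da tolerance.
discriminating_coords <- function(lp, lr, sep = 0.02) {
  stopifnot(nrow(lp) == nrow(lr))
  diff <- abs(lp$neutral_mass - lr$neutral_mass) > sep
  lp[diff, c("series", "index", "neutral_mass"), drop = FALSE]
}

#' Site-determining ions of a proteoform against isobaric rivals
#'
#' For each modification of `p`, the theoretical ions whose mass
#' distinguishes `p` from the rivals not carrying that modification (mass
#' difference above `sep`, twice the Da fragment-matching tolerance by
#' default).  With no rivals every ion is site-determining.
#'
#' @param p A `proteoform`.
#' @param rivals List of isobaric rival proteoforms.
#' @param scheme A [label_scheme()].
#' @param sep Minimum Da mass separation for an ion to discriminate two
#'   placements.
#' @return Named list (by single-modification notation) of ion data frames.
#' @export
site_determining_ions <- function(p, rivals, scheme = label_scheme(),
                                  sep = 0.02) {
  lp <- ion_ladder(p, scheme)
  mods <- p$mods
  labels <- vapply(seq_len(nrow(mods)), function(i)
    format_notation(mods[i, , drop = FALSE]), "")
  if (!length(rivals)) {
    out <- rep(list(lp), max(1L, nrow(mods)))
    names(out) <- if (nrow(mods)) labels else "(all)"
    return(out)
  }
  lrs <- lapply(rivals, ion_ladder, scheme = scheme)
  rival_has_mod <- function(r, i) {
    any(r$mods$site == mods$site[i] & r$mods$kind == mods$kind[i] &
          r$mods$heavy == mods$heavy[i])
  }
  out <- lapply(seq_len(nrow(mods)), function(i) {
    rel <- which(!vapply(rivals, rival_has_mod, TRUE, i = i))
    if (!length(rel)) return(lp)          # no rival contests this mod
    dd <- lapply(lrs[rel], function(lr) discriminating_coords(lp, lr, sep))
    dd <- unique(do.call(rbind, dd))
    rownames(dd) <- NULL
    dd
  })
  names(out) <- labels
  out
}

#' Apply the site-localization filter to a PSM
#'
#' An identification is accepted only if every co-isolated isobaric rival
#' is contradicted by at least one matched discriminating ion within the
#' ppm tolerance; placements whose rivals cannot all be ruled out are
#' rejected as ambiguous and discarded from quantification.  This applies
#' to unmodified proteoforms too (they carry no sites to localize, but
#' co-isolation ambiguity still does): with no rivals they accept on score
#' alone.
#'
#' @param psm A `psm` object (see [search_spectra()]).
#' @param rivals List of isobaric rival proteoforms.
#' @param cfg A [search_config()].
#' @return The PSM with `status` set to one of `accepted`,
#'   `rejected_ambiguous`, `rejected_score`, and `localization` filled with
#'   the per-modification site-determining matched ions.
#' @export
isoscale_filter <- function(psm, rivals, cfg = search_config()) {
  psm$rivals <- vapply(rivals, notation, "")
  if (psm$score < cfg$min_score || !nrow(psm$matched)) {
    psm$status <- "rejected_score"
    return(psm)
  }
  psm$localization <- site_determining_ions(psm$proteoform, rivals,
                                            cfg$scheme, 2 * cfg$fragment_tol)
  ok_within <- function(coords) {
    if (!nrow(coords)) return(FALSE)
    hit <- merge(psm$matched, coords[, c("series", "index")],
                 by = c("series", "index"))
    any(abs(hit$error_ppm) <= cfg$filter_ppm)
  }
  lp <- ion_ladder(psm$proteoform, cfg$scheme)
  contradicted <- vapply(rivals, function(r) {
    ok_within(discriminating_coords(lp, ion_ladder(r, cfg$scheme),
                                    2 * cfg$fragment_tol))
  }, TRUE)
  psm$status <- if (all(contradicted)) "accepted" else "rejected_ambiguous"
  psm
}

new_psm <- function(spectrum_id, p, matched, score) {
  structure(list(spectrum_id = spectrum_id, proteoform = p,
                 matched = matched, score = score,
                 localization = NULL, rivals = character(),
                 status = "unfiltered"),
            class = "psm")
}

#' @export
print.psm <- function(x, ...) {
  cat("<psm> ", x$spectrum_id, " -> ",
      if (nzchar(notation(x$proteoform))) notation(x$proteoform)
      else "(unmodified)",
      " [", x$proteoform$channel, "] score=", round(x$score, 4),
      " status=", x$status, "\n", sep = "")
  invisible(x)
}

#' Search spectra against a tail
#'
#' For each spectrum: enumerate candidates within the precursor window,
#' match and score each, keep the top-scoring candidate (ties broken by
#' fewer modifications, then notation), collect its isobaric rivals (within
#' `isobaric_window` of its mass) and apply the localization filter.
#'
#' @param spectra List of [spectrum()] objects.
#' @param tail A [tail_sequence].
#' @param cfg A [search_config()].
#' @return List of `psm` objects (spectra with no candidates are dropped);
#'   each carries `all_candidates` (the enumerated set) and
#'   `rival_proteoforms` for downstream intensity splitting.
#' @export
search_spectra <- function(spectra, tail, cfg = search_config()) {
  out <- list()
  for (s in spectra) {
    cands <- enumerate_candidates(s$precursor_neutral_mass, cfg, tail)
    if (!length(cands)) next
    ladders <- lapply(cands, ion_ladder, scheme = cfg$scheme)
    matches <- lapply(ladders, function(l)
      match_fragments(s, l, cfg$fragment_tol, "da"))
    scores <- vapply(seq_along(cands), function(i)
      score_psm(matches[[i]], ladders[[i]], s), numeric(1))
    key <- sprintf("%02d|%s", vapply(cands, function(p) nrow(p$mods), 0L),
                   vapply(cands, notation, ""))
    best <- order(-scores, key, method = "radix")[1L]
    p <- cands[[best]]
    masses <- vapply(cands, proteoform_mass, numeric(1), scheme = cfg$scheme)
    riv_idx <- setdiff(
      which(abs(masses - masses[best]) <= cfg$isobaric_window), best)
    psm <- new_psm(s$id, p, matches[[best]], scores[best])
    psm <- isoscale_filter(psm, cands[riv_idx], cfg)
    psm$spectrum <- s
    psm$rival_proteoforms <- cands[riv_idx]
    psm$rival_matches <- matches[riv_idx]
    out[[length(out) + 1L]] <- psm
  }
  out
}

#' Tabulate PSMs for export
#'
#' @param psms List of `psm` objects.
#' @param scheme [label_scheme()] for mass computation.
#' @return Data frame: `spectrum_id`, `proteoform`, `channel`, `mass`,
#'   `score`, `status`, `n_matched`, `max_ppm_error`.
#' @export
psm_table <- function(psms, scheme = label_scheme()) {
  do.call(rbind, lapply(psms, function(x) {
    data.frame(
      spectrum_id = x$spectrum_id,
      proteoform = notation(x$proteoform),
      channel = x$proteoform$channel,
      mass = proteoform_mass(x$proteoform, scheme),
      score = x$score,
      status = x$status,
      n_matched = nrow(x$matched),
      max_ppm_error = if (nrow(x$matched)) max(abs(x$matched$error_ppm)) else NA_real_,
      stringsAsFactors = FALSE)
  }))
}
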