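# Proteoforms: a tail plus a site-resolved set of modifications (each with a
# heavy-methyl count) and a sequence-label channel.  The compact notation
# "K14acK27me2:2" is the canonical external identifier.

empty_mods <- function() {
  data.frame(site = integer(), residue = character(),
             kind = character(), heavy = integer(),
             stringsAsFactors = FALSE)
}

#' Build a modification set for a tail
#'
#' @param site Integer vector of parent-protein positions.
#' @param kind Character vector of kinds (`me1`, `me2`, `me3`, `ac`).
#' @param heavy Integer vector of heavy-methyl counts `h`, `0 <= h <= k`
#'   where `k` is the methyl degree of the kind (acetylation forces `h = 0`).
#' @param tail The [tail_sequence] the sites refer to.
#' @param rules Modification rule set, see [default_mod_rules()].
#' @return A data frame with columns `site`, `residue`, `kind`, `heavy`,
#'   sorted by site.
#' @export
modifications <- function(site, kind, heavy = 0L, tail,
                          rules = default_mod_rules()) {
  site <- as.integer(site)
  heavy <- as.integer(rep_len(heavy, length(site)))
  stopifnot(length(kind) == length(site))
  mods <- data.frame(site = site,
                     residue = rep(NA_character_, length(site)),
                     kind = as.character(kind), heavy = heavy,
                     stringsAsFactors = FALSE)
  validate_mods(mods, tail, rules)
}

validate_mods <- function(mods, tail, rules = default_mod_rules()) {
  if (!nrow(mods)) return(empty_mods())
  pos <- tail_positions(tail)
  letters <- tail_letters(tail)
  idx <- match(mods$site, pos)
  if (anyNA(idx))
    stop("modification site ", mods$site[which(is.na(idx))[1L]],
         " outside tail '", tail$name, "'")
  mods$residue <- letters[idx]
  if (anyDuplicated(mods$site))
    stop("more than one modification at site ",
         mods$site[anyDuplicated(mods$site)])
  k <- methyl_degree(mods$kind)
  for (i in seq_len(nrow(mods))) {
    allowed <- rules[[mods$kind[i]]]
    if (is.null(allowed) || !mods$residue[i] %in% allowed)
      stop(mods$kind[i], " not allowed on residue ", mods$residue[i],
           " (site ", mods$site[i], ")")
  }
  if (any(mods$heavy < 0L | mods$heavy > k))
    stop("heavy-methyl count must satisfy 0 <= h <= k for ",
         format_notation(mods[which(mods$heavy < 0L | mods$heavy > k)[1L], ,
                              drop = FALSE]))
  mods <- mods[order(mods$site), , drop = FALSE]
  rownames(mods) <- NULL
  mods
}

#' Mass delta of one modification
#'
#' `k * 14.01565 + h * 4.022186` for a k-fold methylation carrying `h` heavy
#' methyl groups; `42.010565` (C2H2O) for acetylation.
#'
#' @param kind Modification kind.
#' @param heavy Heavy-methyl count.
#' @param scheme [label_scheme()] providing the heavy-methyl delta.
#' @return Mass delta in Da.
#' @export
mod_delta <- function(kind, heavy = 0L, scheme = label_scheme()) {
  k <- methyl_degree(kind)
  ifelse(kind == "ac", MASS_AC, k * MASS_CH2 + heavy * scheme$heavy_methyl_delta)
}

#' Construct a proteoform
#'
#' @param tail A [tail_sequence].
#' @param mods A modification data frame (see [modifications()]) or a compact
#'   notation string such as `"K14acK27me2:2"`.
#' @param channel Sequence-label channel, `"light"` or `"heavy_KR"`.
#' @param rules Modification rule set.
#' @param heavy_residues Optional integer positions of heavy K/R residues for
#'   partially labeled sequences; default under `channel = "heavy_KR"` is all
#'   K and R residues.
#' @return An object of class `proteoform`.
#' @examples
#' p <- proteoform(h3_tail(), "K27me2:2")
#' proteoform_mass(p)
#' @export
proteoform <- function(tail, mods = NULL, channel = c("light", "heavy_KR"),
                       rules = default_mod_rules(), heavy_residues = NULL) {
  channel <- match.arg(channel)
  if (is.null(mods)) mods <- empty_mods()
  if (is.character(mods)) mods <- parse_notation(mods, tail, rules)
  mods <- validate_mods(mods, tail, rules)
  if (!is.null(heavy_residues)) {
    heavy_residues <- as.integer(heavy_residues)
    letters <- tail_letters(tail)[match(heavy_residues, tail_positions(tail))]
    if (anyNA(letters) || !all(letters %in% c("K", "R")))
      stop("heavy_residues must be K/R positions within the tail")
  }
  structure(list(tail = tail, mods = mods, channel = channel,
                 heavy_residues = heavy_residues),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  nt <- format_notation(x$mods)
  cat("<proteoform> ", x$tail$name, " ",
      if (nzchar(nt)) nt else "(unmodified)", " [", x$channel, "]\n", sep = "")
  invisible(x)
}

#' Compact notation of a proteoform
#' @param p A `proteoform`.
#' @return The canonical notation string (empty for unmodified).
#' @export
notation <- function(p) format_notation(p$mods)

# Per-residue mass profile including sequence labels and modifications;
# the workhorse behind both intact mass and fragment ladders.
residue_mass_profile <- function(p, scheme = label_scheme()) {
  letters <- tail_letters(p$tail)
  if (scheme$methyl_channel && any(letters == "M") && !scheme$allow_heavy_met)
    stop("tail '", p$tail$name, "' contains methionine; under heavy-methyl ",
         "labeling the sequence itself becomes heavy. Set allow_heavy_met ",
         "= TRUE to override.")
  m <- unname(RESIDUE_MASS[letters])
  if (p$channel == "heavy_KR") {
    hv <- if (is.null(p$heavy_residues)) which(letters %in% c("K", "R"))
          else match(p$heavy_residues, tail_positions(p$tail))
    m[hv] <- m[hv] + ifelse(letters[hv] == "K",
                            scheme$heavy_K_delta, scheme$heavy_R_delta)
  }
  if (nrow(p$mods)) {
    idx <- p$mods$site - p$tail$first_position + 1L
    m[idx] <- m[idx] + mod_delta(p$mods$kind, p$mods$heavy, scheme)
  }
  m
}

#' Neutral monoisotopic mass of a proteoform
#'
#' Sum of residue masses, water, modification deltas and label deltas.
#'
#' @param p A `proteoform`.
#' @param scheme A [label_scheme()].
#' @return Mass in Da.
#' @export
proteoform_mass <- function(p, scheme = label_scheme()) {
  sum(residue_mass_profile(p, scheme)) + MASS_WATER
}

#' Theoretical ETD c / z-radical fragment ladder
#'
#' Returns the full ladder `c1..c(n-1)` and `z1..z(n-1)` of neutral fragment
#' masses; modifications and labels are carried by the fragment containing
#' their residue.  The two series are complementary:
#' `c_i + z_(n-i) = M + 1.007824` for every `i`.
#'
#' @param p A `proteoform` whose tail has at least 2 residues.
#' @param scheme A [label_scheme()].
#' @return Data frame with columns `series` ("c" or "z"), `index`,
#'   `neutral_mass`.
#' @export
ion_ladder <- function(p, scheme = label_scheme()) {
  m <- residue_mass_profile(p, scheme)
  n <- length(m)
  if (n < 2L) stop("fragment ladder requires a tail of length >= 2")
  cum <- cumsum(m)
  idx <- seq_len(n - 1L)
  data.frame(
    series = rep(c("c", "z"), each = n - 1L),
    index = c(idx, idx),
    neutral_mass = c(cum[idx] + C_ION_OFFSET,
                     (cum[n] - cum[n - idx]) + Z_ION_OFFSET),
    stringsAsFactors = FALSE
  )
}

MOD_TOKEN_RE <- "([A-Z])([0-9]+)(me[1-3]|ac)(:([0-9]+))?"

# Parse notation tokens without requiring a tail (site/kind/heavy only);
# heavy may be "*" meaning any count when wildcard = TRUE.
parse_mark_tokens <- function(s, wildcard = FALSE) {
  if (!nzchar(s))
    return(data.frame(residue = character(), site = integer(),
                      kind = character(), heavy = character(),
                      stringsAsFactors = FALSE))
  re <- if (wildcard) "([A-Z])([0-9]+)(me[1-3]|ac)(:([0-9]+|\\*))?"
        else paste0(MOD_TOKEN_RE)
  m <- gregexpr(re, s)[[1L]]
  tokens <- regmatches(s, gregexpr(re, s))[[1L]]
  if (m[1L] == -1L || paste(tokens, collapse = "") != s) {
    covered <- if (m[1L] == -1L) "" else paste(tokens, collapse = "")
    bad <- if (nzchar(covered)) sub(covered, "", s, fixed = TRUE) else s
    stop("malformed modification token near '",
         substr(bad, 1L, 12L), "' in \"", s, "\"")
  }
  parts <- regmatches(tokens, regexec(re, tokens))
  data.frame(
    residue = vapply(parts, `[`, "", 2L),
    site = as.integer(vapply(parts, `[`, "", 3L)),
    kind = vapply(parts, `[`, "", 4L),
    heavy = vapply(parts, function(x) if (nzchar(x[6L])) x[6L] else "0", ""),
    stringsAsFactors = FALSE
  )
}

#' Parse compact proteoform notation
#'
#' Inverse of [format_notation()].  Tokens look like `K27me2:2`: residue
#' letter, parent-protein site, kind, and an optional `:h` giving the number
#' of heavy-labeled methyl groups (`me3:1` = trimethyl with one heavy
#' methyl); `h = 0` is written without the suffix.
#'
#' @param s Notation string; `""` means unmodified.
#' @param tail The [tail_sequence] the sites refer to.
#' @param rules Modification rule set.
#' @return Modification data frame as from [modifications()].
#' @examples
#' parse_notation("K23me1:1K27me2:2", h3_tail())
#' @export
parse_notation <- function(s, tail, rules = default_mod_rules()) {
  stopifnot(is.character(s), length(s) == 1L)
  tk <- parse_mark_tokens(s)
  if (!nrow(tk)) return(empty_mods())
  letters <- tail_letters(tail)[match(tk$site, tail_positions(tail))]
  if (anyNA(letters))
    stop("site ", tk$site[which(is.na(letters))[1L]], " outside tail '",
         tail$name, "' in \"", s, "\"")
  mism <- which(letters != tk$residue)
  if (length(mism))
    stop("residue mismatch at site ", tk$site[mism[1L]], ": notation says ",
         tk$residue[mism[1L]], ", tail has ", letters[mism[1L]])
  mods <- data.frame(site = tk$site, residue = tk$residue, kind = tk$kind,
                     heavy = as.integer(tk$heavy), stringsAsFactors = FALSE)
  validate_mods(mods, tail, rules)
}

#' Format a modification set as compact notation
#'
#' @param mods Modification data frame.
#' @return Site-ascending concatenation such as `"K14acK27me2:2"`; the `:h`
#'   suffix is omitted when `h = 0`.  Empty string for no modifications.
#' @export
format_notation <- function(mods) {
  if (!nrow(mods)) return("")
  mods <- mods[order(mods$site), , drop = FALSE]
  paste0(mods$residue, mods$site, mods$kind,
         ifelse(mods$heavy > 0L, paste0(":", mods$heavy), ""),
         collapse = "")
}
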