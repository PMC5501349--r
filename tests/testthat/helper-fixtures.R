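# Shared fixtures: toy tails, noiseless spectra, and a brute-force candidate
# oracle used to verify the composition-first enumeration.

toy_tail_KK <- function() tail_sequence("toyKK", "ARTKAYKA")      # K4, K7
toy_tail_KRK <- function() tail_sequence("toyKRK", "ARTKQRKA")    # R2?, K4, R6, K7
toy_tail_K <- function() tail_sequence("toyK", "ARTK")            # K4

# Noiseless spectrum of one proteoform: its exact ladder at uniform intensity.
pure_spectrum <- function(p, scheme = label_scheme(), id = "pure",
                          intensity = 100) {
  l <- ion_ladder(p, scheme)
  spectrum(id, proteoform_mass(p, scheme),
           data.frame(mass = l$neutral_mass,
                      intensity = rep(intensity, nrow(l))))
}

# Exhaustive universe of proteoforms by brute force over every per-site
# state (and heavy-methyl distribution / sequence channel where enabled);
# the independent oracle for enumerate_candidates on small tails.  Returns
# a data frame of keys ("notation|channel") and masses; filter per
# precursor with bf_enumerate().
bf_universe <- function(tail, cfg) {
  letters <- strsplit(tail$residues, "")[[1L]]
  pos <- seq(tail$first_position, length.out = nchar(tail$residues))
  sites <- cfg$sites
  if (is.null(sites)) {
    modifiable <- unique(unlist(cfg$mod_rules))
    sites <- pos[letters %in% modifiable]
  }
  res <- letters[match(sites, pos)]
  deg <- c(me1 = 1L, me2 = 2L, me3 = 3L, ac = 0L)
  opts <- lapply(res, function(r) {
    o <- list(NULL)
    for (k in names(cfg$mod_rules)) {
      if (!r %in% cfg$mod_rules[[k]]) next
      hs <- if (cfg$scheme$methyl_channel) 0:deg[[k]] else 0L
      for (h in hs) o <- c(o, list(list(kind = k, heavy = h)))
    }
    o
  })
  channels <- if (cfg$scheme$sequence_channel) c("light", "heavy_KR") else "light"
  grid <- expand.grid(lapply(opts, seq_along))
  keys <- character(); masses <- numeric()
  for (ch in channels) {
    for (i in seq_len(nrow(grid))) {
      picks <- lapply(seq_along(sites), function(j) opts[[j]][[grid[i, j]]])
      on <- !vapply(picks, is.null, TRUE)
      if (sum(on) > cfg$max_mods) next
      mods <- if (any(on)) {
        data.frame(site = sites[on], residue = res[on],
                   kind = vapply(picks[on], function(x) x$kind, ""),
                   heavy = vapply(picks[on], function(x) x$heavy, 0L),
                   stringsAsFactors = FALSE)
      } else NULL
      p <- proteoform(tail, mods, channel = ch, rules = cfg$mod_rules)
      keys <- c(keys, paste0(notation(p), "|", ch))
      masses <- c(masses, proteoform_mass(p, cfg$scheme))
    }
  }
  data.frame(key = keys, mass = masses, stringsAsFactors = FALSE)
}

bf_enumerate <- function(precursor, tail, cfg, universe = NULL) {
  if (is.null(universe)) universe <- bf_universe(tail, cfg)
  sort(universe$key[abs(universe$mass - precursor) <= cfg$precursor_tol])
}

candidate_keys <- function(cands)
  sort(vapply(cands, function(p) paste0(notation(p), "|", p$channel), ""))

# A random valid proteoform on a tail (used by property-style tests).
random_proteoform <- function(tail, sites, rules = default_mod_rules(),
                              scheme = label_scheme(), max_mods = length(sites)) {
  letters <- strsplit(tail$residues, "")[[1L]]
  pos <- seq(tail$first_position, length.out = nchar(tail$residues))
  res <- letters[match(sites, pos)]
  n <- sample(0:max_mods, 1L)
  picked <- sort(sample(seq_along(sites), n))
  rows <- list()
  for (j in picked) {
    kinds <- names(rules)[vapply(rules, function(r) res[j] %in% r, TRUE)]
    k <- sample(kinds, 1L)
    h <- if (scheme$methyl_channel) sample(0:methyl_degree(k), 1L) else 0L
    rows[[length(rows) + 1L]] <- data.frame(
      site = sites[j], residue = res[j], kind = k, heavy = h,
      stringsAsFactors = FALSE)
  }
  mods <- if (length(rows)) do.call(rbind, rows) else NULL
  ch <- if (scheme$sequence_channel && stats::runif(1) < 0.5) "heavy_KR" else "light"
  proteoform(tail, mods, channel = ch, rules = rules)
}
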