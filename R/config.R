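# Run configuration: a YAML file that round-trips losslessly and rejects
# unknown keys, holding the fixed acquisition/search parameters as defaults
# (2.1 Da precursor, 0.01 Da fragment, 30 ppm filter, charge 8+, GluC tail).

run_config_template <- function() {
  list(
    tail = list(name = "H3_1-50",
                residues = h3_tail()$residues,
                first_position = 1L,
                cleavage_context = "GluC after E50"),
    sites = h3_mod_sites(),
    mod_rules = default_mod_rules(),
    label_scheme = list(sequence_channel = FALSE, methyl_channel = FALSE,
                        allow_heavy_met = FALSE),
    search = list(precursor_tol = 2.1, fragment_tol = 0.01, filter_ppm = 30,
                  isobaric_window = 0.05, max_mods = 4L,
                  max_candidates = 50000L, min_score = 0),
    mixture = list(
      proteoforms = list(),   # list of {notation, channel, proportion}
      noise = list(cv = 0.1, dropout = 0.05, ppm_jitter = 2),
      replicates = 1L),
    seed = 1L,
    sample = "s1"
  )
}

check_known_keys <- function(x, template, path = "") {
  extra <- setdiff(names(x), names(template))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s", ": ",
         paste0(path, extra, collapse = ", "))
  for (k in intersect(names(x), names(template))) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(x[[k]]))
      check_known_keys(x[[k]], template[[k]], paste0(path, k, "."))
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[k]]) && !is.null(names(override[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a run configuration file
#'
#' YAML keys mirror [run_config_template()]; unknown keys are rejected,
#' missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  template <- run_config_template()
  check_known_keys(user, template)
  cfg <- merge_config(template, user)
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' @param cfg Config list (as from [read_run_config()] or
#'   [run_config_template()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_tail <- function(cfg) {
  tail_sequence(cfg$tail$name, cfg$tail$residues,
                first_position = cfg$tail$first_position,
                cleavage_context = cfg$tail$cleavage_context %||% NA_character_)
}

config_scheme <- function(cfg) {
  label_scheme(sequence_channel = isTRUE(cfg$label_scheme$sequence_channel),
               methyl_channel = isTRUE(cfg$label_scheme$methyl_channel),
               allow_heavy_met = isTRUE(cfg$label_scheme$allow_heavy_met))
}

config_search <- function(cfg) {
  rules <- lapply(cfg$mod_rules, unlist)
  search_config(precursor_tol = cfg$search$precursor_tol,
                fragment_tol = cfg$search$fragment_tol,
                filter_ppm = cfg$search$filter_ppm,
                isobaric_window = cfg$search$isobaric_window,
                mod_rules = rules, sites = unlist(cfg$sites),
                max_mods = cfg$search$max_mods,
                scheme = config_scheme(cfg),
                max_candidates = cfg$search$max_candidates,
                min_score = cfg$search$min_score)
}

config_mixture <- function(cfg) {
  pf <- cfg$mixture$proteoforms
  if (!length(pf)) stop("config declares no mixture proteoforms")
  df <- data.frame(
    notation = vapply(pf, function(x) as.character(x$notation %||% ""), ""),
    channel = vapply(pf, function(x) as.character(x$channel %||% "light"), ""),
    proportion = vapply(pf, function(x) as.numeric(x$proportion), numeric(1)),
    stringsAsFactors = FALSE)
  nm <- cfg$mixture$noise
  mixture_spec(config_tail(cfg), df,
               noise = noise_model(nm$cv %||% 0, nm$dropout %||% 0,
                                   nm$ppm_jitter %||% 0),
               replicates = cfg$mixture$replicates %||% 1L,
               seed = cfg$seed %||% 1L,
               scheme = config_scheme(cfg),
               isobaric_window = cfg$search$isobaric_window)
}
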