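# End-to-end pipeline: simulate -> search -> quantify -> analyze, plus the
# command-line surface.

#' Run the full simulate/search/quantify/analyze pipeline
#'
#' Simulates the configured mixture, writes the spectra (MGF) and ground
#' truth, searches and filters them, quantifies with FIRR splitting, and
#' derives single-mark, hybrid-mark and interplay tables.  All outputs are
#' deterministic TSV/MGF files under `out_dir`.
#'
#' @param cfg A `run_config` (or path to a YAML config file).
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress progress messages.
#' @return Invisible list with `spectra`, `truth`, `psms`, `quant`,
#'   `single_marks`, `interplay`.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("effective config:\n", yaml::as.yaml(unclass(cfg)))
  tail <- config_tail(cfg)
  scfg <- config_search(cfg)
  spec <- config_mixture(cfg)
  sim <- simulate_spectra(spec)
  write_mgf(sim$spectra, file.path(out_dir, "spectra.mgf"))
  write_tsv(sim$truth$expected_table, file.path(out_dir, "ground_truth.tsv"))
  say(length(sim$spectra), " spectra simulated (seed ", cfg$seed, ")")
  psms <- search_spectra(sim$spectra, tail, scfg)
  write_tsv(psm_table(psms, scfg$scheme), file.path(out_dir, "psms.tsv"))
  say(length(psms), " PSMs; ",
      sum(vapply(psms, function(x) x$status == "accepted", TRUE)),
      " accepted")
  quant <- quantify_psms(psms, tail, scfg, sample = cfg$sample %||% "s1")
  write_tsv(quant, file.path(out_dir, "quant.tsv"))
  single <- interp <- NULL
  for (ch in unique(quant$channel)) {
    sub <- quant[quant$channel == ch, , drop = FALSE]
    sm <- single_mark_table(sub)
    if (nrow(sm)) sm$channel <- ch
    single <- rbind(single, sm)
    it <- interplay_table(sub)
    if (!is.null(it) && nrow(it)) { it$channel <- ch; interp <- rbind(interp, it) }
  }
  if (!is.null(single))
    write_tsv(single, file.path(out_dir, "single_marks.tsv"))
  if (!is.null(interp))
    write_tsv(interp, file.path(out_dir, "interplay.tsv"))
  say("wrote outputs to ", normalizePath(out_dir))
  invisible(list(spectra = sim$spectra, truth = sim$truth, psms = psms,
                 quant = quant, single_marks = single, interplay = interp))
}

cli_usage <- function() {
  paste(
    "usage: middlemarks <command> [options]",
    "",
    "commands:",
    "  simulate  --config C --out D     simulate spectra + ground truth",
    "  search    --spectra F --config C --out D    search + filter an MGF",
    "  quantify  --spectra F --config C --out D    search, filter, quantify",
    "  analyze   --quant F --out D [--heavy-fraction] [--interplay]",
    "            [--correlate F2]       analytics on a quant table",
    "  pipeline  --config C --out D     simulate -> search -> quantify -> analyze",
    "  template  --out F                write a commented config template",
    "",
    "global: --help", sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list(flags = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3L)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        opts$flags <- c(opts$flags, key); i <- i + 1L
      }
    } else stop("unexpected argument '", a, "'")
  }
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see `cli_usage()` for the
#' subcommands.  Returns an exit status instead of quitting so it can be
#' called programmatically; the installed `cli/middlemarks` script wraps it
#' with `quit(status = ...)`.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status: 0 on success, 2 on usage/validation errors.
#' @export
mm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(0L)
  }
  cmd <- args[1L]
  res <- tryCatch({
    opts <- parse_cli_args(args[-1L])
    if ("help" %in% opts$flags) { cat(cli_usage(), "\n"); return(0L) }
    switch(cmd,
      template = {
        out <- opts$out %||% stop("template needs --out")
        write_run_config(run_config_template(), out)
        message("wrote config template to ", out)
      },
      simulate = {
        cfg <- read_run_config(opts$config %||% stop("simulate needs --config"))
        out <- opts$out %||% stop("simulate needs --out")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        sim <- simulate_spectra(config_mixture(cfg))
        write_mgf(sim$spectra, file.path(out, "spectra.mgf"))
        write_tsv(sim$truth$expected_table, file.path(out, "ground_truth.tsv"))
      },
      search = ,
      quantify = {
        cfg <- read_run_config(opts$config %||% stop(cmd, " needs --config"))
        out <- opts$out %||% stop(cmd, " needs --out")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        spectra <- read_mgf(opts$spectra %||% stop(cmd, " needs --spectra"))
        tail <- config_tail(cfg)
        scfg <- config_search(cfg)
        psms <- search_spectra(spectra, tail, scfg)
        write_tsv(psm_table(psms, scfg$scheme), file.path(out, "psms.tsv"))
        if (cmd == "quantify")
          write_tsv(quantify_psms(psms, tail, scfg,
                                  sample = cfg$sample %||% "s1"),
                    file.path(out, "quant.tsv"))
      },
      analyze = {
        out <- opts$out %||% stop("analyze needs --out")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        quant <- read_tsv(opts$quant %||% stop("analyze needs --quant"))
        for (ch in unique(quant$channel)) {
          sub <- quant[quant$channel == ch, , drop = FALSE]
          sm <- single_mark_table(sub)
          write_tsv(sm, file.path(out, paste0("single_marks_", ch, ".tsv")))
          if ("interplay" %in% opts$flags)
            write_tsv(interplay_table(sub),
                      file.path(out, paste0("interplay_", ch, ".tsv")))
          if ("heavy-fraction" %in% opts$flags)
            message("heavy fraction [", ch, "]: ",
                    format(heavy_fraction(sub)))
        }
        if (!is.null(opts$correlate)) {
          q2 <- read_tsv(opts$correlate)
          m <- merge(quant, q2, by = c("tail", "proteoform", "channel"))
          rc <- replicate_correlation(m$relative_abundance.x,
                                      m$relative_abundance.y)
          message("replicate correlation r = ", format(rc$r),
                  ", p = ", format(rc$p), " (n = ", rc$n, ")")
        }
      },
      pipeline = {
        cfg <- read_run_config(opts$config %||% stop("pipeline needs --config"))
        run_pipeline(cfg, opts$out %||% stop("pipeline needs --out"))
      },
      stop("unknown command '", cmd, "'")
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    cat(cli_usage(), "\n")
    2L
  })
  res
}
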