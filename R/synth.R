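# Synthetic data with ground truth: mixed ETD spectra of proteoform
# mixtures (co-isolating isobaric members), exact incomplete-incorporation
# distributions, and a heavy-methyl labeling time course emulating an
# EMT-style experiment.

#' Noise model for simulated spectra
#'
#' @param cv Coefficient of variation of multiplicative log-normal
#'   fragment-intensity noise (0 = noiseless).
#' @param dropout Bernoulli probability that any fragment peak is missing.
#' @param ppm_jitter Gaussian fragment mass jitter, standard deviation in
#'   ppm.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0, dropout = 0, ppm_jitter = 0) {
  stopifnot(cv >= 0, dropout >= 0, dropout <= 1, ppm_jitter >= 0)
  structure(list(cv = cv, dropout = dropout, ppm_jitter = ppm_jitter),
            class = "noise_model")
}

#' Specify a proteoform mixture to simulate
#'
#' @param tail A [tail_sequence].
#' @param proteoforms Data frame with columns `notation`, `channel`,
#'   `proportion`; proportions must be positive and sum to 1.
#' @param noise A [noise_model()].
#' @param replicates Spectra emitted per isobaric group.
#' @param seed Integer seed; all randomness is derived from it.
#' @param scheme A [label_scheme()].
#' @param isobaric_window Da window within which members co-isolate into one
#'   mixed spectrum.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(tail, proteoforms, noise = noise_model(),
                         replicates = 1L, seed = 1L,
                         scheme = label_scheme(), isobaric_window = 0.05) {
  stopifnot(all(c("notation", "channel", "proportion") %in%
                  names(proteoforms)))
  if (any(proteoforms$proportion <= 0))
    stop("mixture proportions must be > 0")
  if (abs(sum(proteoforms$proportion) - 1) > 1e-9)
    stop("mixture proportions must sum to 1")
  structure(list(tail = tail, proteoforms = proteoforms, noise = noise,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 scheme = scheme, isobaric_window = isobaric_window),
            class = "mixture_spec")
}

# lognormal multipliers with mean 1 and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate deconvoluted ETD spectra of a proteoform mixture
#'
#' Each proteoform contributes its exact c/z fragment ladder with uniform
#' base intensity proportional to its mixture proportion; members whose
#' masses fall within the isobaric window are merged into a single mixed
#' spectrum (co-isolation), with coinciding fragment masses summed.
#' Log-normal intensity noise, Bernoulli peak dropout and Gaussian ppm mass
#' jitter are then applied.  Fully reproducible from the seed.
#'
#' @param spec A [mixture_spec()].
#' @return List with elements `spectra` (list of [spectrum()]) and `truth`
#'   (class `ground_truth`: the spec, a per-spectrum member map, and the
#'   expected per-channel quantification table).
#' @export
simulate_spectra <- function(spec) {
  set.seed(spec$seed)
  tail <- spec$tail
  pf <- spec$proteoforms
  forms <- lapply(seq_len(nrow(pf)), function(i)
    proteoform(tail, pf$notation[i], channel = pf$channel[i]))
  masses <- vapply(forms, proteoform_mass, numeric(1), scheme = spec$scheme)
  o <- order(masses)
  grp_of <- integer(nrow(pf))
  grp_of[o] <- cumsum(c(1, diff(masses[o]) > spec$isobaric_window))
  base <- 1e6
  spectra <- list()
  members_map <- list()
  for (g in sort(unique(grp_of))) {
    idx <- which(grp_of == g)
    ladders <- lapply(forms[idx], ion_ladder, scheme = spec$scheme)
    pk <- do.call(rbind, lapply(seq_along(idx), function(k) {
      l <- ladders[[k]]
      data.frame(mass = round(l$neutral_mass, 6),
                 intensity = base * pf$proportion[idx[k]])
    }))
    pk <- stats::aggregate(intensity ~ mass, data = pk, FUN = sum)
    prec <- sum(masses[idx] * pf$proportion[idx]) / sum(pf$proportion[idx])
    for (r in seq_len(spec$replicates)) {
      m <- pk$mass
      int <- pk$intensity * rlnorm_cv(nrow(pk), spec$noise$cv)
      keep <- stats::runif(nrow(pk)) >= spec$noise$dropout
      m <- m * (1 + stats::rnorm(nrow(pk), 0, spec$noise$ppm_jitter) * 1e-6)
      sid <- sprintf("grp%02d_rep%02d", g, r)
      spectra[[length(spectra) + 1L]] <-
        spectrum(sid, prec, data.frame(mass = m[keep],
                                       intensity = int[keep]))
      members_map[[sid]] <- pf$notation[idx]
    }
  }
  expected <- do.call(rbind, lapply(unique(pf$channel), function(ch) {
    sel <- pf$channel == ch
    data.frame(tail = tail$name, proteoform = pf$notation[sel], channel = ch,
               sample = "truth",
               intensity = base * pf$proportion[sel] * spec$replicates,
               relative_abundance = pf$proportion[sel] /
                 sum(pf$proportion[sel]),
               stringsAsFactors = FALSE)
  }))
  truth <- structure(list(spec = spec, members = members_map,
                          expected_table = expected),
                     class = "ground_truth")
  list(spectra = spectra, truth = truth)
}

#' Exact distribution of heavy-label incorporation
#'
#' Long polypeptides are rarely 100% labeled; each labelable residue is
#' heavy independently with probability `p`, so the count of heavy K and R
#' residues follows independent binomials.  Returns the exact joint
#' probability mass function together with the resulting precursor mass
#' shifts -- no sampling involved.
#'
#' @param n_K,n_R Numbers of labelable lysines and arginines (for a tail,
#'   count with [incorporation_sites()]).
#' @param p Per-site heavy-incorporation probability in `[0, 1]`.
#' @param scheme A [label_scheme()] providing the per-residue deltas.
#' @return Data frame `k_K`, `k_R`, `n_heavy`, `mass_shift`, `prob`;
#'   probabilities sum to 1.
#' @export
simulate_incorporation <- function(n_K, n_R = 0L, p = 0.95,
                                   scheme = label_scheme()) {
  stopifnot(p >= 0, p <= 1, n_K >= 0, n_R >= 0)
  g <- expand.grid(k_K = 0:n_K, k_R = 0:n_R)
  g$prob <- stats::dbinom(g$k_K, n_K, p) * stats::dbinom(g$k_R, n_R, p)
  g$n_heavy <- g$k_K + g$k_R
  g$mass_shift <- g$k_K * scheme$heavy_K_delta + g$k_R * scheme$heavy_R_delta
  g[, c("k_K", "k_R", "n_heavy", "mass_shift", "prob")]
}

#' Count labelable K/R residues of a tail
#'
#' @param tail A [tail_sequence].
#' @return Named integer vector `c(K = ..., R = ...)`.
#' @export
incorporation_sites <- function(tail) {
  letters <- tail_letters(tail)
  c(K = sum(letters == "K"), R = sum(letters == "R"))
}

#' Default single-mark marginal frequencies for the H3 tail
#'
#' Per-site mark probabilities used by the population sampler; chosen as
#' plausible bulk H3 single-mark abundances (K9 and K27 methylation-rich,
#' moderate K14/K18/K23 acetylation, sparse R methylation).
#'
#' @return Data frame `site`, `residue`, `kind`, `prob`; per-site totals
#'   are below 1, the remainder being the unmodified state.
#' @export
h3_mark_marginals <- function() {
  data.frame(
    site = c(4L, 8L, 9L, 9L, 9L, 9L, 14L, 18L, 18L, 23L, 23L, 26L,
             27L, 27L, 27L, 36L, 36L, 36L),
    residue = c("K", "R", "K", "K", "K", "K", "K", "K", "K", "K", "K", "R",
                "K", "K", "K", "K", "K", "K"),
    kind = c("me1", "me1", "me1", "me2", "me3", "ac", "ac", "me1", "ac",
             "me1", "ac", "me1", "me1", "me2", "me3", "me1", "me2", "me3"),
    prob = c(0.05, 0.05, 0.15, 0.20, 0.15, 0.05, 0.20, 0.05, 0.10,
             0.10, 0.15, 0.05, 0.15, 0.30, 0.20, 0.10, 0.20, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Sample a population of combinatorial tails
#'
#' Site states are drawn independently per site from the marginal
#' frequencies; each methyl group then carries a heavy label independently
#' with probability `q` (first-order replacement kinetics give
#' `q = 1 - exp(-lambda * t)`).  Optional coupling perturbs one pair of
#' marks away from independence.
#'
#' @param n Number of tails.
#' @param marginals Data frame `site`, `residue`, `kind`, `prob`
#'   (per-site totals <= 1).
#' @param q Probability that any methyl group is heavy.
#' @param coupling Optional list `list(a=, b=, type=, strength=)`: whenever
#'   mark `a` is present, with probability `strength` mark `b` is forced on
#'   (`type = "boost"`) or erased (`type = "exclude"`).  `a`/`b` are mark
#'   keys without heavy suffix.
#' @param seed Optional integer seed.
#' @return Character vector of `n` proteoform notations.
#' @export
simulate_tail_population <- function(n, marginals = h3_mark_marginals(),
                                     q = 0, coupling = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites <- unique(marginals$site)
  state <- matrix("", nrow = n, ncol = length(sites))
  hcount <- matrix(0L, nrow = n, ncol = length(sites))
  for (j in seq_along(sites)) {
    mg <- marginals[marginals$site == sites[j], , drop = FALSE]
    if (sum(mg$prob) > 1) stop("per-site marginals exceed 1 at site ",
                               sites[j])
    u <- stats::runif(n)
    cuts <- cumsum(mg$prob)
    pick <- findInterval(u, c(0, cuts), left.open = TRUE)  # 1..k marks, k+1 none
    kind <- c(mg$kind, "")[pick]
    state[, j] <- kind
  }
  if (!is.null(coupling)) {
    ka <- parse_mark_key(coupling$a); kb <- parse_mark_key(coupling$b)
    ja <- match(ka$site, sites); jb <- match(kb$site, sites)
    has_a <- state[, ja] == ka$kind
    act <- has_a & stats::runif(n) < (coupling$strength %||% 1)
    if (identical(coupling$type, "boost")) state[act, jb] <- kb$kind
    else if (identical(coupling$type, "exclude")) state[act, jb] <- ""
    else stop("coupling$type must be 'boost' or 'exclude'")
  }
  if (q > 0) {
    for (j in seq_along(sites)) {
      isme <- state[, j] %in% c("me1", "me2", "me3")
      if (!any(isme)) next
      k <- methyl_degree(state[isme, j])
      hcount[isme, j] <- stats::rbinom(sum(isme), k, q)
    }
  }
  res_of <- marginals$residue[match(sites, marginals$site)]
  cols <- lapply(seq_along(sites), function(j) {
    tok <- ifelse(state[, j] == "", "",
                  paste0(res_of[j], sites[j], state[, j],
                         ifelse(hcount[, j] > 0L,
                                paste0(":", hcount[, j]), "")))
    tok
  })
  o <- order(sites)
  do.call(paste0, cols[o])
}

#' Tabulate a sampled tail population into a quantification table
#'
#' @param notations Character vector of proteoform notations (from
#'   [simulate_tail_population()]).
#' @param tail_name Tail name recorded in the table.
#' @param sample Sample identifier.
#' @param channel Sequence channel of the population.
#' @return Normalized quantification table (abundance = frequency).
#' @export
population_quant_table <- function(notations, tail_name, sample,
                                   channel = "light") {
  tb <- table(notations)
  data.frame(tail = tail_name, proteoform = names(tb), channel = channel,
             sample = sample, intensity = as.numeric(tb),
             relative_abundance = as.numeric(tb) / length(notations),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a heavy-methyl labeling time course
#'
#' Emulates plating cells into heavy-methionine medium at t = 0: each
#' pre-existing methyl group is independently replaced by (or deposited as)
#' a heavy methyl with probability `1 - exp(-lambda * t)`, so the heavy
#' count of a k-fold methylation is Binomial(k, 1 - exp(-lambda t)).
#' Slower-growing (confluent) cultures correspond to a smaller `lambda`.
#'
#' @param times Time points in days.
#' @param lambda First-order methyl replacement rate per day.
#' @param n_tails Tails sampled per time point.
#' @param marginals Single-mark marginals, see [h3_mark_marginals()].
#' @param tail A [tail_sequence] (names the output tables).
#' @param seed Integer seed.
#' @return Named list of normalized quantification tables, one per time
#'   point (`day0`, `day1`, ...).
#' @export
simulate_emt_timecourse <- function(times = c(0, 1, 2), lambda = 2.0,
                                    n_tails = 5000L,
                                    marginals = h3_mark_marginals(),
                                    tail = h3_tail(), seed = 1L) {
  stopifnot(lambda >= 0, all(times >= 0))
  set.seed(seed)
  out <- lapply(seq_along(times), function(i) {
    q <- 1 - exp(-lambda * times[i])
    nt <- simulate_tail_population(n_tails, marginals, q = q)
    population_quant_table(nt, tail$name, sprintf("day%g", times[i]))
  })
  names(out) <- sprintf("day%g", times)
  out
}
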