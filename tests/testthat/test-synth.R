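test_that("noiseless simulation emits the exact fragment ladder and is seed-deterministic", {
  t <- h3_tail()
  p <- proteoform(t, "K27me3")
  spec <- mixture_spec(t, data.frame(notation = "K27me3", channel = "light",
                                     proportion = 1), seed = 5)
  sim <- simulate_spectra(spec)
  expect_length(sim$spectra, 1)
  l <- ion_ladder(p)
  expect_equal(sort(sim$spectra[[1]]$peaks$mass),
               sort(round(l$neutral_mass, 6)), tolerance = 1e-9)
  expect_equal(sim$spectra[[1]]$precursor_neutral_mass, proteoform_mass(p))

  sim2 <- simulate_spectra(spec)
  expect_identical(sim$spectra[[1]]$peaks, sim2$spectra[[1]]$peaks)

  noisy <- mixture_spec(t, data.frame(notation = "K27me3", channel = "light",
                                      proportion = 1),
                        noise = noise_model(cv = 0.2, dropout = 0.1,
                                            ppm_jitter = 2), seed = 9)
  expect_identical(simulate_spectra(noisy)$spectra[[1]]$peaks,
                   simulate_spectra(noisy)$spectra[[1]]$peaks)
})

test_that("an isobaric 3:1 pair yields exactly 3:1 site-determining intensities", {
  t <- h3_tail()
  spec <- mixture_spec(t, data.frame(notation = c("K9me2", "K14me2"),
                                     channel = "light",
                                     proportion = c(0.75, 0.25)), seed = 2)
  sim <- simulate_spectra(spec)
  expect_length(sim$spectra, 1)
  pk <- sim$spectra[[1]]$peaks
  lA <- ion_ladder(proteoform(t, "K9me2"))
  c9 <- lA$neutral_mass[lA$series == "c" & lA$index == 9]
  lB <- ion_ladder(proteoform(t, "K14me2"))
  c9b <- lB$neutral_mass[lB$series == "c" & lB$index == 9]
  iA <- pk$intensity[abs(pk$mass - c9) < 1e-4]
  iB <- pk$intensity[abs(pk$mass - c9b) < 1e-4]
  expect_equal(iA / iB, 3, tolerance = 1e-9)
})

test_that("ground truth reproduces the mixture proportions per channel", {
  t <- h3_tail()
  ls <- label_scheme(sequence_channel = TRUE)
  pf <- data.frame(notation = c("K9me2", "", "K9me2"),
                   channel = c("light", "light", "heavy_KR"),
                   proportion = c(0.4, 0.4, 0.2))
  sim <- simulate_spectra(mixture_spec(t, pf, scheme = ls, seed = 1))
  et <- sim$truth$expected_table
  expect_equal(et$relative_abundance[et$channel == "light"], c(0.5, 0.5))
  expect_equal(et$relative_abundance[et$channel == "heavy_KR"], 1)
})

test_that("mixture specs validate proportions", {
  t <- h3_tail()
  expect_error(mixture_spec(t, data.frame(notation = "", channel = "light",
                                          proportion = 0.9)), "sum to 1")
  expect_error(mixture_spec(t, data.frame(notation = c("", "K9me2"),
                                          channel = "light",
                                          proportion = c(1.2, -0.2))),
               "> 0")
})

test_that("incorporation pmf is exact binomial with linear mean shift", {
  # p = 1: point mass at the full shift; H3 1-50 rounds to 134 Da
  ns <- incorporation_sites(h3_tail())
  expect_identical(unname(ns), c(8L, 7L))
  full <- simulate_incorporation(ns["K"], ns["R"], p = 1)
  on <- full[full$prob > 0.999, ]
  expect_equal(nrow(on), 1L)
  expect_equal(round(on$mass_shift), 134)

  zero <- simulate_incorporation(ns["K"], ns["R"], p = 0)
  expect_equal(zero$mass_shift[zero$prob > 0.999], 0)

  # binomial moments at n = 15, p = 0.9
  d <- simulate_incorporation(15, 0, p = 0.9)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  mu <- sum(d$n_heavy * d$prob)
  expect_equal(mu, 13.5, tolerance = 1e-9)
  expect_equal(sum((d$n_heavy - mu)^2 * d$prob), 1.35, tolerance = 1e-9)

  # mean mass shift is p times the full shift (linearity)
  d2 <- simulate_incorporation(ns["K"], ns["R"], p = 0.95)
  expect_equal(sum(d2$mass_shift * d2$prob),
               0.95 * (8 * MASS_HEAVY_K + 7 * MASS_HEAVY_R),
               tolerance = 1e-9)
})

test_that("labeling time course: no heavy at t=0, increasing with t and with rate", {
  tc_fast <- simulate_emt_timecourse(times = c(0, 1, 2), lambda = 2.0,
                                     n_tails = 3000, seed = 8)
  hf_fast <- vapply(tc_fast, heavy_fraction, numeric(1))
  expect_equal(unname(hf_fast["day0"]), 0)
  expect_true(all(diff(hf_fast) > 0))

  tc_slow <- simulate_emt_timecourse(times = c(0, 1, 2), lambda = 0.8,
                                     n_tails = 3000, seed = 8)
  hf_slow <- vapply(tc_slow, heavy_fraction, numeric(1))
  expect_true(all(hf_fast[-1] > hf_slow[-1]))

  # lambda -> large: every methylated tail is heavy, so the heavy fraction
  # equals the total methylated-tail fraction
  tc_inf <- simulate_emt_timecourse(times = c(0, 2), lambda = 50,
                                    n_tails = 2000, seed = 8)
  tb <- tc_inf$day2
  methylated <- grepl("me", tb$proteoform, fixed = TRUE)
  expect_equal(heavy_fraction(tb),
               sum(tb$relative_abundance[methylated]), tolerance = 1e-9)
})

test_that("heavy counts follow Binomial(k, 1 - exp(-lambda t))", {
  lambda <- 0.8
  q <- 1 - exp(-lambda * 1)
  marg <- data.frame(site = 27L, residue = "K", kind = "me3", prob = 0.6,
                     stringsAsFactors = FALSE)
  nt <- simulate_tail_population(20000, marg, q = q, seed = 13)
  hs <- integer()
  for (h in 0:3) {
    key <- if (h == 0) "K27me3" else sprintf("K27me3:%d", h)
    hs[h + 1] <- sum(nt == key)
  }
  expect_gt(sum(hs), 10000)
  ref <- stats::dbinom(0:3, 3, q)
  gof <- stats::chisq.test(hs, p = ref)
  expect_gt(gof$p.value, 0.01)
})

test_that("population coupling shifts coexistence in the constructed direction", {
  marg <- h3_mark_marginals()
  boost <- simulate_tail_population(20000, marg, seed = 3,
                                    coupling = list(a = "K9me2", b = "K27me3",
                                                    type = "boost",
                                                    strength = 0.8))
  itb <- interplay(population_quant_table(boost, "t", "s"), "K9me2", "K27me3")
  expect_true(itb$defined)
  expect_gt(itb$score, 0.5)

  excl <- simulate_tail_population(20000, marg, seed = 3,
                                   coupling = list(a = "K9me2", b = "K27me3",
                                                   type = "exclude",
                                                   strength = 1))
  ite <- interplay(population_quant_table(excl, "t", "s"), "K9me2", "K27me3")
  expect_false(ite$defined)
  expect_equal(ite$F_ab, 0)
})
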