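test_that("enumeration finds the unmodified form and exact isobaric sets on toy tails", {
  t <- toy_tail_K()
  cfg <- search_config(mod_rules = default_mod_rules())
  base <- proteoform_mass(proteoform(t))
  keys <- candidate_keys(enumerate_candidates(base, cfg, t))
  expect_true("|light" %in% keys)

  # +2 CH2 at 0.01 Da resolves to exactly K4me2 when only K4 is searched
  cfg2 <- search_config(precursor_tol = 0.01, sites = 4L)
  keys2 <- candidate_keys(enumerate_candidates(base + 2 * MASS_CH2, cfg2, t))
  expect_identical(keys2, "K4me2|light")

  # two K sites, +2 methyl units: the three isobaric placements
  tkk <- toy_tail_KK()
  basekk <- proteoform_mass(proteoform(tkk))
  cfg3 <- search_config(precursor_tol = 0.01, sites = c(4L, 7L))
  keys3 <- candidate_keys(
    enumerate_candidates(basekk + 2 * MASS_CH2, cfg3, tkk))
  expect_identical(keys3,
                   sort(c("K4me1K7me1|light", "K4me2|light", "K7me2|light")))
})

test_that("enumeration equals the brute-force oracle on toy tails", {
  cfgs <- list(
    list(tail = toy_tail_KK(),
         cfg = search_config(precursor_tol = 2.1, max_mods = 2)),
    list(tail = toy_tail_KRK(),
         cfg = search_config(precursor_tol = 2.1, max_mods = 3,
                             scheme = label_scheme(sequence_channel = TRUE))),
    list(tail = toy_tail_KK(),
         cfg = search_config(precursor_tol = 0.05, max_mods = 2,
                             scheme = label_scheme(methyl_channel = TRUE)))
  )
  set.seed(101)
  for (cc in cfgs) {
    base <- proteoform_mass(proteoform(cc$tail))
    uni <- bf_universe(cc$tail, cc$cfg)
    for (i in 1:40) {
      m <- base + stats::runif(1, -5, 140)
      expect_identical(candidate_keys(enumerate_candidates(m, cc$cfg, cc$tail)),
                       bf_enumerate(m, cc$tail, cc$cfg, uni))
    }
  }
})

test_that("the candidate cap errors instead of silently truncating", {
  cfg <- search_config(sites = h3_mod_sites(), max_candidates = 10L)
  m <- proteoform_mass(proteoform(h3_tail(), "K9me1K14me1K27me1"))
  expect_error(enumerate_candidates(m, cfg, h3_tail()), "cap")
})

test_that("fragment matching is exact on noiseless spectra and empty on empty ones", {
  p <- proteoform(h3_tail(), "K9me2")
  s <- pure_spectrum(p)
  l <- ion_ladder(p)
  m <- match_fragments(s, l, 0.01)
  expect_equal(nrow(m), nrow(l))
  expect_equal(max(abs(m$error_ppm)), 0, tolerance = 1e-6)

  s0 <- spectrum("empty", 100, data.frame(mass = numeric(),
                                          intensity = numeric()))
  expect_equal(nrow(match_fragments(s0, l, 0.01)), 0L)
})

test_that("a misplaced methyl shifts the intervening c-ions by 2 CH2", {
  t <- h3_tail()
  s <- pure_spectrum(proteoform(t, "K9me2"))
  rival <- ion_ladder(proteoform(t, "K14me2"))
  m <- match_fragments(s, rival, 0.01)
  missed_c <- setdiff(9:13, m$index[m$series == "c"])
  expect_identical(missed_c, 9:13)
  # the unmatched rival ions sit exactly 2*CH2 from the true peaks
  true_l <- ion_ladder(proteoform(t, "K9me2"))
  for (i in 9:13) {
    d <- true_l$neutral_mass[true_l$series == "c" & true_l$index == i] -
      rival$neutral_mass[rival$series == "c" & rival$index == i]
    expect_equal(d, 2 * MASS_CH2, tolerance = 1e-9)
  }
})

test_that("the PSM score is the mean of ion-count and intensity coverage", {
  p <- proteoform(toy_tail_KK(), "K4me2")
  l <- ion_ladder(p)
  s <- pure_spectrum(p)
  full <- match_fragments(s, l, 0.01)
  expect_equal(score_psm(full, l, s), 1.0)
  none <- full[0, ]
  expect_equal(score_psm(none, l, s), 0.0)
  # half the ions carrying half the matchable intensity -> 0.5
  half <- full[seq_len(nrow(l) / 2), ]
  expect_equal(sum(half$intensity) / sum(s$peaks$intensity), 0.5)
  expect_equal(score_psm(half, l, s), 0.5)
})

test_that("site-determining ions match the brute-force ladder comparison", {
  t <- h3_tail()
  p <- proteoform(t, "K9me2")
  riv <- list(proteoform(t, "K14me2"))
  sdi <- site_determining_ions(p, riv)
  expect_named(sdi, "K9me2")
  cs <- sort(sdi$K9me2$index[sdi$K9me2$series == "c"])
  expect_identical(cs, 9:13)
  zs <- sort(sdi$K9me2$index[sdi$K9me2$series == "z"])
  expect_identical(zs, (50 - 13):(50 - 9))   # mirror z ions

  # brute force: coordinates whose masses differ between the two ladders
  lp <- ion_ladder(p); lr <- ion_ladder(riv[[1]])
  bf <- which(abs(lp$neutral_mass - lr$neutral_mass) > 0.02)
  got <- sort(paste0(sdi$K9me2$series, sdi$K9me2$index))
  expect_identical(got, sort(paste0(lp$series[bf], lp$index[bf])))

  # no rivals: every ion is site-determining
  all_ions <- site_determining_ions(p, list())
  expect_equal(nrow(all_ions$K9me2), nrow(lp))
})

test_that("rivals differing in disjoint regions are intersected per modification", {
  t <- h3_tail()
  p <- proteoform(t, "K9me2K27ac")
  rivals <- list(proteoform(t, "K14me2K27ac"),   # contests the me2 placement
                 proteoform(t, "K9me2K18ac"))    # contests the ac placement
  sdi <- site_determining_ions(p, rivals)
  lp <- ion_ladder(p)
  for (nm in names(sdi)) {
    riv_lacking <- Filter(function(r) !grepl(nm, paste0(notation(r), "x"),
                                             fixed = TRUE), rivals)
    bf <- unique(unlist(lapply(riv_lacking, function(r) {
      lr <- ion_ladder(r)
      which(abs(lp$neutral_mass - lr$neutral_mass) > 0.02)
    })))
    expect_setequal(paste0(sdi[[nm]]$series, sdi[[nm]]$index),
                    paste0(lp$series[bf], lp$index[bf]))
  }
})

test_that("localization accepts clean spectra and rejects when the distinguishing region is gone", {
  t <- h3_tail()
  cfg <- search_config(sites = h3_mod_sites(), max_mods = 2)
  p <- proteoform(t, "K9me2")
  s <- pure_spectrum(p)
  psms <- search_spectra(list(s), t, cfg)
  expect_length(psms, 1)
  expect_identical(notation(psms[[1]]$proteoform), "K9me2")
  expect_identical(psms[[1]]$status, "accepted")

  # delete every peak whose mass depends on the placement within 9..14
  l <- ion_ladder(p)
  keep_c <- !(l$series == "c" & l$index %in% 9:13)
  keep_z <- !(l$series == "z" & l$index %in% (50 - 13):(50 - 9))
  s2 <- spectrum("gap", proteoform_mass(p),
                 data.frame(mass = l$neutral_mass[keep_c & keep_z],
                            intensity = 100))
  psms2 <- search_spectra(list(s2), t, cfg)
  expect_identical(psms2[[1]]$status, "rejected_ambiguous")

  # the unmodified proteoform accepts on score alone
  s3 <- pure_spectrum(proteoform(t))
  psms3 <- search_spectra(list(s3), t, cfg)
  expect_identical(notation(psms3[[1]]$proteoform), "")
  expect_identical(psms3[[1]]$status, "accepted")
})

test_that("trimethyl and acetyl candidates never share a site-determining peak at 0.01 Da", {
  t <- h3_tail()
  p_me3 <- proteoform(t, "K27me3")
  p_ac <- proteoform(t, "K27ac")
  s <- pure_spectrum(p_me3)
  sdi <- site_determining_ions(p_me3, list(p_ac))
  m_me3 <- match_fragments(s, ion_ladder(p_me3), 0.01)
  m_ac <- match_fragments(s, ion_ladder(p_ac), 0.01)
  coords <- paste0(sdi$K27me3$series, sdi$K27me3$index)
  peaks_me3 <- m_me3$peak_mass[paste0(m_me3$series, m_me3$index) %in% coords]
  peaks_ac <- m_ac$peak_mass[paste0(m_ac$series, m_ac$index) %in% coords]
  expect_gt(length(peaks_me3), 0)
  expect_length(intersect(peaks_me3, peaks_ac), 0)
})

test_that("noiseless search returns the true proteoform top-ranked and accepted", {
  t <- toy_tail_KRK()
  sites <- c(2L, 4L, 6L, 7L)[-1]  # K4, R6, K7
  ls <- label_scheme(methyl_channel = TRUE)
  cfg <- search_config(sites = c(4L, 6L, 7L), max_mods = 3, scheme = ls)
  set.seed(23)
  for (i in 1:30) {
    p <- random_proteoform(t, c(4L, 6L, 7L), scheme = ls)
    psms <- search_spectra(list(pure_spectrum(p, ls)), t, cfg)
    expect_length(psms, 1)
    expect_identical(notation(psms[[1]]$proteoform), notation(p))
    expect_identical(psms[[1]]$status, "accepted")
  }
})
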