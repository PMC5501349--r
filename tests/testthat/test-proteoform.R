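test_that("intact masses match hand-computed monoisotopic values", {
  gg <- proteoform(tail_sequence("gg", "GG"))
  expect_equal(proteoform_mass(gg), 2 * 57.021464 + 18.010565,
               tolerance = 1e-9)

  t <- h3_tail()
  base <- proteoform_mass(proteoform(t))
  # trimethyl adds 42.047, acetyl 42.011 (3 dp); they differ by ~0.0364
  d_me3 <- proteoform_mass(proteoform(t, "K27me3")) - base
  d_ac <- proteoform_mass(proteoform(t, "K14ac")) - base
  expect_equal(round(d_me3, 3), 42.047)
  expect_equal(round(d_ac, 3), 42.011)
  expect_gte(d_me3 - d_ac, 0.03)

  # one heavy methyl shifts a dimethyl by ~4.022: me2:1 = 32.0535
  ls <- label_scheme(methyl_channel = TRUE)
  d_me21 <- proteoform_mass(proteoform(t, "K27me2:1"), ls) - base
  expect_equal(round(d_me21, 4), 32.0535)

  expect_error(proteoform_mass(proteoform(tail_sequence("x", "AXG"))),
               "unknown residue")
})

test_that("heavy-KR channel shift equals the K/R count times the label deltas", {
  t <- h3_tail()
  letters <- strsplit(t$residues, "")[[1]]
  nK <- sum(letters == "K")
  nR <- sum(letters == "R")
  expect_identical(c(nK, nR), c(8L, 7L))
  shift <- proteoform_mass(proteoform(t, channel = "heavy_KR")) -
    proteoform_mass(proteoform(t))
  expect_equal(shift, nK * MASS_HEAVY_K + nR * MASS_HEAVY_R, tolerance = 1e-9)
  expect_equal(round(shift), 134)
  # partial labeling: only the flagged residues shift
  part <- proteoform(t, channel = "heavy_KR", heavy_residues = c(4L, 8L))
  expect_equal(proteoform_mass(part) - proteoform_mass(proteoform(t)),
               MASS_HEAVY_K + MASS_HEAVY_R, tolerance = 1e-9)
})

test_that("mass additivity: adding one modification adds exactly its delta", {
  t <- h3_tail()
  ls <- label_scheme(methyl_channel = TRUE)
  set.seed(42)
  for (i in 1:20) {
    p <- random_proteoform(t, h3_mod_sites(), scheme = ls, max_mods = 3)
    free <- setdiff(h3_mod_sites(), p$mods$site)
    site <- sample(free, 1)
    res <- strsplit(t$residues, "")[[1]][site]
    kind <- if (res == "K") sample(c("me1", "me2", "me3", "ac"), 1) else
      sample(c("me1", "me2"), 1)
    h <- sample(0:methyl_degree(kind), 1)
    p2 <- proteoform(t, rbind(p$mods, data.frame(site = site, residue = res,
                                                 kind = kind, heavy = h)))
    p2$channel <- p$channel
    expect_equal(proteoform_mass(p2, ls) - proteoform_mass(p, ls),
                 mod_delta(kind, h, ls), tolerance = 1e-9)
  }
})

test_that("m/z conversion follows (M + z*proton)/z", {
  expect_equal(mz(1000, 1), 1001.007276)
  expect_equal(mz(0, 8), 1.007276)
  # linearity: a mass difference D maps to D/z in m/z space
  D <- 134.1715
  expect_equal(mz(5000 + D, 8) - mz(5000, 8), D / 8, tolerance = 1e-12)
  expect_error(mz(100, 0), "charge")
  expect_equal(neutral_mass(mz(1234.5, 8), 8), 1234.5, tolerance = 1e-9)
})

test_that("ETD ladder has 2(n-1) ions and the frozen terminal constants", {
  t5 <- tail_sequence("t5", "ARTKA")
  l <- ion_ladder(proteoform(t5))
  expect_equal(nrow(l), 2 * (5 - 1))
  c1 <- l$neutral_mass[l$series == "c" & l$index == 1]
  expect_equal(c1, 71.037114 + 17.026549, tolerance = 1e-9)
  expect_error(ion_ladder(proteoform(tail_sequence("t1", "A"))), "length")
})

test_that("c/z complementarity holds for every index on random labeled proteoforms", {
  t <- h3_tail()
  ls <- label_scheme(sequence_channel = TRUE, methyl_channel = TRUE)
  set.seed(7)
  for (i in 1:15) {
    p <- random_proteoform(t, h3_mod_sites(), scheme = ls, max_mods = 4)
    M <- proteoform_mass(p, ls)
    l <- ion_ladder(p, ls)
    n <- nchar(t$residues)
    cc <- l$neutral_mass[l$series == "c"][1:(n - 1)]
    zz <- l$neutral_mass[l$series == "z"][1:(n - 1)]
    sums <- cc + rev(zz) - M
    expect_equal(sums, rep(MASS_CZ_COMPLEMENT, n - 1), tolerance = 1e-9)
    expect_equal(round(MASS_CZ_COMPLEMENT, 5), 1.00782)
  }
})

test_that("notation parses and formats the field-standard tokens", {
  t <- h3_tail()
  m1 <- parse_notation("K27me2:2", t)
  expect_equal(m1$site, 27L)
  expect_equal(m1$kind, "me2")
  expect_equal(m1$heavy, 2L)

  m2 <- parse_notation("K23me1:1K27me2:2", t)
  expect_equal(m2$heavy, c(1L, 2L))

  expect_equal(nrow(parse_notation("", t)), 0L)
  expect_equal(format_notation(parse_notation("", t)), "")
  expect_equal(format_notation(modifications(27, "me3", 1, t)), "K27me3:1")
  # h = 0 suffix omitted, sites sorted ascending
  expect_equal(format_notation(parse_notation("K27me2K14ac", t)),
               "K14acK27me2")
})

test_that("notation rejects malformed or chemically invalid tokens", {
  t <- h3_tail()
  expect_error(parse_notation("K27me4", t), "malformed")
  expect_error(parse_notation("K27me2:3", t), "0 <= h <= k")
  expect_error(parse_notation("K27ac:1", t), "0 <= h <= k")
  expect_error(parse_notation("K26me1", t), "residue mismatch")
  expect_error(parse_notation("K99me1", t), "outside tail")
  expect_error(parse_notation("R8me3", t), "not allowed")
  expect_error(parse_notation("K9me2 junk", t), "malformed")
})

test_that("parse/format notation round-trips on random modification sets", {
  t <- h3_tail()
  ls <- label_scheme(methyl_channel = TRUE)
  set.seed(11)
  for (i in 1:25) {
    p <- random_proteoform(t, h3_mod_sites(), scheme = ls)
    s <- notation(p)
    expect_identical(format_notation(parse_notation(s, t)), s)
  }
})

test_that("methionine-containing tails are rejected under methyl labeling unless overridden", {
  tm <- tail_sequence("withM", "ARTKMA")
  ls <- label_scheme(methyl_channel = TRUE)
  expect_error(proteoform_mass(proteoform(tm), ls), "methionine")
  ls_ok <- label_scheme(methyl_channel = TRUE, allow_heavy_met = TRUE)
  expect_silent(proteoform_mass(proteoform(tm), ls_ok))
  # H3 1-50 has no methionine, so the default path is unaffected
  expect_silent(proteoform_mass(proteoform(h3_tail()), ls))
})
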