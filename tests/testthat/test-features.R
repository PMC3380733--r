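mc <- mass_constants()

test_that("normalized intensities are proportions summing to one", {
  s <- spectrum("p", 500, 1, mz = c(100, 200, 300), intensity = c(10, 30, 60))
  ni <- normalized_intensities(s)
  expect_equal(ni$normi, c(0.1, 0.3, 0.6))
  one <- spectrum("one", 500, 1, 100, 42)
  expect_equal(normalized_intensities(one)$normi, 1.0)
  withr::local_seed(1)
  for (i in 1:20) {
    s <- random_spectrum()
    expect_equal(sum(normalized_intensities(s)$normi), 1, tolerance = 1e-12)
  }
})

test_that("the three-peak fixture reproduces every hand-derived feature", {
  s <- fixture_sa()
  expect_equal(f1_complement_intensity(s, mc), 0.7)
  expect_equal(f2_uncharged_precursor_mass(s, mc), 600.0, tolerance = 1e-4)
  expect_equal(f3_aa_difference_count(s, mc), 1)
  expect_equal(f4_mean_delta_mass(s), 100.0)
  expect_equal(f5_good_diff_fraction(s, mc), 0.4)
  expect_equal(f6_complementary_pair_count(s, mc), 1)
  expect_equal(f7_neutral_loss_pair_count(s, mc), 0)
  expect_equal(f8_intense_peak_ratio(s), 1.0)
  expect_equal(f9_delta_mass_std(s), sd(c(57.02, 142.98)))
  expect_equal(f10_support_ion_pair_count(s, mc), 0)
})

test_that("precursor mass, neutral-loss and support-ion arithmetic", {
  s2 <- spectrum("z2", 500.5, 2, c(100, 200), c(1, 1))
  expect_equal(f2_uncharged_precursor_mass(s2, mc), 998.98544,
               tolerance = 1e-4)
  # water and ammonia losses
  w <- spectrum("w", 900, 1, c(300.0, 318.01), c(1, 1))
  expect_equal(f7_neutral_loss_pair_count(w, mc), 1)
  wa <- spectrum("wa", 900, 1, c(300.0, 317.03, 318.01), c(1, 1, 1))
  expect_equal(f7_neutral_loss_pair_count(wa, mc), 2)
  # CO and NH support ions
  co <- spectrum("co", 900, 1, c(300.0, 327.99), c(1, 1))
  expect_equal(f10_support_ion_pair_count(co, mc), 1)
  nh <- spectrum("nh", 900, 1, c(300.0, 315.01), c(1, 1))
  expect_equal(f10_support_ion_pair_count(nh, mc), 1)
})

test_that("boundary behaviour of intensity and delta-mass features", {
  s <- spectrum("i", 900, 1, c(100, 200, 300), c(100, 0.5, 0.4))
  expect_equal(f8_intense_peak_ratio(s), 1 / 3)  # 1% of 100.9 = 1.009
  eq <- spectrum("eq", 900, 1, seq(100, 400, by = 50), rep(1, 7))
  expect_equal(f8_intense_peak_ratio(eq), 1.0)
  expect_equal(f4_mean_delta_mass(eq), 50)
  expect_equal(f9_delta_mass_std(eq), 0.0)
  two <- spectrum("two", 900, 1, c(100, 163), c(1, 1))
  expect_equal(f4_mean_delta_mass(two), 63)
  expect_warning(v <- f9_delta_mass_std(two), "fewer than 3")
  expect_equal(v, 0)
  # exact glycine gap with equal intensities -> Good-Diff fraction 1
  gly <- spectrum("gly", 900, 1, c(200, 200 + 57.02146), c(5, 5))
  expect_equal(f5_good_diff_fraction(gly, mc), 1.0)
  # no residue near a 0.6 Da gap
  near <- spectrum("near", 900, 1, c(100.0, 100.6), c(1, 1))
  expect_equal(f3_aa_difference_count(near, mc), 0)
})

test_that("degenerate spectra yield zeros with a warning, not errors", {
  one <- spectrum("one", 601.00728, 1, 300, 10)
  expect_warning(expect_equal(f1_complement_intensity(one, mc), 0))
  expect_equal(f3_aa_difference_count(one, mc), 0)
  expect_equal(f6_complementary_pair_count(one, mc), 0)
  expect_warning(fm <- compute_feature_matrix(list(one), mc), "peak")
  expect_equal(unname(unlist(fm[paste0("f", c(1, 3:7, 9:10))])),
               rep(0, 8))
  expect_equal(fm$f8, 1.0)
  expect_equal(compute_feature_matrix(list(), mc),
               data.frame(id = character(),
                          matrix(numeric(), 0, 10,
                                 dimnames = list(NULL, paste0("f", 1:10)))))
})

test_that("windowed pair scans equal the brute-force double-loop oracles", {
  withr::local_seed(101)
  for (r in 1:60) {
    s <- random_spectrum(max_peaks = 50)
    expect_equal(f1_complement_intensity(s, mc), oracle_f1(s, mc),
                 tolerance = 1e-12)
    expect_equal(f3_aa_difference_count(s, mc),
                 oracle_diff_count(s, mc$residue_masses, mc$tolerance))
    expect_equal(f5_good_diff_fraction(s, mc), oracle_f5(s, mc),
                 tolerance = 1e-12)
    expect_equal(f6_complementary_pair_count(s, mc), oracle_f6(s, mc))
    expect_equal(f7_neutral_loss_pair_count(s, mc),
                 oracle_diff_count(s, c(mc$water, mc$ammonia), mc$tolerance))
    expect_equal(f10_support_ion_pair_count(s, mc),
                 oracle_diff_count(s, c(mc$co_group, mc$nh_group),
                                   mc$tolerance))
  }
})

test_that("features are invariant to intensity scaling and peak order", {
  withr::local_seed(7)
  for (r in 1:10) {
    s <- random_spectrum()
    perm <- sample(nrow(s$peaks))
    s_perm <- spectrum(s$id, s$precursor_mz, s$precursor_charge,
                       s$peaks$mz[perm], s$peaks$intensity[perm])
    s_scaled <- spectrum(s$id, s$precursor_mz, s$precursor_charge,
                         s$peaks$mz, s$peaks$intensity * 1000)
    base <- compute_feature_matrix(list(s), mc)
    expect_equal(compute_feature_matrix(list(s_perm), mc), base)
    expect_equal(compute_feature_matrix(list(s_scaled), mc), base)
  }
  # permuting input spectrum order permutes rows identically
  spectra <- lapply(1:5, function(i) random_spectrum(paste0("o", i)))
  fm <- compute_feature_matrix(spectra, mc)
  fm_rev <- compute_feature_matrix(rev(spectra), mc)
  expect_equal(fm_rev, fm[5:1, ], ignore_attr = TRUE)
})

test_that("planting an extra complementary pair never decreases f1 or f6", {
  withr::local_seed(9)
  for (r in 1:10) {
    s <- random_spectrum()
    target <- s$precursor_mz * s$precursor_charge -
      s$precursor_charge * mc$proton
    x <- runif(1, 150, target - 150)
    planted <- spectrum(s$id, s$precursor_mz, s$precursor_charge,
                        c(s$peaks$mz, x, target - x),
                        c(s$peaks$intensity, 10, 10))
    expect_gte(f6_complementary_pair_count(planted, mc),
               f6_complementary_pair_count(s, mc))
    expect_gte(f1_complement_intensity(planted, mc) + 1e-12,
               f1_complement_intensity(s, mc))
  }
})

test_that("pair-sum conventions and constants overrides are honoured", {
  s <- fixture_sa()
  mc_by <- mass_constants(pair_sum_convention = "by")
  # under the b/y convention the 200+400 pair no longer matches (target ~602)
  expect_equal(f6_complementary_pair_count(s, mc_by), 0)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tolerance: 0.1", "pair_sum_convention: protonated",
               "residue_masses:", "  G: 57.0"), path)
  mc2 <- read_mass_config(path)
  expect_equal(mc2$tolerance, 0.1)
  expect_equal(mc2$pair_sum_convention, "protonated")
  expect_equal(unname(mc2$residue_masses["G"]), 57.0)
  expect_equal(unname(mc2$residue_masses["A"]), 71.03711)
})
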