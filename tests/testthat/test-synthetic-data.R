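test_that("multiplet area scales linearly with concentration", {
  cfg <- cohort_config(grid_points = 16384, noise_sd = 0)
  specs <- list(metabolite_spec("Alanine", peak_shape(1.4715, "d", protons = 3)))
  area_of <- function(conc) {
    sp <- generate_polar_spectrum(specs, conc, cfg, seed = 1)
    idx <- abs(sp$ppm - 1.4715) <= 0.15
    abs(pracma::trapz(rev(sp$ppm[idx]), rev(sp$intensity[idx])))
  }
  expect_equal(area_of(2) / area_of(1), 2.0, tolerance = 0.01)
  # absolute area against the analytic Lorentzian window oracle
  a1 <- area_of(1)
  hw <- 0.003
  expected <- 3 * sum(c(0.5, 0.5) * lorentz_window_area(
    1.4715 + c(-1, 1) * 0.0175 / 2, hw, 1.4715 - 0.15, 1.4715 + 0.15))
  expect_equal(a1, expected, tolerance = 0.01)
})

test_that("a glycine spec puts its apex at the annotated shift", {
  cfg <- cohort_config(grid_points = 32768, noise_sd = 0)
  sp <- generate_polar_spectrum(
    list(metabolite_spec("Glycine", peak_shape(3.5648, "s", protons = 2))),
    1, cfg, seed = 1)
  near <- abs(sp$ppm - 3.5648) <= 0.05
  apex <- sp$ppm[near][which.max(sp$intensity[near])]
  expect_lt(abs(apex - 3.5648), 0.002)
})

test_that("generation is deterministic under a seed and rejects bad input", {
  cfg <- cohort_config(grid_points = 2048, noise_sd = 0.4, baseline_amp = 2)
  specs <- default_polar_specs()
  conc <- vapply(specs, `[[`, numeric(1), "base_conc")
  s1 <- generate_polar_spectrum(specs, conc, cfg, seed = 99)
  s2 <- generate_polar_spectrum(specs, conc, cfg, seed = 99)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- generate_polar_spectrum(specs, conc, cfg, seed = 100)
  expect_false(identical(s1$intensity, s3$intensity))

  expect_error(metabolite_spec("Bad", peak_shape(11.5, "s")), "outside")
  expect_error(generate_polar_spectrum(specs, conc * 0, cfg, seed = 1),
               "positive")
  expect_error(peak_shape(1, "s", halfwidth_ppm = 0), "halfwidth")
})

test_that("apolar spectra obey the region stoichiometry", {
  cfg <- cohort_config(grid_points = 16384, noise_sd = 0)
  win <- default_region_windows()
  integ <- function(sp, reg) {
    idx <- sp$ppm >= win[[reg]][1] & sp$ppm <= win[[reg]][2]
    abs(pracma::trapz(rev(sp$ppm[idx]), rev(sp$intensity[idx])))
  }
  # no DHA -> F' window empty
  sp0 <- generate_apolar_spectrum(lipid_composition(60, 40, 20, 0), cfg, seed = 1)
  expect_lt(integ(sp0, "Fprime"), 0.02 * integ(sp0, "F"))
  # fully saturated -> E, G, J all empty
  ssat <- generate_apolar_spectrum(lipid_composition(0, 100, 0, 0), cfg, seed = 1)
  for (reg in c("E", "G", "J")) {
    expect_lt(integ(ssat, reg), 1e-3 * integ(ssat, "B"))
  }
  # A/(A+B) tracks the omega-3 fraction (up to Lorentzian tail leakage)
  for (w3 in c(5, 20, 45)) {
    sp <- generate_apolar_spectrum(lipid_composition(60, 40, w3, 1), cfg, seed = 1)
    ratio <- 100 * integ(sp, "A") / (integ(sp, "A") + integ(sp, "B"))
    expect_equal(ratio, w3, tolerance = 0.2)
  }
  expect_error(lipid_composition(60, 41, 20, 2), "100")
  expect_error(lipid_composition(60, 40, 20, 25), "dha")
})

test_that("cohorts have the configured size, labels and sex effects", {
  cfg <- test_cohort_config(seed = 5)
  sim <- generate_cohort(cfg, make_shift_panel(6, effects = c("2" = 1.5), cv = 0.1))
  expect_equal(nrow(sim$meta), 37)
  expect_equal(sum(sim$meta$sex == "male"), 23)
  expect_equal(sum(sim$meta$sex == "female"), 14)
  expect_named(sim$meta, c("id", "sex", "site", "diameter_mm", "height_mm",
                           "weight_g", "gonad_g", "gsi_pct"))
  # seeded fold change shows up in the true concentrations
  cm <- colMeans(sim$concentrations[sim$meta$sex == "male", ])
  cf <- colMeans(sim$concentrations[sim$meta$sex == "female", ])
  expect_gt(cf[2] / cm[2], 2^1.0)          # target 2^1.5 with cv 0.1
  expect_lt(max(abs(log2(cf[-2] / cm[-2]))), 0.5)

  # determinism at cohort level
  sim2 <- generate_cohort(cfg, make_shift_panel(6, effects = c("2" = 1.5), cv = 0.1))
  expect_identical(sim$spectra[[10]]$intensity, sim2$spectra[[10]]$intensity)
  expect_identical(sim$meta, sim2$meta)

  # minimal cohort
  tiny <- generate_cohort(cohort_config(n_male = 1, n_female = 1,
                                        grid_points = 2048),
                          make_shift_panel(3))
  expect_equal(nrow(tiny$meta), 2)
  expect_length(tiny$spectra, 2)
})

test_that("null cohorts give chance-level cross-validated discrimination", {
  panel <- make_shift_panel(20)              # every sex_log2fc is zero
  aucs <- vapply(1:20, function(r) {
    cfg <- cohort_config(n_male = 18, n_female = 18, seed = 4000 + r,
                         noise_sd = 0.3, grid_points = 4096)
    sim <- generate_cohort(cfg, panel)
    H <- cohort_height_matrix(sim, 20)
    y <- factor(sim$meta$sex, levels = c("male", "female"))
    cross_validate(H, y, scaling_spec("auto"), A_max = 2, k = 6,
                   seed = r)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})
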