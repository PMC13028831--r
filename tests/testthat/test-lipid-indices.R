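test_that("region integration matches the analytic Lorentzian oracle", {
  ppm <- seq(11, -0.5, length.out = 32768)
  hw <- 0.003
  ity <- (hw / pi) / ((ppm - 2.80)^2 + hw^2)      # unit-area line centred in G
  sp <- spectrum1d(ppm, ity, solvent = "cdcl3", reference = "residual_solvent")
  ri <- integrate_regions(sp)
  win <- default_region_windows()
  expect_equal(ri[["G"]],
               lorentz_window_area(2.80, hw, win$G[1], win$G[2]),
               tolerance = 0.02)
  expect_equal(ri[["G"]], 1, tolerance = 0.02)
  others <- setdiff(names(win), "G")
  expect_true(all(abs(ri[others]) < 0.01))
  # zero spectrum -> all zero integrals
  z <- integrate_regions(spectrum1d(ppm, rep(0, length(ppm))))
  expect_true(all(z == 0))
  # default F' bounds
  expect_equal(win$Fprime, c(2.37, 2.40))
  # a window fully outside the grid is absent, not zero
  narrow <- window_spectrum(sp, 2.5, 3.0)
  expect_true(is.na(integrate_regions(narrow)[["A"]]))
})

test_that("the solver honours limiting cases and conservation", {
  ri <- structure(c(A = 0, B = 300, C = 10, D = 10, E = 0, F = 10,
                    Fprime = 0, G = 0, H = 1, I = 1, J = 0),
                  class = "region_integrals")
  li <- solve_indices(ri)
  expect_equal(c(li$n_unsat, li$s_sat, li$omega3, li$dha), c(0, 100, 0, 0))
  expect_false(li$excluded)
  expect_identical(li$n_unsat + li$s_sat, 100)
  ri0 <- structure(c(A = 0, B = 0), class = "region_integrals")
  expect_error(solve_indices(ri0), "A \\+ B")
})

test_that("generator and solver round-trip a composition within 0.5 mol%", {
  cfg <- cohort_config(grid_points = 16384, noise_sd = 0)
  comp <- lipid_composition(60, 40, 20, 2)
  sp <- generate_apolar_spectrum(comp, cfg, seed = 1)
  li <- solve_indices(integrate_regions(sp))
  expect_false(li$excluded)
  expect_equal(li$n_unsat, 60, tolerance = 0.5)
  expect_equal(li$s_sat, 40, tolerance = 0.5)
  expect_equal(li$omega3, 20, tolerance = 0.5)
  expect_equal(li$dha, 2, tolerance = 0.5)
})

test_that("indices are invariant to overall intensity scaling", {
  cfg <- cohort_config(grid_points = 8192, noise_sd = 0)
  comp <- lipid_composition(55, 45, 18, 1.5)
  li1 <- solve_indices(integrate_regions(
    generate_apolar_spectrum(comp, cfg, seed = 2)))
  li37 <- solve_indices(integrate_regions(
    generate_apolar_spectrum(comp, cfg, seed = 2, scale = 37)))
  expect_equal(li1$n_unsat, li37$n_unsat, tolerance = 1e-9)
  expect_equal(li1$omega3, li37$omega3, tolerance = 1e-9)
  expect_equal(li1$dha, li37$dha, tolerance = 1e-9)
})

test_that("QC flags each violated constraint and never throws", {
  li <- structure(list(n_unsat = 50, s_sat = 50, omega3 = 3, dha = 5,
                       qc_flags = character(), excluded = FALSE,
                       spectrum_id = "bad"),
                  class = "lipid_indices")
  ri <- structure(c(A = 10, B = 90, E = 80, Fprime = 1, J = 100),
                  class = "region_integrals")
  out <- qc_check(li, ri)
  expect_true(out$excluded)
  expect_true("dha_exceeds_omega3" %in% out$qc_flags)
  # clean case
  li2 <- structure(list(n_unsat = 50, s_sat = 50, omega3 = 20, dha = 2,
                        qc_flags = character(), excluded = FALSE,
                        spectrum_id = "ok"),
                   class = "lipid_indices")
  expect_length(qc_check(li2, ri)$qc_flags, 0)
  # negative integral and double-bond inconsistency
  ri_neg <- structure(c(A = 10, B = 90, E = 80, Fprime = 1, J = 10),
                      class = "region_integrals")
  out2 <- qc_check(li2, ri_neg)
  expect_true("db_inconsistent" %in% out2$qc_flags)
  ri_neg2 <- structure(c(A = 10, B = 90, E = -5, Fprime = 1, J = 100),
                       class = "region_integrals")
  expect_true(any(grepl("negative_integral", qc_check(li2, ri_neg2)$qc_flags)))
})

test_that("batch summaries separate sexes and benchmark against fish oils", {
  # identical results -> zero-width IQR
  cfg <- cohort_config(grid_points = 8192, noise_sd = 0)
  li <- solve_indices(integrate_regions(
    generate_apolar_spectrum(lipid_composition(60, 40, 20, 2), cfg, seed = 1)))
  batch <- rep(list(li), 6)
  s <- summarize_batch(batch, rep(c("male", "female"), 3))
  expect_equal(s$summary$q1, s$summary$q3)
  # sea-urchin-like DHA sits below the fish-oil range
  dha_row <- s$benchmark[s$benchmark$index == "dha", ]
  expect_equal(dha_row$position, "below_range")
  expect_equal(dha_row$ref_low, 7.0)
  expect_equal(dha_row$ref_high, 19.2)
  w3_row <- s$benchmark[s$benchmark$index == "omega3", ]
  expect_equal(w3_row$ref_median, 26.7)
  # all-excluded batch errors out
  bad <- li; bad$excluded <- TRUE; bad$qc_flags <- "dha_exceeds_omega3"
  expect_error(summarize_batch(list(bad, bad), c("male", "female")),
               "empty batch")
})

test_that("round-trip holds across a grid of compositions", {
  cfg <- cohort_config(grid_points = 8192, noise_sd = 0)
  set.seed(60)
  grid <- expand.grid(n = c(20, 45, 61.6, 80), w3_frac = c(0.15, 0.35),
                      dha_frac = c(0.02, 0.10))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; w3 <- n * grid$w3_frac[i]; dha <- w3 * grid$dha_frac[i]
    comp <- lipid_composition(n, 100 - n, w3, dha)
    li <- solve_indices(integrate_regions(
      generate_apolar_spectrum(comp, cfg, seed = i)))
    expect_false(li$excluded)
    expect_lt(abs(li$n_unsat - n), 0.5)
    expect_lt(abs(li$omega3 - w3), 0.5)
    expect_lt(abs(li$dha - dha), 0.5)
    expect_equal(li$n_unsat + li$s_sat, 100)
  }
})
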