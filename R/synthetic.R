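#' Lorentzian peak shape for synthetic multiplets
#'
#' Describes one resonance: centre, multiplicity, coupling and linewidth.
#' The default half-width at half-maximum (0.003 ppm, i.e. ~1.2 Hz at a
#' 400 MHz field) reflects an exponential line broadening of a few tenths
#' of a Hz on top of natural linewidth; the default splitting corresponds
#' to a typical 3J(H,H) of 7 Hz (7/400 = 0.0175 ppm).
#'
#' @param center_ppm Chemical shift of the multiplet centre (ppm).
#' @param multiplicity One of `"s"`, `"d"`, `"t"`, `"m"` (an `"m"` is
#'   rendered as an unresolved 5-stick binomial cluster).
#' @param J_ppm Coupling splitting in ppm (ignored for singlets).
#' @param halfwidth_ppm Lorentzian HWHM (ppm), must be > 0.
#' @param protons Number of protons contributing to the multiplet area.
#' @return A `peak_shape` list.
#' @export
peak_shape <- function(center_ppm, multiplicity = c("s", "d", "t", "m"),
                       J_ppm = 0.0175, halfwidth_ppm = 0.003, protons = 1) {
  multiplicity <- match.arg(multiplicity)
  if (halfwidth_ppm <= 0) stop("halfwidth_ppm must be > 0", call. = FALSE)
  if (protons < 1) stop("protons must be >= 1", call. = FALSE)
  if (J_ppm < 0) stop("J_ppm must be >= 0", call. = FALSE)
  structure(list(center_ppm = center_ppm, multiplicity = multiplicity,
                 J_ppm = J_ppm, halfwidth_ppm = halfwidth_ppm,
                 protons = protons),
            class = "peak_shape")
}

#' Metabolite specification for the polar-spectrum generator
#'
#' @param name Metabolite label (conventionally from the bundled polar table).
#' @param peaks List of [peak_shape()] objects.
#' @param base_conc Mean relative concentration (a.u.), > 0.
#' @param sex_log2fc Log2 fold change, female relative to male.
#' @param cv_biological Coefficient of variation of the log-normal
#'   inter-individual concentration factor (>= 0).
#' @return A `metabolite_spec` list.
#' @export
metabolite_spec <- function(name, peaks, base_conc = 1, sex_log2fc = 0,
                            cv_biological = 0.3) {
  if (base_conc <= 0) stop("base_conc must be > 0", call. = FALSE)
  if (cv_biological < 0) stop("cv_biological must be >= 0", call. = FALSE)
  if (inherits(peaks, "peak_shape")) peaks <- list(peaks)
  centers <- vapply(peaks, `[[`, numeric(1), "center_ppm")
  if (any(centers < -0.5 | centers > 11.0)) {
    stop("peak centre outside the global window (-0.5 to 11.0 ppm)",
         call. = FALSE)
  }
  structure(list(name = name, peaks = peaks, base_conc = base_conc,
                 sex_log2fc = sex_log2fc, cv_biological = cv_biological),
            class = "metabolite_spec")
}

#' Acyl-chain composition driving the apolar generator
#'
#' Mol% composition per 100 acyl chains. Invariants: `n_unsat + s_sat`
#' is exactly 100 and `0 <= dha <= omega3 <= n_unsat <= 100`.
#'
#' @param n_unsat Mol% unsaturated chains.
#' @param s_sat Mol% saturated chains.
#' @param omega3 Mol% omega-3 chains.
#' @param dha Mol% DHA chains.
#' @param mean_db_per_unsat_chain Mean number of double bonds per
#'   unsaturated chain (>= 1).
#' @param glyceride_fraction Fraction of chains esterified on glycerol.
#' @return A `lipid_composition` list.
#' @export
lipid_composition <- function(n_unsat, s_sat, omega3, dha,
                              mean_db_per_unsat_chain = 2.5,
                              glyceride_fraction = 0.9) {
  if (abs(n_unsat + s_sat - 100) > 1e-9) {
    stop("n_unsat + s_sat must equal 100", call. = FALSE)
  }
  if (!(dha >= 0 && dha <= omega3 && omega3 <= n_unsat && n_unsat <= 100)) {
    stop("composition must satisfy 0 <= dha <= omega3 <= n_unsat <= 100",
         call. = FALSE)
  }
  if (mean_db_per_unsat_chain < 1) {
    stop("mean_db_per_unsat_chain must be >= 1", call. = FALSE)
  }
  if (glyceride_fraction < 0 || glyceride_fraction > 1) {
    stop("glyceride_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_unsat = n_unsat, s_sat = s_sat, omega3 = omega3, dha = dha,
                 mean_db_per_unsat_chain = mean_db_per_unsat_chain,
                 glyceride_fraction = glyceride_fraction),
            class = "lipid_composition")
}

#' Cohort configuration for synthetic studies
#'
#' Defaults emulate the study cohort: 23 males and 14 females on a 32k-point
#' grid over 11.0 to -0.5 ppm, with per-sex biometrics drawn from the
#' published cohort summaries.
#'
#' @param n_male,n_female Per-sex sample counts (>= 1).
#' @param seed Integer RNG seed for the cohort.
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param baseline_amp Amplitude of a random low-order polynomial baseline.
#' @param grid_points Number of spectral points (>= 1024).
#' @param biometrics_model Per-sex `mean`/`sd` for biometrics, see
#'   [default_biometrics_model()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_male = 23, n_female = 14, seed = 1,
                          noise_sd = 0.5, baseline_amp = 0,
                          grid_points = 32768,
                          biometrics_model = default_biometrics_model()) {
  if (n_male < 1 || n_female < 1) stop("need at least one sample per sex",
                                       call. = FALSE)
  if (grid_points < 1024) stop("grid_points must be >= 1024", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 baseline_amp = baseline_amp,
                 grid_points = as.integer(grid_points),
                 biometrics_model = biometrics_model),
            class = "cohort_config")
}

#' Per-sex biometrics distributions (mean, sd)
#'
#' Means and standard deviations of test diameter (mm), test height (mm),
#' total wet weight (g), gonad weight (g) and gonadosomatic index (%) used
#' to draw synthetic cohort metadata, matching the published cohort summary.
#'
#' @return Nested list `male`/`female` of `c(mean, sd)` pairs.
#' @export
default_biometrics_model <- function() {
  list(
    male = list(diameter_mm = c(48.7, 6.5), height_mm = c(27.5, 3.7),
                weight_g = c(50.0, 15.4), gonad_g = c(4.0, 2.3),
                gsi_pct = c(7.4, 2.9)),
    female = list(diameter_mm = c(52.5, 6.5), height_mm = c(29.6, 4.2),
                  weight_g = c(54.5, 20.5), gonad_g = c(3.7, 2.7),
                  gsi_pct = c(6.5, 2.9))
  )
}

.ppm_grid <- function(grid_points) {
  seq(11.0, -0.5, length.out = grid_points)
}

# Unit-area Lorentzian evaluated only near the centre (tails beyond
# 500 half-widths carry < 0.13% of the area and are skipped for speed).
.add_lorentzian <- function(intensity, ppm, center, hw, area, radius = NULL) {
  if (area == 0) return(intensity)
  if (is.null(radius)) radius <- max(0.35, 500 * hw)
  idx <- which(abs(ppm - center) <= radius)
  if (!length(idx)) return(intensity)
  x <- ppm[idx] - center
  intensity[idx] <- intensity[idx] + area * (hw / pi) / (x^2 + hw^2)
  intensity
}

# Stick pattern (offsets, weights) for a multiplicity.
.multiplet_sticks <- function(multiplicity, J) {
  switch(multiplicity,
    s = list(off = 0, w = 1),
    d = list(off = c(-J / 2, J / 2), w = c(0.5, 0.5)),
    t = list(off = c(-J, 0, J), w = c(0.25, 0.5, 0.25)),
    m = list(off = (-2:2) * J / 2, w = c(1, 4, 6, 4, 1) / 16)
  )
}

.render_multiplet <- function(intensity, ppm, shape, area) {
  st <- .multiplet_sticks(shape$multiplicity, shape$J_ppm)
  for (k in seq_along(st$off)) {
    intensity <- .add_lorentzian(intensity, ppm,
                                 shape$center_ppm + st$off[k],
                                 shape$halfwidth_ppm, area * st$w[k])
  }
  intensity
}

#' Generate one synthetic polar spectrum
#'
#' Renders Lorentzian multiplets at the specified shifts, each multiplet's
#' total area proportional to concentration times proton count, plus a TSP
#' reference singlet at 0.00 ppm, an optional low-order polynomial baseline
#' and additive Gaussian noise. Output is bit-identical for identical seeds.
#'
#' @param specs List of [metabolite_spec()] objects.
#' @param concentrations Named (or positionally matched) numeric vector of
#'   per-metabolite concentrations (a.u., > 0).
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for noise and baseline.
#' @param sample_id Identifier stored in the spectrum.
#' @param tsp_area Area of the reference singlet (default 9, i.e. nine
#'   equivalent protons at unit concentration).
#' @return A [spectrum1d()] on the descending 11.0 to -0.5 ppm grid.
#' @export
generate_polar_spectrum <- function(specs, concentrations, cfg = cohort_config(),
                                    seed = 1, sample_id = NA_character_,
                                    tsp_area = 9) {
  if (inherits(specs, "metabolite_spec")) specs <- list(specs)
  if (length(concentrations) != length(specs)) {
    stop("need one concentration per metabolite spec", call. = FALSE)
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  ppm <- .ppm_grid(cfg$grid_points)
  intensity <- numeric(length(ppm))
  for (i in seq_along(specs)) {
    for (shape in specs[[i]]$peaks) {
      intensity <- .render_multiplet(intensity, ppm, shape,
                                     concentrations[i] * shape$protons)
    }
  }
  intensity <- .add_lorentzian(intensity, ppm, 0.0, 0.003, tsp_area)
  set.seed(seed)
  if (cfg$baseline_amp > 0) {
    u <- stats::runif(3, -1, 1)
    x <- seq(-1, 1, length.out = length(ppm))
    intensity <- intensity + cfg$baseline_amp * (u[1] + u[2] * x + u[3] * x^2)
  }
  if (cfg$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(ppm), 0, cfg$noise_sd)
  }
  spectrum1d(ppm, intensity, solvent = "aqueous_buffer", reference = "tsp",
             sample_id = sample_id)
}

# Stick centres used to render the diagnostic apolar regions; each sits
# inside its integration window (see default_region_windows()).
.apolar_stick_centers <- c(
  A = 0.9739, B = 0.8806, C = 1.2800, D = 1.6350, E = 2.0500,
  F = 2.3100, Fprime = 2.3869, G = 2.8000, H = 4.2000, I = 5.2500,
  J = 5.3750
)

# Target in-window areas per 100 acyl chains for a composition.
.apolar_region_areas <- function(comp, stoich) {
  n <- comp$n_unsat; w3 <- comp$omega3; h <- comp$dha
  db <- comp$mean_db_per_unsat_chain; gf <- comp$glyceride_fraction
  c(
    A = stoich$k_methyl * w3,
    B = stoich$k_methyl * (100 - w3),
    C = 16 * 100,
    D = 2 * 100,
    E = stoich$k_E * n,
    F = 2 * (100 - h),
    Fprime = stoich$k_Fprime * h,
    G = 2 * n * max(db - 1, 0),
    H = (4 / 3) * 100 * gf,
    I = (1 / 3) * 100 * gf,
    J = stoich$k_J * n * db
  )
}

#' Generate one synthetic apolar (lipid) spectrum
#'
#' Renders each diagnostic region (A-J and the DHA-sensitive F' window) as
#' a narrow Lorentzian whose integral *inside its integration window* equals
#' the proton-stoichiometric area implied by the composition: per 100 acyl
#' chains, A = 3 x omega3, B = 3 x (100 - omega3), E = 4 x n_unsat,
#' F' = 2 x dha, G = 2 x (db - 1) per unsaturated chain, J = 2 x total
#' double bonds, with glycerol-backbone H/I scaled by `glyceride_fraction`.
#' The stoichiometry table is shared with [solve_indices()] so that the
#' generator and the solver cannot drift apart.
#'
#' @param comp A [lipid_composition()].
#' @param cfg A [cohort_config()].
#' @param seed Integer seed for noise and baseline.
#' @param sample_id Identifier stored in the spectrum.
#' @param windows Region windows, see [default_region_windows()].
#' @param stoich Stoichiometry table, see [lipid_stoichiometry()].
#' @param halfwidth_ppm HWHM of the rendered region signals. Kept narrow
#'   (5e-4 ppm) so each window contains essentially all of its own signal.
#' @param scale Overall intensity multiplier (a.u. per chain-%).
#' @return A [spectrum1d()] in CDCl3.
#' @export
generate_apolar_spectrum <- function(comp, cfg = cohort_config(), seed = 1,
                                     sample_id = NA_character_,
                                     windows = default_region_windows(),
                                     stoich = lipid_stoichiometry(),
                                     halfwidth_ppm = 5e-4, scale = 1) {
  stopifnot(inherits(comp, "lipid_composition"))
  ppm <- .ppm_grid(cfg$grid_points)
  intensity <- numeric(length(ppm))
  areas <- .apolar_region_areas(comp, stoich) * scale
  for (reg in names(areas)) {
    if (areas[[reg]] == 0) next
    ctr <- .apolar_stick_centers[[reg]]
    shape_i <- .add_lorentzian(numeric(length(ppm)), ppm, ctr, halfwidth_ppm, 1)
    win <- windows[[reg]]
    in_win <- ppm >= win[1] & ppm <= win[2]
    if (sum(in_win) < 2L) next
    capture <- abs(pracma::trapz(ppm[in_win], shape_i[in_win]))
    if (capture <= 0) next
    intensity <- intensity + (areas[[reg]] / capture) * shape_i
  }
  # residual CHCl3 marker, outside every diagnostic window
  intensity <- .add_lorentzian(intensity, ppm, 7.26, 0.003, 1 * scale)
  set.seed(seed)
  if (cfg$baseline_amp > 0) {
    u <- stats::runif(3, -1, 1)
    x <- seq(-1, 1, length.out = length(ppm))
    intensity <- intensity + cfg$baseline_amp * (u[1] + u[2] * x + u[3] * x^2)
  }
  if (cfg$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(ppm), 0, cfg$noise_sd)
  }
  spectrum1d(ppm, intensity, solvent = "cdcl3", reference = "residual_solvent",
             sample_id = sample_id)
}

#' Default metabolite panel for synthetic polar cohorts
#'
#' A panel of common gonad metabolites at shifts taken from the bundled
#' polar table. The seven metabolites with documented sex-discriminant
#' behaviour (glycine, alanine, creatine, betaine, TMAO, histidine, lysine)
#' carry |log2 fold changes| between 0.5 and 1.0 (signs are synthetic
#' choices, not measured effect sizes); every other metabolite is null.
#'
#' @param sex_effects If `FALSE`, all `sex_log2fc` are zeroed (null panel).
#' @param cv_biological Inter-individual log-normal CV for every metabolite.
#' @return List of [metabolite_spec()] objects.
#' @export
default_polar_specs <- function(sex_effects = TRUE, cv_biological = 0.3) {
  ps <- function(...) peak_shape(...)
  fc <- function(x) if (sex_effects) x else 0
  specs <- list(
    metabolite_spec("Glycine", ps(3.5648, "s", protons = 2),
                    base_conc = 3, sex_log2fc = fc(1.0), cv_biological = cv_biological),
    metabolite_spec("Alanine", list(ps(1.4715, "d", protons = 3),
                                    ps(3.7979, "m", protons = 1)),
                    base_conc = 2, sex_log2fc = fc(-0.8), cv_biological = cv_biological),
    metabolite_spec("Creatine", ps(3.9323, "s", protons = 2),
                    base_conc = 1.5, sex_log2fc = fc(0.7), cv_biological = cv_biological),
    metabolite_spec("Betaine", list(ps(3.2298, "s", protons = 9),
                                    ps(3.9000, "s", protons = 2)),
                    base_conc = 2, sex_log2fc = fc(0.6), cv_biological = cv_biological),
    metabolite_spec("Trimethylamine oxide (TMAO)", ps(3.2488, "s", protons = 9),
                    base_conc = 1, sex_log2fc = fc(-0.6), cv_biological = cv_biological),
    metabolite_spec("Histidine", list(ps(3.1273, "t", protons = 2),
                                      ps(7.1260, "s", protons = 1)),
                    base_conc = 1, sex_log2fc = fc(0.5), cv_biological = cv_biological),
    metabolite_spec("Lysine", list(ps(3.0362, "t", protons = 2),
                                   ps(1.7280, "m", protons = 2)),
                    base_conc = 1.5, sex_log2fc = fc(-0.5), cv_biological = cv_biological),
    metabolite_spec("Taurine", ps(3.2665, "t", protons = 2),
                    base_conc = 3, cv_biological = cv_biological),
    metabolite_spec("Lactate", ps(1.3390, "d", protons = 3),
                    base_conc = 1, cv_biological = cv_biological),
    metabolite_spec("Valine", list(ps(0.9587, "d", protons = 3),
                                   ps(1.0521, "d", protons = 3)),
                    base_conc = 0.8, cv_biological = cv_biological),
    metabolite_spec("Glutamate", list(ps(2.0816, "m", protons = 2),
                                      ps(2.3570, "t", protons = 2)),
                    base_conc = 2, cv_biological = cv_biological),
    metabolite_spec("Glutamine", ps(2.1488, "m", protons = 2),
                    base_conc = 1.5, cv_biological = cv_biological),
    metabolite_spec("Threonine", ps(1.3061, "d", protons = 3),
                    base_conc = 1, cv_biological = cv_biological),
    metabolite_spec("Acetate", ps(1.9052, "s", protons = 3),
                    base_conc = 0.5, cv_biological = cv_biological),
    metabolite_spec("Choline", ps(3.2040, "s", protons = 9),
                    base_conc = 0.8, cv_biological = cv_biological),
    metabolite_spec("Methanol", ps(3.3539, "s", protons = 3),
                    base_conc = 0.4, cv_biological = cv_biological),
    metabolite_spec("Tyrosine", list(ps(6.9070, "d", protons = 2),
                                     ps(7.1850, "d", protons = 2)),
                    base_conc = 0.6, cv_biological = cv_biological),
    metabolite_spec("Phenylalanine", ps(7.2662, "m", protons = 5),
                    base_conc = 0.6, cv_biological = cv_biological),
    metabolite_spec("Uridine", list(ps(5.7910, "d", protons = 1),
                                    ps(7.8620, "d", protons = 1)),
                    base_conc = 0.5, cv_biological = cv_biological),
    metabolite_spec("Hypoxanthine", ps(8.0000, "s", protons = 1),
                    base_conc = 0.5, cv_biological = cv_biological),
    metabolite_spec("Trigonelline", list(ps(4.3665, "s", protons = 3),
                                         ps(9.1260, "s", protons = 1)),
                    base_conc = 0.4, cv_biological = cv_biological),
    metabolite_spec("Purine riboside/ribonucleotide (inosine/IMP-like)",
                    list(ps(8.2351, "s", protons = 1),
                         ps(8.3460, "s", protons = 1)),
                    base_conc = 0.5, cv_biological = cv_biological)
  )
  specs
}

# Mean-one log-normal multiplicative factor with coefficient of variation cv.
.lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a full synthetic polar cohort
#'
#' Draws sex labels (`n_male` males then `n_female` females), biometrics
#' from the per-sex model, per-sample metabolite concentrations (base
#' concentration x sex fold change x log-normal individual factor) and
#' renders one polar spectrum per sample. Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @param specs List of [metabolite_spec()]s, default [default_polar_specs()].
#' @return List with elements `meta` (data frame: id, sex, site, biometrics)
#'   and `spectra` (list of [spectrum1d()]), plus the per-sample
#'   `concentrations` matrix as ground truth.
#' @export
generate_cohort <- function(cfg = cohort_config(), specs = default_polar_specs()) {
  set.seed(cfg$seed)
  n <- cfg$n_male + cfg$n_female
  sex <- factor(c(rep("male", cfg$n_male), rep("female", cfg$n_female)),
                levels = c("male", "female"))
  id <- sprintf("SU%03d", seq_len(n))
  site <- sample(c("alicante", "javea_denia"), n, replace = TRUE)
  bm <- cfg$biometrics_model
  draw_bio <- function(field) {
    vapply(as.character(sex), function(s) {
      p <- bm[[s]][[field]]
      stats::rnorm(1, p[1], p[2])
    }, numeric(1), USE.NAMES = FALSE)
  }
  meta <- data.frame(
    id = id, sex = sex, site = site,
    diameter_mm = round(pmax(draw_bio("diameter_mm"), 30), 1),
    height_mm = round(pmax(draw_bio("height_mm"), 15), 1),
    weight_g = round(pmax(draw_bio("weight_g"), 10), 1),
    gonad_g = round(pmax(draw_bio("gonad_g"), 0.3), 2),
    gsi_pct = round(pmax(draw_bio("gsi_pct"), 1), 2),
    stringsAsFactors = FALSE
  )
  conc <- matrix(NA_real_, nrow = n, ncol = length(specs),
                 dimnames = list(id, vapply(specs, `[[`, "", "name")))
  for (j in seq_along(specs)) {
    sp <- specs[[j]]
    base <- sp$base_conc * ifelse(sex == "female", 2^sp$sex_log2fc, 1)
    conc[, j] <- base * .lnorm_factor(n, sp$cv_biological)
  }
  child_seed <- sample.int(.Machine$integer.max, n)
  spectra <- lapply(seq_len(n), function(i) {
    generate_polar_spectrum(specs, conc[i, ], cfg, seed = child_seed[i],
                            sample_id = id[i])
  })
  list(meta = meta, spectra = spectra, concentrations = conc)
}

#' Generate a synthetic apolar cohort around per-sex target compositions
#'
#' Per-sample compositions are drawn as log-normal perturbations of the
#' per-sex target (`cv` on each index), with the ordering constraints
#' `dha <= omega3 <= n_unsat` re-imposed by truncation, and one apolar
#' spectrum is rendered per sample.
#'
#' @param cfg A [cohort_config()].
#' @param male_comp,female_comp Target [lipid_composition()]s per sex.
#' @param cv Log-normal coefficient of variation applied to each index.
#' @return List with `meta` (id, sex), `spectra`, and the true per-sample
#'   `compositions` data frame.
#' @export
generate_apolar_cohort <- function(cfg = cohort_config(),
                                   male_comp = lipid_composition(66.6, 33.4, 21.6, 1.74),
                                   female_comp = lipid_composition(57.9, 42.1, 19.4, 1.52),
                                   cv = 0.05) {
  set.seed(cfg$seed)
  n <- cfg$n_male + cfg$n_female
  sex <- factor(c(rep("male", cfg$n_male), rep("female", cfg$n_female)),
                levels = c("male", "female"))
  id <- sprintf("SU%03d", seq_len(n))
  comps <- vector("list", n)
  truth <- data.frame(id = id, sex = sex, n_unsat = NA_real_,
                      omega3 = NA_real_, dha = NA_real_)
  for (i in seq_len(n)) {
    tgt <- if (sex[i] == "male") male_comp else female_comp
    nu <- min(max(tgt$n_unsat * .lnorm_factor(1, cv), 1), 99.5)
    w3 <- min(tgt$omega3 * .lnorm_factor(1, cv), nu)
    hh <- min(tgt$dha * .lnorm_factor(1, cv), w3)
    comps[[i]] <- lipid_composition(nu, 100 - nu, w3, hh,
                                    tgt$mean_db_per_unsat_chain,
                                    tgt$glyceride_fraction)
    truth$n_unsat[i] <- nu; truth$omega3[i] <- w3; truth$dha[i] <- hh
  }
  child_seed <- sample.int(.Machine$integer.max, n)
  spectra <- lapply(seq_len(n), function(i) {
    generate_apolar_spectrum(comps[[i]], cfg, seed = child_seed[i],
                             sample_id = id[i])
  })
  list(meta = data.frame(id = id, sex = sex, stringsAsFactors = FALSE),
       spectra = spectra, compositions = truth)
}
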