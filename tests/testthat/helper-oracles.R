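# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# Analytic Lorentzian area within [lo, hi] for a unit-area line at `center`.
lorentz_window_area <- function(center, hw, lo, hi) {
  (atan((hi - center) / hw) - atan((lo - center) / hw)) / pi
}

# Full-enumeration Mann-Whitney oracle for tie-free data: enumerates every
# C(n1+n2, n1) assignment of the pooled ranks to group 1.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  list(U = u_obs,
       p_two_sided = min(1, 2 * min(p_le, p_ge)),
       p_greater = p_ge)
}

# PLS1 oracle via the Krylov-subspace characterisation: the A-component
# PLS1 regression vector is the least-squares solution restricted to
# span{s, Cs, ..., C^(A-1) s} with s = X'y and C = X'X. This is an
# independent closed-form route that never touches NIPALS iterations.
pls1_krylov_oracle <- function(X, y, A) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  C <- crossprod(Xc)
  K <- matrix(0, ncol(X), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v / sqrt(sum(v^2))
    v <- C %*% K[, a]
  }
  b <- K %*% solve(crossprod(K, C %*% K), crossprod(K, s))
  list(coef = b,
       fitted = drop(Xc %*% b) + mean(y))
}

# A panel of V well-separated singlet "metabolites" for calibration and
# power studies; `effects` is a named vector peak_index -> log2 fold change.
make_shift_panel <- function(V = 50, effects = numeric(), cv = 0.3) {
  shifts <- seq(0.9, 8.9, length.out = V)
  lapply(seq_len(V), function(j) {
    lfc <- if (as.character(j) %in% names(effects)) effects[[as.character(j)]] else 0
    metabolite_spec(sprintf("M%02d", j),
                    peak_shape(shifts[j], "s", protons = 2),
                    base_conc = 1, sex_log2fc = lfc, cv_biological = cv)
  })
}

panel_peak_table <- function(V = 50) {
  data.frame(peak_no = seq_len(V), delta_ppm = seq(0.9, 8.9, length.out = V))
}

# Peak-height matrix for a generated cohort over the panel shifts.
cohort_height_matrix <- function(sim, V = 50) {
  tab <- panel_peak_table(V)
  H <- do.call(rbind, lapply(sim$spectra, extract_peak_heights, table = tab))
  rownames(H) <- sim$meta$id
  H
}

# Small, fast cohort configuration for tests (8k grid keeps each spectrum
# ~30 ms to render while preserving ~1.4e-3 ppm resolution).
test_cohort_config <- function(seed, n_male = 23, n_female = 14,
                               noise_sd = 0.3) {
  cohort_config(n_male = n_male, n_female = n_female, seed = seed,
                noise_sd = noise_sd, grid_points = 8192)
}

# Multiply the intensities inside a ppm window (used to corrupt spectra
# for QC tests).
corrupt_window <- function(sp, lo, hi, factor) {
  idx <- sp$ppm >= lo & sp$ppm <= hi
  sp$intensity[idx] <- sp$intensity[idx] * factor
  sp
}
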