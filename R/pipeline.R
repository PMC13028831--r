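#' Run configuration for the analysis pipeline
#'
#' Bundles everything one run needs: the cohort (simulated via
#' [cohort_config()] or read from `input_dir`), scaling choices, model
#' complexity, SPA settings, integration windows and the output directory.
#' Every output records the seed.
#'
#' @param mode One of `"simulate"`, `"polar"`, `"apolar"`, `"full"`.
#' @param seed Master seed; also overrides `cohort$seed`.
#' @param cohort A [cohort_config()].
#' @param specs Metabolite panel for simulation, see [default_polar_specs()].
#' @param cv_scaling,mccv_scaling [scaling_spec()]s for k-fold CV and MCCV.
#' @param A_max,k,mccv_reps,mccv_split Validation settings.
#' @param spa An [spa_config()].
#' @param windows A [default_region_windows()] list.
#' @param stoich A [lipid_stoichiometry()].
#' @param input_dir Optional directory of spectrum text files plus a
#'   `metadata.csv` (columns `id`, `sex`); `NULL` = simulate.
#' @param out_dir Optional output directory for report files.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("full", "simulate", "polar", "apolar"),
                       seed = 1,
                       cohort = cohort_config(seed = seed),
                       specs = default_polar_specs(),
                       cv_scaling = scaling_spec("pareto"),
                       mccv_scaling = scaling_spec("auto"),
                       A_max = 6, k = 7, mccv_reps = 200, mccv_split = 0.8,
                       spa = spa_config(seed = seed),
                       windows = default_region_windows(),
                       stoich = lipid_stoichiometry(),
                       input_dir = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  cohort$seed <- as.integer(seed)
  spa$seed <- as.integer(seed)
  structure(list(mode = mode, seed = as.integer(seed), cohort = cohort,
                 specs = specs, cv_scaling = cv_scaling,
                 mccv_scaling = mccv_scaling, A_max = A_max, k = k,
                 mccv_reps = mccv_reps, mccv_split = mccv_split, spa = spa,
                 windows = windows, stoich = stoich, input_dir = input_dir,
                 out_dir = out_dir),
            class = "run_config")
}

.config_hash <- function(rc) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(rc[setdiff(names(rc), c("out_dir", "input_dir"))]), f)
  substr(unname(tools::md5sum(f)), 1, 8)
}

.read_input_cohort <- function(input_dir, solvent) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("missing metadata.csv in ", input_dir, call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  files <- file.path(input_dir, paste0(meta$id, ".txt"))
  missing <- meta$id[!file.exists(files)]
  if (length(missing)) {
    stop("metadata/spectra mismatch; missing spectra for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spectra <- lapply(seq_along(files), function(i) {
    read_spectrum_text(files[i], solvent = solvent, sample_id = meta$id[i])
  })
  list(meta = meta, spectra = spectra)
}

#' Run the polar discrimination arm
#'
#' window -> reference -> full-resolution matrix and peak-height matrix ->
#' mask -> PLS-LDA fit -> k-fold CV and MCCV -> SPA on the peak-height
#' matrix -> univariate Mann-Whitney tests on the selected peaks. When
#' `rc$out_dir` is set, the tables are written as CSV plus a Markdown
#' report.
#'
#' @param rc A [run_config()].
#' @return A `polar_report` list: `n`, `model` (fit, r2x, r2y), `cv`,
#'   `mccv`, `spa` (full table), `univariate` (per selected peak), `seed`,
#'   `config_hash`.
#' @export
run_polar_arm <- function(rc = run_config()) {
  if (!is.null(rc$input_dir)) {
    inp <- .read_input_cohort(rc$input_dir, "aqueous_buffer")
    meta <- inp$meta; spectra <- inp$spectra
  } else {
    sim <- generate_cohort(rc$cohort, rc$specs)
    meta <- sim$meta; spectra <- sim$spectra
  }
  y <- factor(meta$sex, levels = c("male", "female"))
  spectra <- lapply(spectra, function(sp) {
    reference_to_tsp(window_spectrum(sp, -0.5, 11.0))
  })
  # full-resolution arm: axes shift slightly per sample after referencing,
  # so re-interpolate onto the first sample's grid
  ax <- spectra[[1]]$ppm
  spectra_common <- lapply(spectra, function(sp) {
    if (length(sp$ppm) == length(ax) && max(abs(sp$ppm - ax)) < 1e-12) return(sp)
    it <- stats::approx(sp$ppm, sp$intensity, xout = ax, rule = 2)$y
    spectrum1d(ax, it, solvent = sp$solvent, reference = sp$reference,
               sample_id = sp$sample_id)
  })
  fm <- spectra_to_matrix(spectra_common, y = y)
  fm <- suppressMessages(apply_mask(fm, default_exclusion_mask("polar")))
  fit_in <- scale_matrix(fm$X, scaling_spec("none"))
  fit <- suppressWarnings(fit_pls_nipals(fit_in$X, y, A = rc$A_max))
  apparent <- classification_metrics(y, predict(fit, fit_in$X, type = "class"),
                                     predict(fit, fit_in$X, type = "score"))
  cv <- cross_validate(fm$X, y, rc$cv_scaling, A_max = rc$A_max, k = rc$k,
                       seed = rc$seed)
  mc <- mccv(fm$X, y, rc$mccv_scaling, A_max = rc$A_max,
             split_fraction = rc$mccv_split, n_reps = rc$mccv_reps,
             seed = rc$seed)
  # peak-level arm on the curated polar table
  ptab <- load_bundled_table("polar")
  H <- do.call(rbind, lapply(spectra, extract_peak_heights, table = ptab))
  keep <- colSums(is.na(H)) == 0L
  H <- H[, keep, drop = FALSE]
  spa_res <- run_spa(H, y, rc$spa)
  spa_res$delta_ppm <- ptab$delta_ppm[keep][match(spa_res$variable,
                                                  ptab$peak_no[keep])]
  spa_res$metabolite <- ptab$metabolite[keep][match(spa_res$variable,
                                                    ptab$peak_no[keep])]
  sel <- which(spa_res$selected)
  univ <- do.call(rbind, lapply(sel, function(i) {
    v <- H[, i]
    mw <- mann_whitney(v[y == "female"], v[y == "male"])
    data.frame(variable = spa_res$variable[i],
               delta_ppm = spa_res$delta_ppm[i],
               metabolite = spa_res$metabolite[i],
               female_median = unname(mw$group_medians["x"]),
               male_median = unname(mw$group_medians["y"]),
               p_value = mw$p_two_sided, stringsAsFactors = FALSE)
  }))
  rep <- structure(list(
    n = length(y), n_male = sum(y == "male"), n_female = sum(y == "female"),
    model = list(A = fit$A, r2x = fit$r2x, r2y = fit$r2y,
                 r2x_cum = sum(fit$r2x), r2y_cum = sum(fit$r2y),
                 apparent = apparent),
    cv = cv, mccv = mc, spa = spa_res, univariate = univ,
    seed = rc$seed, config_hash = .config_hash(rc)
  ), class = "polar_report")
  if (!is.null(rc$out_dir)) .write_polar_report(rep, rc$out_dir)
  rep
}

#' Run the apolar lipid-index arm
#'
#' integrate -> solve -> QC filter -> sex-stratified summaries with
#' Mann-Whitney tests -> fish-oil benchmark block.
#'
#' @param rc A [run_config()].
#' @return An `apolar_report` list: `batch` (per-sample indices), `summary`
#'   (from [summarize_batch()]), `seed`, `config_hash`.
#' @export
run_apolar_arm <- function(rc = run_config()) {
  if (!is.null(rc$input_dir)) {
    inp <- .read_input_cohort(rc$input_dir, "cdcl3")
    meta <- inp$meta; spectra <- inp$spectra
  } else {
    sim <- generate_apolar_cohort(rc$cohort)
    meta <- sim$meta; spectra <- sim$spectra
  }
  indices <- lapply(spectra, function(sp) {
    solve_indices(integrate_regions(window_spectrum(sp, -0.5, 11.0),
                                    rc$windows), rc$stoich)
  })
  summ <- summarize_batch(indices, meta$sex)
  batch <- data.frame(
    id = meta$id, sex = meta$sex,
    n_unsat = vapply(indices, `[[`, numeric(1), "n_unsat"),
    s_sat = vapply(indices, `[[`, numeric(1), "s_sat"),
    omega3 = vapply(indices, `[[`, numeric(1), "omega3"),
    dha = vapply(indices, `[[`, numeric(1), "dha"),
    excluded = vapply(indices, `[[`, logical(1), "excluded"),
    flags = vapply(indices, function(x) paste(x$qc_flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  rep <- structure(list(batch = batch, summary = summ, seed = rc$seed,
                        config_hash = .config_hash(rc)),
                   class = "apolar_report")
  if (!is.null(rc$out_dir)) .write_apolar_report(rep, rc$out_dir)
  rep
}

.write_polar_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep$spa, file.path(out_dir, "spa_table.csv"),
                   row.names = FALSE)
  if (!is.null(rep$univariate)) {
    utils::write.csv(rep$univariate, file.path(out_dir, "univariate_table.csv"),
                     row.names = FALSE)
  }
  md <- c(
    "# Polar arm report",
    sprintf("- seed: %d, config: %s", rep$seed, rep$config_hash),
    sprintf("- n = %d (%d male / %d female)", rep$n, rep$n_male, rep$n_female),
    sprintf("- R2X per LV: %s (cum %.4f)",
            paste(sprintf("%.4f", rep$model$r2x), collapse = ", "),
            rep$model$r2x_cum),
    sprintf("- R2Y per LV: %s (cum %.4f)",
            paste(sprintf("%.4f", rep$model$r2y), collapse = ", "),
            rep$model$r2y_cum),
    sprintf("- CV (%s): optLV = %d, error_min = %.4f, sens = %.4f, spec = %.4f, AUC = %.4f",
            rep$cv$scheme, rep$cv$optLV, rep$cv$error_min, rep$cv$sensitivity,
            rep$cv$specificity, rep$cv$auc),
    sprintf("- MCCV: optLV = %d, error_min = %.4f", rep$mccv$optLV,
            rep$mccv$error_min),
    sprintf("- SPA: %d of %d variables selected (p < %.2f)",
            sum(rep$spa$selected), nrow(rep$spa),
            attr(rep$spa, "config")$alpha)
  )
  writeLines(md, file.path(out_dir, "polar_report.md"))
  invisible(out_dir)
}

.write_apolar_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep$batch, file.path(out_dir, "lipid_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$summary$summary, file.path(out_dir, "lipid_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$summary$qc_log, file.path(out_dir, "qc_log.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$summary$benchmark,
                   file.path(out_dir, "benchmark.csv"), row.names = FALSE)
  md <- c(
    "# Apolar arm report",
    sprintf("- seed: %d, config: %s", rep$seed, rep$config_hash),
    sprintf("- n used = %d, QC-excluded = %d", rep$summary$n_used,
            rep$summary$n_excluded),
    sprintf("- medians (mol%%): unsaturated %.1f, saturated %.1f, omega-3 %.1f, DHA %.2f",
            rep$summary$summary$median[rep$summary$summary$index == "n_unsat"],
            rep$summary$summary$median[rep$summary$summary$index == "s_sat"],
            rep$summary$summary$median[rep$summary$summary$index == "omega3"],
            rep$summary$summary$median[rep$summary$summary$index == "dha"])
  )
  writeLines(md, file.path(out_dir, "apolar_report.md"))
  invisible(out_dir)
}

#' Write a simulated cohort to disk
#'
#' Emits one spectrum text file per sample plus `metadata.csv`, in the
#' formats the pipeline reads back.
#'
#' @param rc A [run_config()]; `rc$out_dir` must be set.
#' @param fraction `"polar"` or `"apolar"`.
#' @return The output directory, invisibly.
#' @export
simulate_to_dir <- function(rc, fraction = c("polar", "apolar")) {
  fraction <- match.arg(fraction)
  if (is.null(rc$out_dir)) stop("rc$out_dir must be set", call. = FALSE)
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (fraction == "polar") generate_cohort(rc$cohort, rc$specs)
         else generate_apolar_cohort(rc$cohort)
  for (sp in sim$spectra) {
    write_spectrum_text(sp, file.path(rc$out_dir, paste0(sp$sample_id, ".txt")))
  }
  utils::write.csv(sim$meta, file.path(rc$out_dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(rc$out_dir)
}

.cli_usage <- function() {
  paste(
    "usage: echino-nmr <simulate|polar|apolar|full> [--seed N] [--out DIR]",
    "                  [--config FILE.yaml] [--input DIR]",
    sep = "\n"
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `polar`, `apolar`,
#' `full`. Flags: `--seed`, `--out`, `--config` (YAML overrides for cohort
#' and validation settings), `--input` (directory of measured spectra).
#' Returns an exit status (0 ok, 1 runtime error, 2 usage error) rather
#' than calling `quit()`, so it is testable in-process.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
cli_entry <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || !argv[1] %in% c("simulate", "polar", "apolar", "full")) {
    message(.cli_usage())
    return(2L)
  }
  mode <- argv[1]
  args <- argv[-1]
  opt <- list(seed = 1L, out = NULL, config = NULL, input = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--seed", "--out", "--config", "--input") ||
        i == length(args)) {
      message("unknown or incomplete flag: ", key, "\n", .cli_usage())
      return(2L)
    }
    val <- args[i + 1L]
    opt[[sub("^--", "", key)]] <- val
    i <- i + 2L
  }
  status <- tryCatch({
    ov <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
    seed <- as.integer(opt$seed)
    co_args <- ov[intersect(names(ov), c("n_male", "n_female", "noise_sd",
                                         "baseline_amp", "grid_points"))]
    cohort <- do.call(cohort_config, c(co_args, list(seed = seed)))
    spa_args <- ov[intersect(names(ov), c("n_iter", "sample_fraction",
                                          "q_vars", "inner_lv", "alpha"))]
    spa <- do.call(spa_config, c(spa_args, list(seed = seed)))
    rc_args <- ov[intersect(names(ov), c("A_max", "k", "mccv_reps",
                                         "mccv_split"))]
    rc <- do.call(run_config, c(list(mode = mode, seed = seed,
                                     cohort = cohort, spa = spa,
                                     input_dir = opt$input,
                                     out_dir = opt$out), rc_args))
    if (mode == "simulate") {
      if (is.null(rc$out_dir)) stop("simulate requires --out")
      simulate_to_dir(rc, "polar")
      message("cohort written to ", rc$out_dir)
    }
    if (mode %in% c("polar", "full")) {
      rep <- run_polar_arm(rc)
      message(sprintf("polar arm: optLV = %d, error_min = %.4f, %d SPA-selected",
                      rep$cv$optLV, rep$cv$error_min, sum(rep$spa$selected)))
    }
    if (mode %in% c("apolar", "full")) {
      rep <- run_apolar_arm(rc)
      message(sprintf("apolar arm: n used = %d, QC-excluded = %d",
                      rep$summary$n_used, rep$summary$n_excluded))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
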