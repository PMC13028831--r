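#' Diagnostic integration windows for apolar spectra
#'
#' Chemical-shift windows (ppm) of the lettered lipid regions: A (omega-3
#' terminal methyls), B (non-omega-3 terminal methyls), C (bulk methylene
#' envelope), D (beta-methylenes to carbonyl), E (allylic methylenes),
#' F (alpha-methylenes to carbonyl), F' (the narrow DHA-sensitive
#' sub-region, 2.37-2.40 ppm), G (bis-allylic methylenes), H (glycerol
#' CH2-O-CO), I (glycerol sn-2 CH-O-CO) and J (olefinic protons). Only F'
#' has an exactly stated literature window; the others are anchored to the
#' approximate motif positions and are overridable.
#'
#' @param ... Named overrides, each a `c(low_ppm, high_ppm)` pair, e.g.
#'   `region_windows(E = c(1.90, 2.20))`.
#' @return Named list of `c(low, high)` windows, class `region_windows`.
#' @export
default_region_windows <- function(...) {
  win <- list(
    A = c(0.93, 1.00), B = c(0.83, 0.93), C = c(1.20, 1.40),
    D = c(1.55, 1.72), E = c(1.95, 2.15), F = c(2.28, 2.36),
    Fprime = c(2.37, 2.40), G = c(2.70, 2.90), H = c(4.05, 4.35),
    I = c(5.20, 5.30), J = c(5.30, 5.45)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(win)) stop("unknown region: ", nm, call. = FALSE)
    if (length(ov[[nm]]) != 2L || ov[[nm]][1] >= ov[[nm]][2]) {
      stop("region ", nm, " needs c(low, high) with low < high", call. = FALSE)
    }
    win[[nm]] <- as.numeric(ov[[nm]])
  }
  structure(win, class = "region_windows")
}

#' Proton stoichiometry shared by the apolar generator and the solver
#'
#' Proton multiplicities per chain for the balance equations: 3 terminal
#' methyl protons per chain (regions A and B), 4 allylic protons per
#' unsaturated chain (region E), 2 alpha-methylene protons in the
#' DHA-sensitive F' window per DHA chain, and 2 olefinic protons per
#' double bond (region J). These are configuration, not constants, so the
#' generator and [solve_indices()] always share one table.
#'
#' @param k_methyl Terminal-methyl protons per chain (A, B).
#' @param k_E Allylic protons per unsaturated chain (E).
#' @param k_Fprime F'-window protons per DHA chain.
#' @param k_J Olefinic protons per double bond (J).
#' @return Named list, class `lipid_stoichiometry`.
#' @export
lipid_stoichiometry <- function(k_methyl = 3, k_E = 4, k_Fprime = 2, k_J = 2) {
  if (any(c(k_methyl, k_E, k_Fprime, k_J) <= 0)) {
    stop("stoichiometric multiplicities must be positive", call. = FALSE)
  }
  structure(list(k_methyl = k_methyl, k_E = k_E, k_Fprime = k_Fprime,
                 k_J = k_J),
            class = "lipid_stoichiometry")
}

#' Integrate the diagnostic apolar regions
#'
#' Plain trapezoidal integration over each region window on the native
#' chemical-shift grid (no peak fitting). A window lying entirely outside
#' the spectral grid is reported as absent (`NA`), never as zero.
#'
#' @param sp An apolar [spectrum1d()], windowed.
#' @param windows A [default_region_windows()] list (or overrides).
#' @return A `region_integrals` object: named numeric vector of integrals
#'   with the windows used and the spectrum id as attributes.
#' @export
integrate_regions <- function(sp, windows = default_region_windows()) {
  stopifnot(inherits(sp, "spectrum1d"))
  # ppm is descending; integrate on the ascending axis so sign is preserved
  vals <- vapply(names(windows), function(reg) {
    win <- windows[[reg]]
    idx <- which(sp$ppm >= win[1] & sp$ppm <= win[2])
    if (length(idx) < 2L) return(NA_real_)
    pracma::trapz(rev(sp$ppm[idx]), rev(sp$intensity[idx]))
  }, numeric(1))
  structure(vals, class = "region_integrals", windows = windows,
            spectrum_id = sp$sample_id)
}

#' Solve the balance equations for lipid-class indices
#'
#' With `T = (A + B) / k_methyl` total chains (per-area units):
#' `omega3 = 100 A / (A + B)`, `dha = 100 (F' / k_F') / T`,
#' `n_unsat = 100 (E / k_E) / T`, `s_sat = 100 - n_unsat`.
#' QC bounds are evaluated before returning (see [qc_check()]).
#'
#' @param ri A `region_integrals` object from [integrate_regions()].
#' @param stoich A [lipid_stoichiometry()] table (must match the one used
#'   to generate/acquire the data).
#' @return A `lipid_indices` object: `n_unsat`, `s_sat`, `omega3`, `dha`
#'   (mol%), `qc_flags` (character vector) and `excluded` (logical).
#' @export
solve_indices <- function(ri, stoich = lipid_stoichiometry()) {
  need <- c("A", "B")
  if (any(is.na(ri[need]))) {
    stop("regions A and B are required to define total chains", call. = FALSE)
  }
  A <- ri[["A"]]; B <- ri[["B"]]
  if (A + B <= 0) stop("undefined chains: A + B must be > 0", call. = FALSE)
  total_chains <- (A + B) / stoich$k_methyl
  omega3 <- 100 * A / (A + B)
  grab <- function(reg) if (reg %in% names(ri) && !is.na(ri[[reg]])) ri[[reg]] else NA_real_
  dha <- if (!is.na(grab("Fprime"))) 100 * (ri[["Fprime"]] / stoich$k_Fprime) / total_chains else NA_real_
  n_unsat <- if (!is.na(grab("E"))) 100 * (ri[["E"]] / stoich$k_E) / total_chains else NA_real_
  s_sat <- 100 - n_unsat
  li <- structure(
    list(n_unsat = n_unsat, s_sat = s_sat, omega3 = omega3, dha = dha,
         qc_flags = character(), excluded = FALSE,
         spectrum_id = attr(ri, "spectrum_id")),
    class = "lipid_indices"
  )
  qc_check(li, ri)
}

#' @export
print.lipid_indices <- function(x, ...) {
  cat(sprintf("<lipid_indices> n=%.2f s=%.2f omega3=%.2f dha=%.2f mol%%%s\n",
              x$n_unsat, x$s_sat, x$omega3, x$dha,
              if (x$excluded) paste0(" [EXCLUDED: ",
                                     paste(x$qc_flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' QC bound checking for solved lipid indices
#'
#' Raises named flags (never errors) for: any index outside [0, 100];
#' `dha > omega3`; `omega3 > n_unsat`; any negative region integral; and
#' the double-bond consistency violation `J / k_J < E / k_E` (fewer
#' olefinic proton-pairs than unsaturated chains). `excluded` is set when
#' any flag is raised.
#'
#' @param li A `lipid_indices` object.
#' @param ri The `region_integrals` it was solved from.
#' @param stoich The [lipid_stoichiometry()] used.
#' @return `li` with `qc_flags` and `excluded` populated.
#' @export
qc_check <- function(li, ri, stoich = lipid_stoichiometry()) {
  flags <- character()
  idx <- c(n_unsat = li$n_unsat, s_sat = li$s_sat,
           omega3 = li$omega3, dha = li$dha)
  oob <- names(idx)[!is.na(idx) & (idx < 0 | idx > 100)]
  if (length(oob)) flags <- c(flags, paste0("out_of_range:", oob))
  if (!is.na(li$dha) && !is.na(li$omega3) && li$dha > li$omega3) {
    flags <- c(flags, "dha_exceeds_omega3")
  }
  if (!is.na(li$omega3) && !is.na(li$n_unsat) && li$omega3 > li$n_unsat) {
    flags <- c(flags, "omega3_exceeds_unsat")
  }
  neg <- names(ri)[!is.na(ri) & ri < 0]
  if (length(neg)) flags <- c(flags, paste0("negative_integral:", neg))
  if (all(c("J", "E") %in% names(ri)) && !anyNA(ri[c("J", "E")])) {
    if (ri[["J"]] / stoich$k_J < ri[["E"]] / stoich$k_E) {
      flags <- c(flags, "db_inconsistent")
    }
  }
  li$qc_flags <- flags
  li$excluded <- length(flags) > 0
  li
}

#' Fish-oil benchmark reference values
#'
#' Published fish-oil ranges used to benchmark batches: DHA spans about
#' 7.0-19.2 mol% (median ~14.0) and total omega-3 about 20.9-35.7 mol%
#' (median ~26.7).
#'
#' @return Data frame with index, low, high, median columns.
#' @export
fish_oil_reference <- function() {
  data.frame(
    index = c("dha", "omega3"),
    low = c(7.0, 20.9),
    high = c(19.2, 35.7),
    median = c(14.0, 26.7),
    stringsAsFactors = FALSE
  )
}

#' Summarize a batch of lipid indices with sex comparisons and benchmarks
#'
#' Excluded (QC-flagged) results are dropped first; the QC log lists each
#' flagged spectrum with its violated constraints. For every index the
#' summary reports median and IQR overall and per sex, a two-sided
#' Mann-Whitney p-value (female vs male), and a benchmark block placing the
#' batch median relative to the fish-oil reference ranges.
#'
#' @param indices List of `lipid_indices` objects.
#' @param sex Factor/character of `"male"`/`"female"` labels, same length.
#' @return A list: `summary` (data frame), `qc_log` (data frame),
#'   `benchmark` (data frame), `n_used`, `n_excluded`.
#' @export
summarize_batch <- function(indices, sex) {
  stopifnot(length(indices) == length(sex))
  sex <- factor(sex, levels = c("male", "female"))
  excluded <- vapply(indices, `[[`, logical(1), "excluded")
  qc_log <- data.frame(
    spectrum_id = vapply(indices, function(x) x$spectrum_id %||% NA_character_,
                         character(1)),
    excluded = excluded,
    flags = vapply(indices, function(x) paste(x$qc_flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE
  )
  keep <- !excluded
  if (!any(keep)) stop("empty batch: every spectrum was QC-excluded",
                       call. = FALSE)
  vals <- do.call(rbind, lapply(indices[keep], function(x) {
    c(n_unsat = x$n_unsat, s_sat = x$s_sat, omega3 = x$omega3, dha = x$dha)
  }))
  sx <- sex[keep]
  row_summary <- function(v, grp = NULL) {
    vv <- if (is.null(grp)) v else v[sx == grp]
    q <- stats::quantile(vv, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
    c(median = unname(q[2]), q1 = unname(q[1]), q3 = unname(q[3]))
  }
  out <- do.call(rbind, lapply(colnames(vals), function(ix) {
    v <- vals[, ix]
    mw_p <- if (nlevels(droplevels(sx)) == 2L) {
      mann_whitney(v[sx == "female"], v[sx == "male"])$p_two_sided
    } else NA_real_
    data.frame(
      index = ix,
      t(row_summary(v)),
      female_median = row_summary(v, "female")[["median"]],
      male_median = row_summary(v, "male")[["median"]],
      p_value = mw_p,
      stringsAsFactors = FALSE
    )
  }))
  ref <- fish_oil_reference()
  bench <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    ix <- ref$index[i]
    med <- out$median[out$index == ix]
    pos <- if (med < ref$low[i]) "below_range"
           else if (med > ref$high[i]) "above_range" else "within_range"
    data.frame(index = ix, batch_median = med, ref_low = ref$low[i],
               ref_high = ref$high[i], ref_median = ref$median[i],
               position = pos, stringsAsFactors = FALSE)
  }))
  list(summary = out, qc_log = qc_log, benchmark = bench,
       n_used = sum(keep), n_excluded = sum(excluded))
}
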