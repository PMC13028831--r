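#' One-dimensional frequency-domain NMR spectrum
#'
#' A `spectrum1d` holds a processed, frequency-domain 1D proton spectrum:
#' a strictly monotone *descending* chemical-shift axis (ppm) and the
#' matching intensity trace (arbitrary units), plus minimal acquisition
#' metadata (solvent and referencing standard).
#'
#' @param ppm Numeric chemical-shift axis in ppm. Any strictly monotone
#'   axis is accepted; it is stored in descending order.
#' @param intensity Numeric intensity vector, same length as `ppm`.
#' @param solvent One of `"aqueous_buffer"` (polar extracts, phosphate
#'   buffer/D2O) or `"cdcl3"` (apolar extracts).
#' @param reference Referencing standard: `"tsp"` (0.00 ppm, aqueous) or
#'   `"residual_solvent"` (CDCl3).
#' @param sample_id Sample identifier string.
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity,
                       solvent = c("aqueous_buffer", "cdcl3"),
                       reference = c("tsp", "residual_solvent"),
                       sample_id = NA_character_) {
  solvent <- match.arg(solvent)
  reference <- match.arg(reference)
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  if (length(ppm) < 2L) {
    stop("a spectrum needs at least two points", call. = FALSE)
  }
  if (!all(is.finite(ppm)) || !all(is.finite(intensity))) {
    stop("non-finite values in spectrum", call. = FALSE)
  }
  d <- diff(ppm)
  if (all(d > 0)) {          # ascending export: normalize orientation
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("chemical-shift axis is not strictly monotone", call. = FALSE)
  }
  structure(
    list(ppm = ppm, intensity = intensity, solvent = solvent,
         reference = reference, sample_id = sample_id),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s: %d points, %.4f to %.4f ppm [%s, ref %s]\n",
              ifelse(is.na(x$sample_id), "(unnamed)", x$sample_id),
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              x$solvent, x$reference))
  invisible(x)
}

#' Read a two-column text spectrum
#'
#' Parses whitespace- or comma-separated `(ppm, intensity)` text exports.
#' Lines starting with `#` are treated as comments; metadata written by
#' [write_spectrum_text()] (`# sample_id:`, `# solvent:`, `# reference:`)
#' is recovered when present. The axis is normalized to descending ppm.
#'
#' @param path Path to the text file.
#' @param solvent,reference,sample_id Overrides for metadata not present in
#'   the file header (`NULL` = use header or defaults).
#' @return A [spectrum1d()].
#' @export
read_spectrum_text <- function(path, solvent = NULL, reference = NULL,
                               sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", raw)
  hdr <- raw[is_comment]
  grab <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:"), "", m[1]))
  }
  if (is.null(sample_id)) sample_id <- grab("sample_id") %||% NA_character_
  if (is.null(solvent))   solvent   <- grab("solvent")   %||% "aqueous_buffer"
  if (is.null(reference)) reference <- grab("reference") %||%
      if (identical(solvent, "cdcl3")) "residual_solvent" else "tsp"

  keep <- !is_comment & nzchar(trimws(raw))
  lineno <- which(keep)
  body <- gsub("[,;]", " ", raw[keep])
  parts <- strsplit(trimws(body), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop(sprintf("parse error at line %d: expected two numeric columns",
                 lineno[which(nf < 2L)[1]]), call. = FALSE)
  }
  ppm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  ity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(ppm) | !is.finite(ity))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-numeric value", lineno[bad[1]]),
         call. = FALSE)
  }
  ord <- order(ppm, decreasing = TRUE)
  ppm <- ppm[ord]; ity <- ity[ord]
  if (anyDuplicated(ppm)) {
    stop("format error: chemical-shift axis not monotone (duplicate ppm values)",
         call. = FALSE)
  }
  spectrum1d(ppm, ity, solvent = solvent, reference = reference,
             sample_id = sample_id)
}

#' Write a spectrum as two-column text
#'
#' The inverse of [read_spectrum_text()]: metadata goes into `#` header
#' lines, data into two whitespace-separated columns at full double
#' precision (round trips to < 1e-9).
#'
#' @param sp A [spectrum1d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_text <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum1d"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id: %s", sp$sample_id),
    sprintf("# solvent: %s", sp$solvent),
    sprintf("# reference: %s", sp$reference),
    sprintf("%.12e %.12e", sp$ppm, sp$intensity)
  ), con)
  invisible(path)
}

#' Restrict a spectrum to a chemical-shift window
#'
#' Keeps points with `low_ppm <= ppm <= high_ppm`. The defaults are the
#' standard processing window -0.5 to 11.0 ppm.
#'
#' @param sp A [spectrum1d()].
#' @param low_ppm,high_ppm Window bounds (ppm), `low_ppm < high_ppm`.
#' @return The windowed [spectrum1d()].
#' @export
window_spectrum <- function(sp, low_ppm = -0.5, high_ppm = 11.0) {
  stopifnot(inherits(sp, "spectrum1d"))
  if (!(low_ppm < high_ppm)) {
    stop("invalid window: low_ppm must be < high_ppm", call. = FALSE)
  }
  keep <- sp$ppm >= low_ppm & sp$ppm <= high_ppm
  if (sum(keep) < 2L) {
    stop("degenerate window: fewer than two points retained", call. = FALSE)
  }
  spectrum1d(sp$ppm[keep], sp$intensity[keep], solvent = sp$solvent,
             reference = sp$reference, sample_id = sp$sample_id)
}

#' Reference the axis to the TSP singlet at 0.00 ppm
#'
#' Locates the apex of the internal standard within `+/- search_halfwidth_ppm`
#' of 0 ppm and shifts the axis so that apex sits at 0.00 ppm. If two grid
#' points tie for the maximum, the more downfield (higher-ppm) candidate is
#' used; this tie-break is deterministic and part of the contract. The apex
#' must be a local maximum (not a window edge), otherwise referencing fails.
#'
#' @param sp Aqueous [spectrum1d()] containing a dominant standard peak near 0.
#' @param search_halfwidth_ppm Search half-window around 0 ppm (default 0.05).
#' @return The re-referenced [spectrum1d()].
#' @export
reference_to_tsp <- function(sp, search_halfwidth_ppm = 0.05) {
  stopifnot(inherits(sp, "spectrum1d"))
  if (search_halfwidth_ppm <= 0) stop("search_halfwidth_ppm must be > 0",
                                      call. = FALSE)
  idx <- which(abs(sp$ppm) <= search_halfwidth_ppm)
  if (length(idx) < 3L) {
    stop("referencing error: too few points near 0 ppm", call. = FALSE)
  }
  mx <- max(sp$intensity[idx])
  cand <- idx[sp$intensity[idx] == mx]
  apex <- min(cand)                      # ppm is descending: min index = most downfield
  if (apex == min(idx) || apex == max(idx)) {
    stop("referencing error: no local maximum inside the search window",
         call. = FALSE)
  }
  shift <- sp$ppm[apex]
  spectrum1d(sp$ppm - shift, sp$intensity, solvent = sp$solvent,
             reference = sp$reference, sample_id = sp$sample_id)
}

#' Exclusion mask for non-informative spectral regions
#'
#' A set of `(low_ppm, high_ppm)` intervals to drop from feature matrices
#' before supervised modelling (residual water, internal standard, residual
#' solvent). Overlapping regions are allowed; removal uses union semantics.
#'
#' @param low_ppm,high_ppm Numeric vectors of equal length; `low < high`
#'   elementwise.
#' @return An `exclusion_mask` data frame.
#' @export
exclusion_mask <- function(low_ppm = numeric(), high_ppm = numeric()) {
  low_ppm <- as.numeric(low_ppm); high_ppm <- as.numeric(high_ppm)
  if (length(low_ppm) != length(high_ppm)) {
    stop("low_ppm and high_ppm must have equal length", call. = FALSE)
  }
  if (any(low_ppm >= high_ppm)) {
    stop("each mask region needs low_ppm < high_ppm", call. = FALSE)
  }
  structure(data.frame(low_ppm = low_ppm, high_ppm = high_ppm),
            class = c("exclusion_mask", "data.frame"))
}

#' Default exclusion masks
#'
#' Polar spectra: residual water (4.70-5.00 ppm) and the TSP standard
#' (+/- 0.05 ppm around 0). Apolar spectra: residual CHCl3 (7.24-7.30 ppm).
#' Bounds are conventional defaults and overridable.
#'
#' @param fraction `"polar"` or `"apolar"`.
#' @return An [exclusion_mask()].
#' @export
default_exclusion_mask <- function(fraction = c("polar", "apolar")) {
  fraction <- match.arg(fraction)
  if (fraction == "polar") {
    exclusion_mask(c(4.70, -0.05), c(5.00, 0.05))
  } else {
    exclusion_mask(7.24, 7.30)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
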