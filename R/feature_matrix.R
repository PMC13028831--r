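#' Samples-by-variables feature matrix
#'
#' Container for the chemometric input: an `n x V` intensity matrix whose
#' columns are either full-resolution spectral points (labelled by ppm) or
#' annotated peak heights (labelled by peak number), together with binary
#' class labels (`"male"`/`"female"`) and sample identifiers.
#'
#' @param X Numeric matrix, samples in rows.
#' @param var_ppm Numeric chemical-shift label per column (ppm).
#' @param y Factor (or coercible) of class labels with levels
#'   `c("male", "female")`; may be `NULL` for unsupervised use.
#' @param sample_ids Character ids, default taken from `rownames(X)`.
#' @param var_label Optional character labels per column (e.g. peak numbers);
#'   defaults to formatted ppm values.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(X, var_ppm, y = NULL, sample_ids = rownames(X),
                           var_label = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  var_ppm <- as.numeric(var_ppm)
  if (length(var_ppm) != ncol(X)) {
    stop("var_ppm must have one entry per column of X", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(nrow(X)))
  if (!is.null(y)) {
    y <- factor(y, levels = c("male", "female"))
    if (length(y) != nrow(X)) stop("y must have one label per row", call. = FALSE)
    if (anyNA(y)) stop("y labels must be 'male' or 'female'", call. = FALSE)
  }
  if (is.null(var_label)) var_label <- sprintf("%.4f", var_ppm)
  colnames(X) <- var_label
  rownames(X) <- sample_ids
  structure(list(X = X, var_ppm = var_ppm, var_label = var_label,
                 y = y, sample_ids = sample_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d variables", nrow(x$X), ncol(x$X)))
  if (!is.null(x$y)) {
    tb <- table(x$y)
    cat(sprintf(" (male %d / female %d)", tb[["male"]], tb[["female"]]))
  }
  cat("\n")
  invisible(x)
}

#' Stack spectra into a full-resolution feature matrix
#'
#' All spectra must share an identical chemical-shift axis (as produced by
#' the generator, or by windowing a common export grid).
#'
#' @param spectra List of [spectrum1d()] objects on a common axis.
#' @param y Optional class labels, see [feature_matrix()].
#' @return A [feature_matrix()] with one row per spectrum.
#' @export
spectra_to_matrix <- function(spectra, y = NULL) {
  stopifnot(length(spectra) >= 1L)
  ax <- spectra[[1]]$ppm
  for (sp in spectra) {
    if (length(sp$ppm) != length(ax) || max(abs(sp$ppm - ax)) > 1e-9) {
      stop("spectra are not on a common chemical-shift axis", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (anyNA(ids)) ids <- sprintf("S%02d", seq_along(spectra))
  feature_matrix(X, var_ppm = ax, y = y, sample_ids = ids)
}

#' Drop masked variables from a feature matrix
#'
#' Removes every column whose ppm label falls inside any region of the
#' mask (union semantics over possibly overlapping regions).
#'
#' @param fm A [feature_matrix()].
#' @param mask An [exclusion_mask()].
#' @return The filtered [feature_matrix()]; the number of removed columns
#'   is reported via `message()`.
#' @export
apply_mask <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(mask, "exclusion_mask"))
  drop <- rep(FALSE, length(fm$var_ppm))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (fm$var_ppm >= mask$low_ppm[i] & fm$var_ppm <= mask$high_ppm[i])
  }
  if (all(drop)) stop("mask removes every variable", call. = FALSE)
  message(sprintf("apply_mask: removed %d of %d variables", sum(drop), length(drop)))
  feature_matrix(fm$X[, !drop, drop = FALSE], fm$var_ppm[!drop], y = fm$y,
                 sample_ids = fm$sample_ids, var_label = fm$var_label[!drop])
}
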