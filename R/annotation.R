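#' Curated peak tables for polar and apolar gonad extracts
#'
#' Loads the bundled, versioned annotation tables: 72 polar resonances
#' (chemical shift, multiplicity, metabolite, moiety) and 29 apolar lipid
#' resonances (chemical shift, moiety, lipid class, assignment). The CSVs
#' are checksummed at load time; a mismatch raises an integrity error.
#'
#' Two derived columns are added:
#' \describe{
#'   \item{confidence}{`assigned`, `tentative`, `putative` or `unassigned`,
#'     parsed from the metabolite label (polar only): "Unassigned" or
#'     ".../unassigned" -> unassigned; "(tentative)", "(probable)" or a
#'     "-like" qualifier -> tentative; "(putative)" -> putative.}
#'   \item{mult_class}{multiplicity normalized to `{s, d, t, m, dm, sm,
#'     unknown}` (polar only).}
#' }
#'
#' @param fraction `"polar"` or `"apolar"`.
#' @return A `peak_table` data frame (attribute `fraction` records which).
#' @export
load_bundled_table <- function(fraction = c("polar", "apolar")) {
  fraction <- match.arg(fraction)
  fname <- paste0(fraction, "_peak_table.csv")
  path <- system.file("extdata", fname, package = "echinoNMR")
  if (!nzchar(path)) stop("bundled table not found: ", fname, call. = FALSE)
  want <- .peak_table_md5[[fraction]]
  got <- unname(tools::md5sum(path))
  if (!identical(got, want)) {
    stop(sprintf("integrity error: %s checksum %s != expected %s",
                 fname, got, want), call. = FALSE)
  }
  tb <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (fraction == "polar") {
    if (nrow(tb) != 72L) stop("integrity error: polar table must have 72 rows",
                              call. = FALSE)
    tb$confidence <- .annotation_confidence(tb$metabolite)
    tb$mult_class <- .normalize_multiplicity(tb$multiplicity)
  } else {
    if (nrow(tb) != 29L) stop("integrity error: apolar table must have 29 rows",
                              call. = FALSE)
  }
  if (anyDuplicated(tb$peak_no)) stop("integrity error: duplicate peak_no",
                                      call. = FALSE)
  if (is.unsorted(tb$delta_ppm)) stop("integrity error: shifts not sorted",
                                      call. = FALSE)
  structure(tb, class = c("peak_table", "data.frame"), fraction = fraction)
}

.peak_table_md5 <- list(
  polar  = "e5ab4788ed93a4ad7ec289f00e5271b6",
  apolar = "33a82c72a272f8bce61a7e9198add6e6"
)

.annotation_confidence <- function(metabolite) {
  out <- rep("assigned", length(metabolite))
  out[grepl("\\(putative\\)", metabolite)] <- "putative"
  out[grepl("\\(tentative\\)|\\(probable\\)|-like", metabolite)] <- "tentative"
  out[grepl("unassigned", metabolite, ignore.case = TRUE)] <- "unassigned"
  out
}

.normalize_multiplicity <- function(mult) {
  m <- tolower(gsub("[()]", "", trimws(mult)))
  m[m == "d/m"] <- "dm"
  m[m == "s/m"] <- "sm"
  m[!m %in% c("s", "d", "t", "m", "dm", "sm")] <- "unknown"
  m
}

#' Extract annotated peak heights from a spectrum
#'
#' For every annotated chemical shift, the height is the maximum intensity
#' within `+/- tol_ppm` of the shift minus a local baseline, estimated as
#' the median intensity in two flanking bands (0.02 to 0.03 ppm away on
#' each side). A peak whose search window falls outside the spectral grid
#' is reported as `NA` (absent), never as zero.
#'
#' @param sp A windowed, referenced [spectrum1d()].
#' @param table A `peak_table` from [load_bundled_table()] (or any data
#'   frame with `peak_no` and `delta_ppm` columns).
#' @param tol_ppm Search half-window in ppm (default 0.005).
#' @return Named numeric vector of heights, names = `peak_no`.
#' @export
extract_peak_heights <- function(sp, table, tol_ppm = 0.005) {
  stopifnot(inherits(sp, "spectrum1d"))
  if (tol_ppm <= 0) stop("tol_ppm must be > 0", call. = FALSE)
  heights <- vapply(seq_len(nrow(table)), function(i) {
    d <- table$delta_ppm[i]
    in_win <- abs(sp$ppm - d) <= tol_ppm
    if (!any(in_win)) return(NA_real_)
    off <- abs(sp$ppm - d)
    flank <- off >= 0.02 & off <= 0.03
    base <- if (any(flank)) stats::median(sp$intensity[flank]) else 0
    max(sp$intensity[in_win]) - base
  }, numeric(1))
  names(heights) <- table$peak_no
  heights
}

#' Count unique metabolites in an annotation table
#'
#' Applies documented, deterministic collapsing rules to the metabolite
#' labels before counting distinct names:
#' \enumerate{
#'   \item rows with confidence `unassigned` are dropped;
#'   \item parenthetical qualifiers are stripped
#'     ("Isoleucine (tentative)" -> "Isoleucine");
#'   \item trailing "-like"/"-related" qualifiers are stripped
#'     ("Choline-related" -> "Choline");
#'   \item composite labels naming more than one candidate ("Xanthine
#'     and/or Tryptophan", anything still containing "/") are ambiguous
#'     and excluded from the count.
#' }
#' The function reports what the rules yield; it never forces agreement
#' with an externally claimed total.
#'
#' @param table A polar `peak_table`.
#' @param details If `TRUE`, return a list with the unique names and the
#'   excluded ambiguous labels as well as the count.
#' @return Integer count, or a list when `details = TRUE`.
#' @export
count_unique_metabolites <- function(table, details = FALSE) {
  if (!"confidence" %in% names(table)) {
    table$confidence <- .annotation_confidence(table$metabolite)
  }
  keep <- table$confidence != "unassigned"
  nm <- table$metabolite[keep]
  nm <- gsub("\\s*\\([^)]*\\)", "", nm)        # strip qualifiers
  nm <- trimws(nm)
  nm <- sub("-(like|related)$", "", nm)
  ambiguous <- grepl("and/or", nm, fixed = TRUE) | grepl("/", nm, fixed = TRUE)
  uniq <- sort(unique(nm[!ambiguous]))
  if (details) {
    list(count = length(uniq), unique_names = uniq,
         ambiguous = sort(unique(nm[ambiguous])))
  } else {
    length(uniq)
  }
}
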