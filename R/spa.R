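#' Mann-Whitney U test with exact small-sample p-values
#'
#' Wraps [stats::wilcox.test()]: when the combined sample size is at most
#' 20 and the data are tie-free, the exact permutation distribution of the
#' rank-sum statistic is used (`method = "exact"`); otherwise the mid-rank
#' normal approximation with tie correction (`method = "normal_approx"`).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param alternative `"two.sided"`, `"greater"` (x stochastically larger)
#'   or `"less"`.
#' @return An `mwu_result` list: `U` (the statistic for `x` relative to
#'   `y`, in `[0, n1*n2]`), `p_two_sided`, `p_one_sided` (for the requested
#'   or, under `"two.sided"`, the `"greater"` direction), `group_medians`,
#'   `n1`, `n2`, `method`, `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty",
                                     call. = FALSE)
  tie_free <- !anyDuplicated(c(x, y))
  exact <- tie_free && (length(x) + length(y)) <= 20L
  run <- function(alt) {
    suppressWarnings(stats::wilcox.test(
      x, y, alternative = alt, exact = exact, correct = !exact
    ))
  }
  one_dir <- if (alternative == "less") "less" else "greater"
  ht2 <- run("two.sided")
  ht1 <- run(one_dir)
  structure(list(
    U = unname(ht2$statistic),
    p_two_sided = min(ht2$p.value, 1),
    p_one_sided = min(ht1$p.value, 1),
    group_medians = c(x = stats::median(x), y = stats::median(y)),
    n1 = length(x), n2 = length(y),
    method = if (exact) "exact" else "normal_approx",
    alternative = alternative
  ), class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("<mann_whitney %s> U=%.1f p(two-sided)=%.4g p(one-sided)=%.4g (n=%d/%d)\n",
              x$method, x$U, x$p_two_sided, x$p_one_sided, x$n1, x$n2))
  invisible(x)
}

#' Conditional synergistic score from a p-value
#'
#' `COSS = -log10(p)`, monotone decreasing in p; the nominal selection
#' threshold p < 0.05 corresponds to COSS > 1.30. p-values below 1e-300
#' are clamped before taking the logarithm (finite precision).
#'
#' @param p p-value(s) in (0, 1].
#' @return Numeric COSS value(s).
#' @export
coss_transform <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]", call. = FALSE)
  -log10(pmax(p, 1e-300))
}

#' Configuration for subwindow permutation analysis
#'
#' Defaults: 1000 Monte Carlo iterations, 75% of samples per sub-model,
#' `ceiling(sqrt(V))` variables per sub-model bounded to [5, 15], two
#' inner latent variables (the validated model complexity), nominal
#' alpha 0.05.
#'
#' @param n_iter Monte Carlo iterations.
#' @param sample_fraction Fraction of samples per sub-model, in (0, 1).
#' @param q_vars Variables drawn per sub-model (`NULL` = automatic rule).
#' @param inner_lv Latent variables of each sub-model.
#' @param alpha Selection threshold on the per-variable p-value.
#' @param seed RNG seed for the whole run.
#' @return An `spa_config` list.
#' @export
spa_config <- function(n_iter = 1000, sample_fraction = 0.75, q_vars = NULL,
                       inner_lv = 2, alpha = 0.05, seed = 1) {
  if (sample_fraction <= 0 || sample_fraction >= 1) {
    stop("sample_fraction must be in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter),
                 sample_fraction = sample_fraction,
                 q_vars = q_vars, inner_lv = as.integer(inner_lv),
                 alpha = alpha, seed = as.integer(seed)),
            class = "spa_config")
}

#' Subwindow permutation analysis with COSS ranking
#'
#' Repeatedly draws a stratified sample subset and a random variable
#' subset, fits an inner PLS-LDA sub-model (autoscaled on the sub-training
#' set), and records the out-of-subset misclassification error twice: with
#' the held-out values of each included variable intact ("normal") and
#' with that variable's held-out values randomly permuted across test
#' samples ("permuted"). Normal and permuted errors are paired on
#' identical sub-models, isolating each variable's predictive
#' contribution. Per variable, the p-value is the one-sided Mann-Whitney
#' probability that permuted errors exceed normal errors, and
#' `COSS = -log10(p)`. Deterministic under `cfg$seed`.
#'
#' @param X Peak-height (or otherwise preprocessed) matrix, samples x
#'   variables.
#' @param y Class labels (`"male"`/`"female"`).
#' @param cfg An [spa_config()].
#' @return An `spa_result` data frame: one row per variable with
#'   `variable`, `p_value`, `coss`, `n_inclusions`, `mean_error_normal`,
#'   `mean_error_permuted`, `selected` (p < alpha).
#' @export
run_spa <- function(X, y, cfg = spa_config()) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("male", "female"))
  V <- ncol(X)
  q <- cfg$q_vars %||% min(15L, max(5L, ceiling(sqrt(V))))
  q <- min(q, V)
  set.seed(cfg$seed)
  err_normal <- vector("list", V)
  err_perm <- vector("list", V)
  for (it in seq_len(cfg$n_iter)) {
    train <- integer()
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_tr <- max(2L, round(cfg$sample_fraction * length(idx)))
      n_tr <- min(n_tr, length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    test <- setdiff(seq_len(nrow(X)), train)
    vars <- sample.int(V, q)
    sc <- scale_matrix(X[train, vars, drop = FALSE], scaling_spec("auto"))
    if (!length(sc$stats$keep)) next
    Xtr <- sc$X
    Xte <- scale_matrix(X[test, vars, drop = FALSE], scaling_spec("auto"),
                        train_stats = sc$stats)$X
    kept_vars <- vars[sc$stats$keep]
    fit <- suppressWarnings(fit_pls_nipals(Xtr, y[train],
                                           A = min(cfg$inner_lv, ncol(Xtr))))
    y_test <- y[test]
    pred <- predict(fit, Xte, type = "class")
    e_norm <- mean(pred != y_test)
    for (j in seq_along(kept_vars)) {
      v <- kept_vars[j]
      Xp <- Xte
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      e_perm <- mean(predict(fit, Xp, type = "class") != y_test)
      err_normal[[v]] <- c(err_normal[[v]], e_norm)
      err_perm[[v]] <- c(err_perm[[v]], e_perm)
    }
  }
  n_inc <- lengths(err_normal)
  if (any(n_inc == 0L)) {
    stop(sprintf(paste0("iteration budget too small: %d variable(s) never ",
                        "sampled; increase n_iter"), sum(n_inc == 0L)),
         call. = FALSE)
  }
  p <- vapply(seq_len(V), function(v) {
    mann_whitney(err_perm[[v]], err_normal[[v]], alternative = "greater")$p_one_sided
  }, numeric(1))
  p <- pmax(p, 1e-300)
  res <- data.frame(
    variable = colnames(X) %||% sprintf("V%d", seq_len(V)),
    p_value = p,
    coss = coss_transform(p),
    n_inclusions = n_inc,
    mean_error_normal = vapply(err_normal, mean, numeric(1)),
    mean_error_permuted = vapply(err_perm, mean, numeric(1)),
    selected = p < cfg$alpha,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("spa_result", "data.frame"), config = cfg)
}

#' Five-number boxplot statistics with 1.5 x IQR whiskers
#'
#' Quartiles use linear interpolation (type 7). Whiskers sit at the most
#' extreme data points within 1.5 x IQR beyond the quartiles; points
#' outside are listed as outliers.
#'
#' @param values Numeric vector (n >= 1).
#' @return List: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("need at least one value", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}
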