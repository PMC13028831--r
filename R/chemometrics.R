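#' Column scaling specification
#'
#' Columns are always mean-centred; optional scaling divides by the column
#' standard deviation (`"auto"`) or its square root (`"pareto"`). Scaling
#' statistics are always computed on training data only and reapplied to
#' held-out data.
#'
#' @param scale One of `"none"`, `"pareto"`, `"auto"`.
#' @return A `scaling_spec` list.
#' @export
scaling_spec <- function(scale = c("none", "pareto", "auto")) {
  structure(list(scale = match.arg(scale)), class = "scaling_spec")
}

#' Centre and scale a matrix, reusably
#'
#' When `train_stats` is supplied the stored centre/scale are applied
#' (for held-out data); otherwise statistics are computed from `X`.
#' Zero-variance columns under `auto`/`pareto` are dropped with a warning
#' rather than silently divided by zero.
#'
#' @param X Numeric matrix (samples x variables).
#' @param spec A [scaling_spec()].
#' @param train_stats Statistics from a previous call (its `stats` element).
#' @return List with `X` (scaled matrix) and `stats` (centre, scale, kept
#'   column indices, spec) reusable on new data.
#' @export
scale_matrix <- function(X, spec = scaling_spec(), train_stats = NULL) {
  X <- as.matrix(X)
  if (!is.null(train_stats)) {
    Xs <- sweep(X[, train_stats$keep, drop = FALSE], 2, train_stats$center, "-")
    Xs <- sweep(Xs, 2, train_stats$scale, "/")
    return(list(X = Xs, stats = train_stats))
  }
  ctr <- colMeans(X)
  n <- nrow(X)
  sds <- sqrt(pmax(colSums(X^2) - n * ctr^2, 0) / max(n - 1, 1))
  keep <- seq_len(ncol(X))
  scl <- rep(1, ncol(X))
  if (spec$scale != "none") {
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      warning(sprintf("dropping %d zero-variance column(s) under %s scaling",
                      sum(zero), spec$scale))
      keep <- which(!zero)
    }
    scl <- if (spec$scale == "auto") sds[keep] else sqrt(sds[keep])
  }
  ctr <- ctr[keep]
  Xs <- sweep(X[, keep, drop = FALSE], 2, ctr, "-")
  Xs <- sweep(Xs, 2, scl, "/")
  list(X = Xs, stats = list(center = ctr, scale = scl, keep = keep, spec = spec))
}

# Class labels -> the documented -1 (male) / +1 (female) coding.
.code_y <- function(y) {
  y <- factor(y, levels = c("male", "female"))
  if (anyNA(y)) stop("y labels must be 'male' or 'female'", call. = FALSE)
  if (nlevels(droplevels(y)) != 2L) {
    stop("supervised fit needs both classes present", call. = FALSE)
  }
  ifelse(y == "female", 1, -1)
}

# Linear discriminant in score space: pooled within-class covariance,
# empirical priors. A tiny ridge keeps near-degenerate covariances
# invertible. Returns the discriminant direction and offset such that
# score > 0 classifies "female".
.fit_lda_scores <- function(TT, y) {
  yf <- factor(y, levels = c("male", "female"))
  TT <- as.matrix(TT)
  n <- nrow(TT)
  m0 <- colMeans(TT[yf == "male", , drop = FALSE])
  m1 <- colMeans(TT[yf == "female", , drop = FALSE])
  n0 <- sum(yf == "male"); n1 <- sum(yf == "female")
  S0 <- if (n0 > 1) stats::cov(TT[yf == "male", , drop = FALSE]) else 0 * diag(ncol(TT))
  S1 <- if (n1 > 1) stats::cov(TT[yf == "female", , drop = FALSE]) else 0 * diag(ncol(TT))
  Sp <- ((n0 - 1) * S0 + (n1 - 1) * S1) / max(n - 2, 1)
  Sp <- Sp + diag(ncol(TT)) * (1e-8 * max(sum(diag(Sp)), 1e-12))
  d <- solve(Sp, m1 - m0)
  offset <- -sum(d * (m0 + m1)) / 2 + log(n1 / n0)
  list(direction = d, offset = offset, priors = c(male = n0 / n, female = n1 / n),
       means = rbind(male = m0, female = m1))
}

.predict_lda_scores <- function(lda, TT) {
  g <- as.matrix(TT) %*% lda$direction + lda$offset
  list(score = drop(g),
       class = factor(ifelse(g > 0, "female", "male"),
                      levels = c("male", "female")))
}

#' Fit a PLS-LDA model with NIPALS latent variables
#'
#' Latent variables are extracted by the NIPALS algorithm with per-LV
#' deflation of both `X` and `y` (coded -1 male / +1 female, mean-centred
#' internally). `r2x[a]`/`r2y[a]` are the fractions of (scaled) X- and
#' y-variance captured by LV `a`. Class separation is obtained by linear
#' discriminant analysis on the latent-variable scores (pooled within-class
#' covariance, empirical priors).
#'
#' `X` is expected to be preprocessed (e.g. via [scale_matrix()]); the fit
#' does not rescale columns.
#'
#' @param X Preprocessed numeric matrix (samples x variables).
#' @param y Class labels (`"male"`/`"female"`), or a numeric response for
#'   plain PLS1 regression use.
#' @param A Number of latent variables; truncated with a warning when it
#'   exceeds the effective rank.
#' @return A `pls_lda` model: weights `W`, X-loadings `P`, y-loadings `q`,
#'   scores `T`, `r2x`, `r2y`, the LDA boundary, and centring info.
#' @export
fit_pls_nipals <- function(X, y, A = 2) {
  X <- as.matrix(X)
  y_numeric <- is.numeric(y) && is.null(levels(y))
  yc_raw <- if (y_numeric) as.numeric(y) else .code_y(y)
  y_mean <- mean(yc_raw)
  yr <- yc_raw - y_mean
  Xc <- sweep(X, 2, colMeans(X), "-")
  x_mean <- colMeans(X)
  SSX0 <- sum(Xc^2); SSY0 <- sum(yr^2)
  n <- nrow(X); V <- ncol(X)
  A_req <- A
  A <- min(A, n - 1L, V)
  W <- matrix(0, V, A); P <- matrix(0, V, A)
  TT <- matrix(0, n, A); qv <- numeric(A)
  r2x <- numeric(A); r2y <- numeric(A)
  Xa <- Xc; ya <- yr
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    p <- crossprod(Xa, t_) / tt
    q <- sum(ya * t_) / tt
    Xa <- Xa - t_ %*% t(p)
    ya <- ya - t_ * q
    W[, a] <- w; P[, a] <- p; TT[, a] <- t_; qv[a] <- q
    r2x[a] <- tt * sum(p^2) / SSX0
    r2y[a] <- if (SSY0 > 0) tt * q^2 / SSY0 else 0
    a_done <- a
  }
  if (a_done < A_req) {
    warning(sprintf("requested %d latent variables; rank supports %d",
                    A_req, a_done))
  }
  A <- a_done
  if (A == 0L) stop("no latent variable could be extracted", call. = FALSE)
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  TT <- TT[, seq_len(A), drop = FALSE]
  qv <- qv[seq_len(A)]; r2x <- r2x[seq_len(A)]; r2y <- r2y[seq_len(A)]
  y_class <- if (y_numeric) NULL else
    factor(ifelse(yc_raw > 0, "female", "male"), levels = c("male", "female"))
  lda <- if (!y_numeric) .fit_lda_scores(TT, y_class) else NULL
  structure(list(A = A, W = W, P = P, q = qv, T = TT, r2x = r2x, r2y = r2y,
                 lda = lda, x_mean = x_mean, y_mean = y_mean,
                 y_numeric = y_numeric, y_class = y_class),
            class = "pls_lda")
}

#' @export
print.pls_lda <- function(x, ...) {
  cat(sprintf("<pls_lda> %d LV(s); R2X(cum)=%.4f R2Y(cum)=%.4f\n",
              x$A, sum(x$r2x), sum(x$r2y)))
  invisible(x)
}

#' Project new samples into the latent space of a fitted model
#'
#' @param object A `pls_lda` model.
#' @param newdata Matrix with the same (preprocessed) columns as the
#'   training matrix.
#' @param A Number of latent variables to use (default: all fitted).
#' @param type `"class"` for LDA class labels, `"score"` for the LDA
#'   discriminant value, `"response"` for the PLS regression prediction,
#'   `"latent"` for the score matrix.
#' @param ... Unused.
#' @return Per `type`: factor, numeric vector, numeric vector, or matrix.
#' @export
predict.pls_lda <- function(object, newdata, A = object$A,
                            type = c("class", "score", "response", "latent"),
                            ...) {
  type <- match.arg(type)
  A <- min(A, object$A)
  Xn <- sweep(as.matrix(newdata), 2, object$x_mean, "-")
  n <- nrow(Xn)
  TT <- matrix(0, n, A)
  for (a in seq_len(A)) {
    t_ <- Xn %*% object$W[, a]
    TT[, a] <- t_
    Xn <- Xn - t_ %*% t(object$P[, a])
  }
  if (type == "latent") return(TT)
  if (type == "response") {
    return(drop(TT %*% object$q[seq_len(A)]) + object$y_mean)
  }
  if (is.null(object$lda)) stop("model was fitted on a numeric response",
                                call. = FALSE)
  lda <- if (A == object$A) object$lda else
    .fit_lda_scores(object$T[, seq_len(A), drop = FALSE], object$y_class)
  pr <- .predict_lda_scores(lda, TT)
  if (type == "score") pr$score else pr$class
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(V * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a` is the y-variance captured by LV `a`. The squared VIPs average
#' to exactly 1 over variables.
#'
#' @param model A fitted `pls_lda`.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_lda"))
  V <- nrow(model$W)
  ssy <- model$r2y
  if (sum(ssy) <= 0) ssy <- rep(1, model$A)
  W2 <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")^2
  vip2 <- V * drop(W2 %*% ssy) / sum(ssy)
  sqrt(vip2)
}

#' Binary classification metrics with rank-based AUC
#'
#' Error is the misclassified fraction; sensitivity and specificity treat
#' `"female"` as the positive class; AUC is the Mann-Whitney rank
#' statistic on `scores` (ties contribute 1/2). With a single-class
#' `y_true` the undefined entries are reported as `NA`, never 0.
#'
#' @param y_true,y_pred Class labels (`"male"`/`"female"`).
#' @param scores Numeric scores, higher = more "female"; optional
#'   (`NULL` skips AUC).
#' @return List: `error`, `sensitivity`, `specificity`, `auc`, `n`.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- factor(y_true, levels = c("male", "female"))
  y_pred <- factor(y_pred, levels = c("male", "female"))
  n <- length(y_true)
  err <- mean(y_pred != y_true)
  pos <- y_true == "female"; neg <- y_true == "male"
  sens <- if (any(pos)) mean(y_pred[pos] == "female") else NA_real_
  spec <- if (any(neg)) mean(y_pred[neg] == "male") else NA_real_
  auc <- NA_real_
  if (!is.null(scores) && any(pos) && any(neg)) {
    r <- rank(scores)
    auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(neg))
  }
  list(error = err, sensitivity = sens, specificity = spec, auc = auc, n = n)
}

# Stratified fold assignment: shuffles within class, then deals samples
# round-robin so every fold keeps both classes whenever k <= min class size.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Shared engine: given train/test index sets, return a per-LV matrix of
# test-set predictions and scores.
.cv_eval_split <- function(X, y, train, test, spec, A_max) {
  sc <- scale_matrix(X[train, , drop = FALSE], spec)
  Xtr <- sc$X
  Xte <- scale_matrix(X[test, , drop = FALSE], spec, train_stats = sc$stats)$X
  fit <- suppressWarnings(fit_pls_nipals(Xtr, y[train], A = A_max))
  A_eff <- fit$A
  Ttr <- fit$T
  Xn <- sweep(Xte, 2, fit$x_mean, "-")
  Tte <- matrix(0, length(test), A_eff)
  for (a in seq_len(A_eff)) {
    t_ <- Xn %*% fit$W[, a]
    Tte[, a] <- t_
    Xn <- Xn - t_ %*% t(fit$P[, a])
  }
  pred <- matrix(NA_character_, length(test), A_max)
  scr <- matrix(NA_real_, length(test), A_max)
  for (a in seq_len(A_max)) {
    aa <- min(a, A_eff)
    lda <- .fit_lda_scores(Ttr[, seq_len(aa), drop = FALSE], y[train])
    pr <- .predict_lda_scores(lda, Tte[, seq_len(aa), drop = FALSE])
    pred[, a] <- as.character(pr$class)
    scr[, a] <- pr$score
  }
  list(pred = pred, score = scr)
}

.cv_result <- function(scheme, err_curve, pred_opt, score_opt, y_opt, k = NULL,
                       n_reps = NULL) {
  optLV <- which.min(err_curve)          # which.min takes the smallest index on ties
  m <- classification_metrics(y_opt, pred_opt[, optLV], score_opt[, optLV])
  structure(list(scheme = scheme, error_curve = err_curve, optLV = optLV,
                 error_min = err_curve[optLV], sensitivity = m$sensitivity,
                 specificity = m$specificity, auc = m$auc, n = length(y_opt),
                 k = k, n_reps = n_reps),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result:%s> optLV=%d error_min=%.4f sens=%.4f spec=%.4f auc=%.4f (n=%d)\n",
              x$scheme, x$optLV, x$error_min, x$sensitivity, x$specificity,
              x$auc, x$n))
  invisible(x)
}

#' Stratified k-fold cross-validation of PLS-LDA
#'
#' Scaling statistics are refit inside every training fold (no leakage);
#' the per-LV error curve pools test predictions over folds; `optLV` is the
#' smallest LV count achieving the minimum error. Sensitivity, specificity
#' and AUC are reported for the pooled predictions at `optLV`.
#'
#' @param X Raw (unscaled) feature matrix.
#' @param y Class labels.
#' @param spec A [scaling_spec()].
#' @param A_max Maximum number of latent variables to evaluate.
#' @param k Number of folds; `k = n` gives leave-one-out.
#' @param seed Optional seed for the fold shuffle.
#' @return A `cv_result`.
#' @export
cross_validate <- function(X, y, spec = scaling_spec("pareto"), A_max = 6,
                           k = 7, seed = NULL) {
  X <- as.matrix(X)
  y <- factor(y, levels = c("male", "female"))
  if (!is.null(seed)) set.seed(seed)
  if (k > length(y)) stop("k cannot exceed n", call. = FALSE)
  fold <- .stratified_folds(y, k)
  for (f in seq_len(k)) {
    if (nlevels(droplevels(y[fold != f])) < 2L) {
      stop("stratification error: a training fold lost a class", call. = FALSE)
    }
  }
  pred <- matrix(NA_character_, length(y), A_max)
  scr <- matrix(NA_real_, length(y), A_max)
  for (f in seq_len(k)) {
    test <- which(fold == f); train <- which(fold != f)
    ev <- .cv_eval_split(X, y, train, test, spec, A_max)
    pred[test, ] <- ev$pred
    scr[test, ] <- ev$score
  }
  err_curve <- colMeans(pred != as.character(y))
  .cv_result("kfold", err_curve, pred, scr, y, k = k)
}

#' Monte Carlo cross-validation (repeated random stratified splits)
#'
#' `n_reps` random stratified splits with a `split_fraction` training
#' share; the per-LV curve is the mean test error over repetitions, and the
#' summary metrics pool all repetition test predictions at `optLV`.
#' Deterministic under `seed`.
#'
#' @inheritParams cross_validate
#' @param split_fraction Training fraction in (0, 1).
#' @param n_reps Number of random splits.
#' @param seed RNG seed.
#' @return A `cv_result`.
#' @export
mccv <- function(X, y, spec = scaling_spec("auto"), A_max = 6,
                 split_fraction = 0.8, n_reps = 500, seed = 1) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  X <- as.matrix(X)
  y <- factor(y, levels = c("male", "female"))
  set.seed(seed)
  err <- matrix(NA_real_, n_reps, A_max)
  pred_all <- NULL; scr_all <- NULL; y_all <- NULL
  for (r in seq_len(n_reps)) {
    train <- integer()
    for (lv in levels(y)) {
      idx <- which(y == lv)
      n_tr <- max(2L, round(split_fraction * length(idx)))
      n_tr <- min(n_tr, length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    test <- setdiff(seq_along(y), train)
    ev <- .cv_eval_split(X, y, train, test, spec, A_max)
    err[r, ] <- colMeans(ev$pred != as.character(y[test]))
    pred_all <- rbind(pred_all, ev$pred)
    scr_all <- rbind(scr_all, ev$score)
    y_all <- c(y_all, as.character(y[test]))
  }
  err_curve <- colMeans(err)
  .cv_result("mccv", err_curve, pred_all, scr_all,
             factor(y_all, levels = c("male", "female")),
             n_reps = n_reps)
}
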