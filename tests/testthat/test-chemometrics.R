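test_that("scaling follows the centring and variance rules", {
  X <- cbind(a = c(1, 3), b = c(0, 8))
  auto <- scale_matrix(X, scaling_spec("auto"))
  expect_equal(auto$X[, "a"], c(-0.7071, 0.7071), tolerance = 1e-4,
               ignore_attr = TRUE)
  par <- scale_matrix(X, scaling_spec("pareto"))
  expect_equal(par$X[, "b"], (c(0, 8) - 4) / sqrt(sd(c(0, 8))),
               ignore_attr = TRUE)
  # a column with sd exactly 4 is divided by sqrt(4) = 2 under pareto
  z <- c(-2 * sqrt(2), 2 * sqrt(2))
  expect_equal(sd(z), 4)
  pz <- scale_matrix(cbind(z), scaling_spec("pareto"))
  expect_equal(pz$X[, 1], z / 2, ignore_attr = TRUE)

  # train stats applied to a row equal to the train mean give zeros
  Xt <- matrix(rnorm(20), 5, 4)
  tr <- scale_matrix(Xt, scaling_spec("auto"))
  mu <- matrix(colMeans(Xt), 1)
  expect_equal(unname(scale_matrix(mu, scaling_spec("auto"),
                                   train_stats = tr$stats)$X[1, ]),
               rep(0, 4))
  # zero-variance column dropped with a warning, not divided by zero
  Xz <- cbind(const = rep(1, 5), ok = rnorm(5))
  expect_warning(sz <- scale_matrix(Xz, scaling_spec("auto")),
                 "zero-variance")
  expect_equal(ncol(sz$X), 1)
})

test_that("NIPALS captures a perfect predictor in one latent variable", {
  y <- factor(rep(c("male", "female"), each = 5), levels = c("male", "female"))
  X <- cbind(ifelse(y == "female", 1, -1))
  fit <- fit_pls_nipals(X, y, A = 1)
  expect_equal(fit$r2y[1], 1.0, tolerance = 1e-10)
  expect_equal(as.character(predict(fit, X)), as.character(y))
})

test_that("NIPALS scores are orthogonal with valid variance accounting", {
  set.seed(7)
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 10), 15, 10)
    y <- factor(sample(rep(c("male", "female"), c(8, 7))),
                levels = c("male", "female"))
    fit <- fit_pls_nipals(scale_matrix(X, scaling_spec("auto"))$X, y, A = 5)
    G <- crossprod(fit$T)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
    expect_true(all(fit$r2x >= 0) && all(fit$r2y >= 0))
    expect_lte(sum(fit$r2x), 1 + 1e-8)
    expect_lte(sum(fit$r2y), 1 + 1e-8)
  }
})

test_that("NIPALS predictions match the Krylov-subspace PLS1 oracle", {
  set.seed(11)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    yv <- ifelse(seq_len(20) %% 2 == 0, 1, -1)
    y <- factor(ifelse(yv > 0, "female", "male"), levels = c("male", "female"))
    for (A in c(1, 2, 4)) {
      fit <- fit_pls_nipals(X, y, A = A)
      oracle <- pls1_krylov_oracle(X, yv, A)
      expect_equal(predict(fit, X, type = "response"), oracle$fitted,
                   tolerance = 1e-8)
    }
  }
})

test_that("rank truncation warns and non-binary labels fail", {
  X <- matrix(rnorm(4 * 2), 4, 2)
  y <- factor(c("male", "male", "female", "female"),
              levels = c("male", "female"))
  expect_warning(fit <- fit_pls_nipals(X, y, A = 5), "rank supports")
  expect_lte(fit$A, 2)
  expect_error(fit_pls_nipals(X, factor(rep("male", 4),
                                        levels = c("male", "female")), A = 1),
               "both classes")
})

test_that("the score-space LDA agrees with an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(3)
  TT <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(30, 1.5), 15, 2))
  y <- factor(rep(c("male", "female"), c(20, 15)), levels = c("male", "female"))
  ours <- echinoNMR:::.fit_lda_scores(TT, y)
  pr <- echinoNMR:::.predict_lda_scores(ours, TT)
  ref <- MASS::lda(TT, grouping = y)
  expect_equal(as.character(pr$class),
               as.character(predict(ref, TT)$class))
})

test_that("VIP normalization and discriminant ranking hold", {
  # single-variable model has VIP exactly 1
  y <- factor(rep(c("male", "female"), each = 4), levels = c("male", "female"))
  X1 <- cbind(rnorm(8) + ifelse(y == "female", 2, 0))
  expect_equal(vip_scores(fit_pls_nipals(X1, y, A = 1)), 1)
  # mean squared VIP is 1 on any fitted model
  set.seed(21)
  X <- matrix(rnorm(30 * 12), 30, 12)
  yy <- factor(rep(c("male", "female"), each = 15), levels = c("male", "female"))
  fit <- fit_pls_nipals(X, yy, A = 3)
  expect_equal(mean(vip_scores(fit)^2), 1, tolerance = 1e-10)
  # a single seeded discriminant variable attains the top VIP almost always
  set.seed(31)
  hits <- sum(vapply(1:20, function(r) {
    n <- 37
    Xs <- matrix(rnorm(n * 51), n, 51)
    ys <- factor(rep(c("male", "female"), c(23, 14)),
                 levels = c("male", "female"))
    Xs[, 17] <- Xs[, 17] + ifelse(ys == "female", 2.5, 0)
    f <- fit_pls_nipals(scale_matrix(Xs, scaling_spec("auto"))$X, ys, A = 2)
    which.max(vip_scores(f)) == 17
  }, logical(1)))
  expect_gte(hits, 18)
})

test_that("classification metrics reproduce the standard ratios", {
  m <- classification_metrics(
    factor(rep(c("male", "female"), c(18, 16)), levels = c("male", "female")),
    factor(c(rep("male", 17), "female", rep("female", 16)),
           levels = c("male", "female")))
  expect_equal(round(m$error, 4), 0.0294)   # one misclassification in 34
  # confusion TP=16 FN=0 TN=15 FP=1
  y_true <- factor(rep(c("female", "male"), c(16, 16)),
                   levels = c("male", "female"))
  y_pred <- factor(c(rep("female", 16), "female", rep("male", 15)),
                   levels = c("male", "female"))
  m2 <- classification_metrics(y_true, y_pred)
  expect_equal(m2$sensitivity, 1.0)
  expect_equal(m2$specificity, 0.9375)
  # AUC limits
  y <- factor(rep(c("male", "female"), each = 5), levels = c("male", "female"))
  sc <- c(1:5, 6:10)
  expect_equal(classification_metrics(y, y, sc)$auc, 1)
  expect_equal(classification_metrics(y, y, -sc)$auc, 0)
  expect_equal(classification_metrics(y, y, rep(0, 10))$auc, 0.5)
  # single-class truth leaves specificity undefined, not zero
  one <- classification_metrics(factor(rep("female", 4),
                                       levels = c("male", "female")),
                                factor(rep("female", 4),
                                       levels = c("male", "female")))
  expect_true(is.na(one$specificity))
})

test_that("cross-validation drives error to zero on separable cohorts", {
  set.seed(5)
  n <- 30
  y <- factor(rep(c("male", "female"), each = 15), levels = c("male", "female"))
  X <- matrix(rnorm(n * 40, sd = 0.3), n, 40)
  X[, 1:3] <- X[, 1:3] + ifelse(y == "female", 3, 0)
  cv <- cross_validate(X, y, scaling_spec("pareto"), A_max = 3, k = 5, seed = 1)
  expect_equal(cv$error_min, 0)
  expect_lte(cv$optLV, 3)
  expect_equal(cv$auc, 1)
  # leave-one-out yields a full error curve
  loo <- cross_validate(X, y, scaling_spec("auto"), A_max = 4, k = n, seed = 1)
  expect_length(loo$error_curve, 4)
})

test_that("in-fold scaling matters: whole-data variable selection is optimistic", {
  set.seed(77)
  n <- 30; V <- 200
  X <- matrix(rnorm(n * V), n, V)
  y <- factor(rep(c("male", "female"), each = 15), levels = c("male", "female"))
  proper <- cross_validate(X, y, scaling_spec("auto"), A_max = 2, k = 5,
                           seed = 2)
  # deliberate leakage: pick the 10 most class-correlated columns using
  # *all* samples, then cross-validate only those
  yv <- ifelse(y == "female", 1, -1)
  r <- abs(drop(cor(X, yv)))
  leaky <- cross_validate(X[, order(-r)[1:10]], y, scaling_spec("auto"),
                          A_max = 2, k = 5, seed = 2)
  expect_lt(leaky$error_min, proper$error_min - 0.1)
})

test_that("MCCV is seed-deterministic, stratified and converges when separable", {
  set.seed(9)
  y <- factor(rep(c("male", "female"), c(23, 14)), levels = c("male", "female"))
  X <- matrix(rnorm(37 * 25, sd = 0.4), 37, 25)
  X[, 1:2] <- X[, 1:2] + ifelse(y == "female", 3, 0)
  a <- mccv(X, y, scaling_spec("auto"), A_max = 3, split_fraction = 0.8,
            n_reps = 60, seed = 42)
  b <- mccv(X, y, scaling_spec("auto"), A_max = 3, split_fraction = 0.8,
            n_reps = 60, seed = 42)
  expect_identical(a$error_curve, b$error_curve)
  expect_lte(a$error_min, 0.05)
  # 0.8 split of 23/14 leaves 5 + 3 = 8 test samples per repetition
  expect_equal(a$n, 60 * 8)
  expect_error(mccv(X, y, split_fraction = 1.2), "split_fraction")
})
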