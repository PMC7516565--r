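test_that("lambda_max matches the null-model KKT condition for the quadratic loss", {
  d <- random_instance(60, 6, seed = 31)
  lam <- lambda_grid(d, "quadratic", m = 20)
  expected <- max(abs(crossprod(d$X, d$y - mean(d$y)) / d$n))
  expect_equal(lam[1], expected, tolerance = 1e-12)
})

test_that("grid endpoints honor the ratio and fits at lambda_1 have empty support", {
  for (seed in c(41, 42, 43)) {
    d <- random_instance(50, 8, seed = seed, beta = c(1, -1, rep(0, 6)))
    for (loss in all_losses()) {
      lam <- lambda_grid(d, loss, m = 20, ratio = 0.01)
      expect_equal(lam[20] / lam[1], 0.01, tolerance = 1e-12)
      expect_true(all(diff(lam) < 0))
      fit <- fit_lasso(d, loss, lam[1])
      expect_length(fit$support, 0)
    }
  }
  expect_error(lambda_grid(random_instance(20, 3, 1), "logistic", m = 1),
               ">= 2")
})

test_that("orthonormal quadratic fits equal the soft-threshold closed form", {
  d <- orthonormal_instance(48, 5, seed = 51)
  ols <- drop(crossprod(d$X, d$y)) / d$n
  for (lam in c(0.005, 0.02, 0.08)) {
    fit <- fit_lasso(d, "quadratic", lam, tol = 1e-10)
    expected <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(fit$beta, expected, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$intercept, mean(d$y), tolerance = 1e-8)
  }
})

test_that("objective values match an independent solver (glmnet)", {
  skip_if_not_installed("glmnet")
  d <- random_instance(30, 8, seed = 61, beta = c(1.5, -1, rep(0, 6)))
  obj <- function(b0, beta, loss, lam) {
    empirical_risk(c(b0, beta), d, loss) + lam * sum(abs(beta))
  }
  for (lossname in c("logistic", "quadratic")) {
    fam <- if (lossname == "logistic") "binomial" else "gaussian"
    lam <- lambda_grid(d, lossname, m = 5)[3]
    g <- glmnet::glmnet(d$X, d$y, family = fam, lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
    ours <- fit_lasso(d, lossname, lam, tol = 1e-9)
    o_glmnet <- obj(as.numeric(g$a0), as.numeric(g$beta), lossname, lam)
    o_ours <- obj(ours$intercept, ours$beta, lossname, lam)
    expect_equal(o_ours, o_glmnet, tolerance = 1e-6)
  }
})

test_that("warm-started path agrees with cold starts and beats the null model", {
  d <- random_instance(70, 10, seed = 71, beta = c(2, -1.5, 1, rep(0, 7)))
  for (loss in all_losses()) {
    lam <- lambda_grid(d, loss, m = 8)
    path <- fit_lasso_path(d, loss, lam)
    lobj <- ssgic:::as_loss_spec(loss)
    null_risk <- empirical_risk(
      c(ssgic:::intercept_only_fit(d, lobj), rep(0, d$p)), d, loss)
    for (i in seq_along(lam)) {
      cold <- fit_lasso(d, loss, lam[i])
      o_warm <- empirical_risk(c(path$intercepts[i], path$coefficients[i, ]),
                               d, loss) + lam[i] * sum(abs(path$coefficients[i, ]))
      o_cold <- cold$objective
      expect_equal(o_warm, o_cold, tolerance = 1e-6)
      # optimality with respect to the intercept-only fit
      expect_lte(o_warm, null_risk + 1e-10)
    }
    expect_identical(path$supports[[1]],
                     unname(which(path$coefficients[1, ] != 0)))
  }
  # single-lambda path reduces to fit_lasso
  single <- fit_lasso_path(d, "logistic", lambda_grid(d, "logistic")[5])
  direct <- fit_lasso(d, "logistic", lambda_grid(d, "logistic")[5])
  expect_equal(single$coefficients[1, ], direct$beta, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("refit on a support matches least squares / glm oracles", {
  d <- random_instance(50, 6, seed = 81, beta = c(1, 1, rep(0, 4)))
  # quadratic: normal equations on the selected columns
  r <- refit_erm(d, c(2, 5), "quadratic")
  ls <- lm.fit(cbind(1, d$X[, c(2, 5)]), d$y)$coefficients
  expect_equal(r$intercept, unname(ls[1]), tolerance = 1e-8)
  expect_equal(r$coefficients[c(2, 5)], unname(ls[-1]), tolerance = 1e-8)
  expect_equal(r$coefficients[-c(2, 5)], rep(0, 4))
  # logistic: agrees with glm
  gf <- glm.fit(cbind(1, d$X[, 1:2]), d$y, family = binomial())
  rl <- refit_erm(d, 1:2, "logistic")
  expect_equal(rl$coefficients[1:2], unname(gf$coefficients[-1]),
               tolerance = 1e-6)
  # huber refit achieves a gradient near zero on the support
  rh <- refit_erm(d, 1:3, "huber")
  g <- risk_gradient(c(rh$intercept, rh$coefficients), d,
                     loss_spec("huber"))
  expect_lt(max(abs(g[c(1, 2, 3, 4)])), 1e-5)
})

test_that("empty-support logistic refit on balanced data gives risk log 2", {
  set.seed(91)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c(0, 1), 20)
  d <- ss_dataset(X, y)
  r <- refit_erm(d, integer(0), "logistic")
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$risk, log(2), tolerance = 1e-10)
})

test_that("refit risk is monotone along nested supports and below the penalized fit", {
  d <- random_instance(60, 8, seed = 101, beta = c(2, -1, 0.5, rep(0, 5)))
  for (loss in all_losses()) {
    chain <- list(integer(0), 1L, c(1L, 2L), c(1L, 2L, 3L), c(1L, 2L, 3L, 7L))
    risks <- vapply(chain, function(w) refit_erm(d, w, loss)$risk, 0)
    expect_true(all(diff(risks) <= 1e-9))
    lam <- lambda_grid(d, loss, m = 10)[6]
    fit <- fit_lasso(d, loss, lam)
    if (length(fit$support) > 0) {
      refit <- refit_erm(d, fit$support, loss)
      expect_lte(refit$risk,
                 empirical_risk(c(fit$intercept, fit$beta), d, loss) + 1e-10)
    }
  }
})

test_that("refit validation and original-scale back-transform", {
  d <- random_instance(20, 5, seed = 111)
  expect_error(refit_erm(d, 1:20, "logistic"), "support")
  expect_error(refit_erm(d, c(0, 1), "logistic"), "range")
  # back-transform reproduces the same linear predictor on raw X
  set.seed(112)
  Xraw <- matrix(rnorm(50 * 4, 5, 3), 50, 4)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  ds <- ss_dataset(Xraw, y, standardize = TRUE)
  r <- refit_erm(ds, c(1, 3), "logistic")
  eta_std <- r$intercept + ds$X %*% r$coefficients
  eta_orig <- r$intercept_original + Xraw %*% r$coefficients_original
  expect_equal(drop(eta_std), drop(eta_orig), tolerance = 1e-10)
})

test_that("cross-validation picks the sparsest penalty on pure-noise data", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    X <- matrix(rnorm(60 * 8), 60, 8)
    y <- rbinom(60, 1, 0.5)
    d <- ss_dataset(X, y)
    lam <- lambda_grid(d, "logistic")
    cv <- cv_select_lambda(d, "logistic", lam, K = 5, rule = "1se",
                           seed = s)
    if (cv$index == 1L) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("cross-validation is deterministic given the seed and validates folds", {
  d <- random_instance(60, 6, seed = 121, beta = c(1.5, rep(0, 5)))
  lam <- lambda_grid(d, "logistic", m = 8)
  cv1 <- cv_select_lambda(d, "logistic", lam, K = 5, seed = 9)
  cv2 <- cv_select_lambda(d, "logistic", lam, K = 5, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda, cv2$lambda)
  # stratification: every fold contains both classes
  for (k in 1:5) expect_setequal(unique(d$y[cv1$folds == k]), c(0, 1))
  # the 1se choice is never below the minimizing index
  expect_lte(cv1$index, which.min(cv1$cvm))
  expect_error(cv_select_lambda(d, "logistic", lam, K = 1), "at least 2")
  expect_error(cv_select_lambda(d, "logistic", lam, K = 40), "2K")
})
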