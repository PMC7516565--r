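test_that("support ordering sorts by magnitude with index tie-breaks", {
  expect_identical(order_support(c(0, 2.5, -3, 0, 1)), c(3L, 2L, 5L))
  expect_identical(order_support(rep(0, 4)), integer(0))
  expect_identical(order_support(c(1, -1)), c(1L, 2L))
})

test_that("nested chains are prefix sets of the ordering", {
  chain <- build_nested_family(c(3L, 2L, 5L))
  expect_identical(chain,
                   list(integer(0), 3L, c(3L, 2L), c(3L, 2L, 5L)))
  expect_identical(build_nested_family(integer(0)), list(integer(0)))
  expect_length(build_nested_family(1:4), 5L)
  expect_error(build_nested_family(c(1, 1, 2)), "duplicates")
})

test_that("union families deduplicate, include the empty set and honor filters", {
  d <- random_instance(40, 6, seed = 201, beta = c(2, -1, rep(0, 4)))
  lam <- lambda_grid(d, "logistic", m = 6)
  path <- fit_lasso_path(d, "logistic", lam)
  fam <- build_union_family(path, d$n)
  expect_true(any(vapply(fam$merged, length, 1L) == 0L))
  keys <- vapply(fam$merged, ssgic:::support_key, "")
  expect_false(any(duplicated(keys)))
  # union bound on the merged size
  expect_lte(length(fam$merged),
             1L + sum(vapply(path$supports, length, 1L)))
  # the |support| <= n filter drops whole chains
  fam2 <- build_union_family(path, n = 1L)
  expect_true(all(vapply(path$lambdas, function(l) TRUE, TRUE)))
  kept_sizes <- vapply(path$supports, length, 1L)
  expect_equal(length(fam2$chains), sum(kept_sizes <= 1L))
  # size cap removes large candidate supports
  fam3 <- build_union_family(path, d$n, size_cap = 1L)
  expect_true(all(vapply(fam3$merged, length, 1L) <= 1L))
})

test_that("penalty factors match their formulas", {
  expect_equal(penalty_value(gic_penalty("aic"), 100, 10), 2)
  expect_equal(penalty_value(gic_penalty("bic"), exp(2), 10), 2)
  expect_equal(penalty_value(gic_penalty("ebic", d = 1), 100, 150),
               log(100) + 2 * log(150))
  expect_equal(penalty_value(gic_penalty("ebic", d = 1), 100, 150),
               14.6265, tolerance = 1e-4)
  expect_equal(penalty_value(gic_penalty("lft"), 100, 150),
               log(log(100)) * log(150))
  expect_error(penalty_value(gic_penalty("lft"), 2, 10), "n >= 3")
  expect_error(gic_penalty("ebic", d = 0), "positive")
})

test_that("the BIC penalty exceeds the AIC penalty exactly from n = 8 on", {
  crossover <- NA_integer_
  for (n in 2:20) {
    if (penalty_value(gic_penalty("bic"), n, 5) >
        penalty_value(gic_penalty("aic"), n, 5)) { crossover <- n; break }
  }
  expect_identical(crossover, 8L)
})

test_that("GIC of the empty model has the closed form n log 2 + a_n", {
  set.seed(211)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- rep(c(0, 1), 50)
  d <- ss_dataset(X, y)
  g <- gic(d, integer(0), "logistic", gic_penalty("bic"))
  expect_equal(g$value, 100 * log(2) + log(100), tolerance = 1e-8)
  expect_equal(g$value, 73.92, tolerance = 1e-3)
  # penalty term strictly increases with support size
  g1 <- gic(d, 1L, "logistic", gic_penalty("bic"))
  g2 <- gic(d, 1:2, "logistic", gic_penalty("bic"))
  expect_lt(g$penalty_term, g1$penalty_term)
  expect_lt(g1$penalty_term, g2$penalty_term)
  # aic <= bic for the same support once n >= 8
  expect_lte(gic(d, 1:2, "logistic", gic_penalty("aic"))$value,
             gic(d, 1:2, "logistic", gic_penalty("bic"))$value)
  # bare-|w| variant drops one a_n from the size term
  g0 <- gic(d, 1L, "logistic",
            gic_penalty("bic", count_intercept = FALSE))
  expect_equal(g1$value - g0$value, log(100), tolerance = 1e-10)
})

test_that("single-penalty selection reduces to a two-model comparison when informative", {
  d <- random_instance(80, 1, seed = 221, beta = 3)
  lam <- lambda_grid(d, "logistic", m = 10)
  sel <- ss_select(d, "logistic", lam[5], gic_penalty("bic"))
  tr <- sel$gic_trace
  g_empty <- tr$gic[tr$size == 0]
  g_one <- tr$gic[tr$size == 1]
  if (length(g_one) == 1 && g_one < g_empty) {
    expect_identical(sel$selected_support, 1L)
  } else {
    expect_identical(sel$selected_support, integer(0))
  }
  # at lambda >= lambda_max the family is {empty set}
  sel0 <- ss_select(d, "logistic", lam[1])
  expect_identical(sel0$selected_support, integer(0))
  expect_identical(nrow(sel0$gic_trace), 1L)
})

test_that("ssnet with one penalty equals ss and its minimum improves on any chain", {
  d <- random_instance(60, 8, seed = 231, beta = c(2, -1.5, rep(0, 6)))
  lam <- lambda_grid(d, "logistic", m = 10)
  one <- ssnet_select(d, "logistic", lambdas = lam[6], pen = gic_penalty("bic"))
  ss <- ss_select(d, "logistic", lam[6], gic_penalty("bic"))
  expect_identical(sort(one$selected_support), sort(ss$selected_support))
  expect_equal(min(one$gic_trace$gic, na.rm = TRUE),
               min(ss$gic_trace$gic, na.rm = TRUE), tolerance = 1e-8)
  full <- ssnet_select(d, "logistic", lambdas = lam, pen = gic_penalty("bic"))
  for (i in c(3, 6, 9)) {
    chain_min <- min(ss_select(d, "logistic", lam[i],
                               gic_penalty("bic"))$gic_trace$gic,
                     na.rm = TRUE)
    expect_lte(min(full$gic_trace$gic, na.rm = TRUE), chain_min + 1e-8)
  }
})

test_that("cross-validated selection is deterministic and reduces to ss on a 1-point grid", {
  d <- random_instance(60, 6, seed = 241, beta = c(2, rep(0, 5)))
  lam <- lambda_grid(d, "logistic", m = 8)
  a <- sscv_select(d, "logistic", lambdas = lam, K = 5, seed = 77)
  b <- sscv_select(d, "logistic", lambdas = lam, K = 5, seed = 77)
  expect_identical(a$selected_support, b$selected_support)
  expect_identical(a$cv$lambda, b$cv$lambda)
  deg <- sscv_select(d, "logistic", lambdas = lam[4], K = 5, seed = 77)
  ref <- ss_select(d, "logistic", lam[4])
  expect_identical(sort(deg$selected_support), sort(ref$selected_support))
  # the single-penalty family is never larger than the union family
  full <- ssnet_select(d, "logistic", lambdas = lam)
  expect_lte(nrow(a$gic_trace), nrow(full$gic_trace))
})

test_that("the plug-in selector returns the empty fit on pure noise and minimizes its criterion", {
  set.seed(251)
  X <- matrix(rnorm(80 * 10), 80, 10)
  y <- rbinom(80, 1, 0.5)
  d <- ss_dataset(X, y)
  sel <- lft_select(d, "logistic")
  expect_identical(sel$selected_support, integer(0))
  expect_lte(min(sel$gic_trace$gic), sel$gic_trace$gic[1])
  expect_true(all(sel$gic_trace$gic >= min(sel$gic_trace$gic)))
})

test_that("exhaustive search over p = 1 compares the two possible models", {
  d <- random_instance(50, 1, seed = 261, beta = 2.5)
  ex <- exhaustive_gic(d, "logistic", gic_penalty("bic"), kmax = 1)
  expect_identical(nrow(ex$gic_trace), 2L)
  expect_true(ex$selected_support %in% list(integer(0), 1L) ||
                identical(ex$selected_support, 1L))
  dd <- random_instance(30, 16, seed = 262)
  expect_error(exhaustive_gic(dd, "logistic"), "p <= 15")
  expect_error(exhaustive_gic(random_instance(30, 5, 263), "logistic",
                              kmax = 7), "kmax <= 6")
})

test_that("selected model size is non-increasing in the penalty factor", {
  d <- random_instance(120, 10, seed = 271,
                       beta = c(1.5, -1, 0.7, rep(0, 7)))
  lam <- lambda_grid(d, "logistic", m = 12)
  pens <- list(gic_penalty("aic"), gic_penalty("bic"),
               gic_penalty("ebic", 1), gic_penalty("ebic", 3))
  sizes <- vapply(pens, function(p) {
    length(ssnet_select(d, "logistic", lambdas = lam,
                        pen = p)$selected_support)
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("separation of the true support implies its presence on the chain", {
  set.seed(281)
  for (rep in 1:100) {
    p <- sample(4:10, 1)
    beta <- rnorm(p) * rbinom(p, 1, 0.6)
    s_star <- sort(sample(p, sample(1:(p - 1), 1)))
    ok <- tryCatch(separation_holds(beta, s_star), error = function(e) NA)
    if (isTRUE(ok) && all(beta[s_star] != 0)) {
      chain <- build_nested_family(order_support(beta))
      keys <- vapply(chain, ssgic:::support_key, "")
      expect_true(ssgic:::support_key(s_star) %in% keys)
    }
  }
})

test_that("the plug-in selector misses the projection support of the augmented design more often than the union selector", {
  # correctly specified cubic-monomial design; small replicate count
  recs_ss <- list(); recs_lft <- list()
  for (k in 1:10) {
    sim <- simulate_m1(500, 150, 0, seed = 3000 + k)
    d <- ss_dataset(sim$X, sim$y)
    recs_ss[[k]] <- replicate_record(
      ssnet_select(d, "logistic", pen = gic_penalty("bic")), sim$truth, k)
    recs_lft[[k]] <- replicate_record(
      lft_select(d, "logistic"), sim$truth, k)
  }
  s_ss <- summarize_replicates(recs_ss)
  s_lft <- summarize_replicates(recs_lft)
  expect_lte(s_lft$Psupset, s_ss$Psupset)
  expect_gte(s_ss$Pinc, s_lft$Pinc)
})
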