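sim_regression_data <- function(n, m, n_qtl = 10, h2 = 0.4, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.5)
  M <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(sprintf("c%03d", 1:n), sprintf("s%04d", 1:m)))
  zc <- impute_and_center(genotype_table(M * 1.0))
  b <- rep(0, m)
  b[sample(m, n_qtl)] <- rnorm(n_qtl)
  g <- drop(zc$Z %*% b)
  g <- g * sqrt(h2) / sd(g)
  y <- setNames(g + rnorm(n, 0, sqrt(1 - h2)), rownames(M))
  list(Z = zc$Z, y = y, g = g)
}

test_that("a zero response yields near-zero posterior-mean effects", {
  d <- sim_regression_data(60, 150, seed = 41)
  y0 <- setNames(rep(0, 60), names(d$y))
  for (fam in c("brr", "bayes_a", "bl")) {
    fit <- fit_bayes(y0, d$Z, prior_spec(fam), n_iter = 1500, burn_in = 300,
                     seed = 42)
    expect_lt(max(abs(fit$effects)), 0.01)
    expect_lt(max(abs(fit$gebv)), 0.02)
  }
})

test_that("BRR posterior-mean GEBVs track closed-form ridge at the posterior variance ratio", {
  d <- sim_regression_data(100, 500, h2 = 0.5, seed = 43)
  fit <- fit_bayes(d$y, d$Z, prior_spec("brr"), n_iter = 6000, burn_in = 700,
                   seed = 44)
  # closed-form ridge oracle at the posterior-mean variance ratio
  m <- ncol(d$Z)
  msx <- sum(colSums(d$Z^2)) / (length(d$y) - 1)
  sigma2_b <- fit$vc[["sigma2_g"]] / msx
  lambda <- fit$vc[["sigma2_e"]] / sigma2_b
  r <- d$y - mean(d$y)
  u_hat <- solve(crossprod(d$Z) + lambda * diag(m), crossprod(d$Z, r))
  ridge_gebv <- drop(d$Z %*% u_hat)
  expect_gt(cor(fit$gebv, ridge_gebv), 0.99)
})

test_that("model-collapse identities hold within Monte Carlo error", {
  d <- sim_regression_data(80, 300, h2 = 0.4, seed = 45)
  ni <- 4000; bi <- 500
  # MC-error yardstick: the same model at two seeds
  brr1 <- fit_bayes(d$y, d$Z, prior_spec("brr"), n_iter = ni, burn_in = bi, seed = 1)
  brr2 <- fit_bayes(d$y, d$Z, prior_spec("brr"), n_iter = ni, burn_in = bi, seed = 2)
  mc_err <- mean(abs(brr1$gebv - brr2$gebv))

  # bayes_c with pi = 0 collapses to BRR
  bc0 <- fit_bayes(d$y, d$Z, prior_spec("bayes_c", pi = 0), n_iter = ni,
                   burn_in = bi, seed = 3)
  expect_lt(mean(abs(bc0$gebv - brr1$gebv)), 3 * mc_err + 1e-8)

  # bayes_b with pi = 0 collapses to bayes_a
  ba1 <- fit_bayes(d$y, d$Z, prior_spec("bayes_a"), n_iter = ni, burn_in = bi, seed = 4)
  ba2 <- fit_bayes(d$y, d$Z, prior_spec("bayes_a"), n_iter = ni, burn_in = bi, seed = 5)
  mc_err_a <- mean(abs(ba1$gebv - ba2$gebv))
  bb0 <- fit_bayes(d$y, d$Z, prior_spec("bayes_b", pi = 0), n_iter = ni,
                   burn_in = bi, seed = 6)
  expect_lt(mean(abs(bb0$gebv - ba1$gebv)), 3 * mc_err_a + 1e-8)
})

test_that("chains are bit-identical for a fixed seed", {
  d <- sim_regression_data(40, 100, seed = 46)
  f1 <- fit_bayes(d$y, d$Z, prior_spec("bayes_b"), n_iter = 800, burn_in = 100,
                  seed = 7)
  f2 <- fit_bayes(d$y, d$Z, prior_spec("bayes_b"), n_iter = 800, burn_in = 100,
                  seed = 7)
  expect_identical(f1$chains$sigma2e, f2$chains$sigma2e)
  expect_identical(f1$effects, f2$effects)
  expect_identical(f1$gebv, f2$gebv)
})

test_that("prediction is linear in the centered genotypes", {
  d <- sim_regression_data(50, 120, seed = 47)
  fit <- fit_bayes(d$y, d$Z, prior_spec("brr"), n_iter = 1500, burn_in = 300,
                   seed = 8)
  # a validation row identical to a training row reproduces fitted GEBV + beta
  pred <- predict_bayes(fit, d$Z[c(5, 12), , drop = FALSE])
  expect_equal(unname(pred), unname(fit$gebv[c(5, 12)] + fit$beta),
               tolerance = 1e-10)
  # an exactly average genotype (all-zero centered row) predicts beta
  z0 <- matrix(0, 1, ncol(d$Z), dimnames = list("avg", colnames(d$Z)))
  expect_equal(unname(predict_bayes(fit, z0)), fit$beta)
  # marker mismatch is an informative error
  z_bad <- z0[, -1, drop = FALSE]
  expect_error(predict_bayes(fit, z_bad), "marker mismatch")
})

test_that("per-iteration h2 stays inside (0, 1) and priors keep variances positive", {
  d <- sim_regression_data(60, 200, h2 = 0.35, seed = 48)
  fit <- fit_bayes(d$y, d$Z, prior_spec("bayes_c"), n_iter = 1500, burn_in = 300,
                   seed = 9)
  expect_true(all(fit$chains$h2 > 0 & fit$chains$h2 < 1))
  expect_true(all(fit$chains$sigma2e > 0))
})

test_that("effective sample size estimates behave on known chains", {
  set.seed(50)
  iid <- rnorm(1000)
  expect_gt(ess(iid), 800)
  expect_lt(ess(iid), 1200)
  expect_true(is.na(ess(rep(1, 500))))
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 4000))
  e1 <- ess(ar[1:2000])
  e2 <- ess(ar)
  expect_gt(e2 / e1, 1.4)   # roughly linear growth with chain length
  expect_lt(e1, 600)        # strongly autocorrelated chain has low ESS

  d <- sim_regression_data(40, 80, seed = 51)
  fit <- fit_bayes(d$y, d$Z, prior_spec("brr"), n_iter = 1200, burn_in = 200,
                   seed = 10)
  diag_tab <- chain_diagnostics(fit)
  expect_setequal(diag_tab$param, c("sigma2e", "h2"))
  expect_true(all(diag_tab$flag %in% c("ok", "low_ess", "degenerate")))
})
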