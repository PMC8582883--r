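test_that("constants-only fits reach the analytic share solution", {
  d <- toy_data(800, seed = 41)
  fit <- ml_fit(d, ml_spec())
  counts <- tabulate(d$severity, 4)
  expect_equal(unname(fit$estimates), log(counts[2:4] / counts[1]),
               tolerance = 1e-5)
  expect_equal(fit$loglik, sum(counts * log(counts / 800)), tolerance = 1e-6)
  expect_equal(fit$loglik, fit$loglik_null, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("the MNL special case matches an independent implementation", {
  skip_if_not_installed("nnet")
  withr::with_seed(52, {
    n <- 700
    d <- tibble::tibble(truck = rbinom(n, 1, 0.3),
                        downtown = rbinom(n, 1, 0.4),
                        severity = sample(1:4, n, replace = TRUE,
                                          prob = c(0.4, 0.3, 0.2, 0.1)))
  })
  # every covariate in every non-baseline severity: the exact model that a
  # standard multinomial regression fits
  spec <- ml_spec(fixed = c(
    "truck[minor]", "truck[severe]", "truck[fatal]",
    "downtown[minor]", "downtown[severe]", "downtown[fatal]"))
  fit <- ml_fit(d, spec)
  ref <- nnet::multinom(factor(severity) ~ truck + downtown, data = d,
                        trace = FALSE, reltol = 1e-12)
  expect_equal(fit$loglik, -ref$deviance / 2, tolerance = 1e-6)
  cf <- t(coef(ref)) # rows: intercept, truck, downtown; cols: levels 2:4
  expect_equal(unname(fit$estimates[c("const[minor]", "const[severe]",
                                      "const[fatal]")]),
               unname(cf[1, ]), tolerance = 1e-4)
  expect_equal(unname(fit$estimates[c("truck[minor]", "truck[severe]",
                                      "truck[fatal]")]),
               unname(cf[2, ]), tolerance = 1e-4)
})

test_that("fixed-coefficient estimates are consistent as n grows", {
  spec <- mnl_spec8()
  truth <- mnl_params8()
  bias <- vapply(c(1000, 4000), function(n) {
    d <- simulate_crashes(n, spec, truth, mnl_probs8, seed = 100 + n)
    fit <- ml_fit(d, spec, se = FALSE)
    mean(abs(fit$estimates - truth))
  }, numeric(1))
  expect_lt(bias[2], bias[1])
  expect_lt(bias[2], 0.1)
})

test_that("identical settings reproduce the fit exactly", {
  d <- toy_data(250, seed = 61)
  f1 <- ml_fit(d, toy_spec(), n_draws = 60, se = FALSE)
  f2 <- ml_fit(d, toy_spec(), n_draws = 60, se = FALSE)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("the retention screen applies the two-tailed 90% rule", {
  d <- simulate_crashes(400, mnl_spec8(), mnl_params8(), mnl_probs8,
                        seed = 71)
  fit <- ml_fit(d, mnl_spec8())
  # rig the standard errors so the t-statistics are known exactly
  fit$std_errors[] <- abs(fit$estimates) / 2.25 # |t| = 2.25: retained
  scr <- retention_screen(fit)
  expect_true(all(scr$retained))
  expect_equal(attr(scr, "z_critical"), qnorm(0.95), tolerance = 1e-10)
  fit$std_errors[] <- abs(fit$estimates) / 1.0 # |t| = 1: flagged
  expect_false(any(retention_screen(fit)$retained))
  fit$std_errors[1] <- NA
  expect_true(is.na(retention_screen(fit)$retained[1]))
})

test_that("the retention screen flags null coefficients at the nominal rate", {
  # under a true-zero coefficient, |t| >= 1.645 should occur ~10% of the time
  spec <- ml_spec(fixed = "truck[severe]")
  flags <- vapply(1:40, function(i) {
    d <- simulate_crashes(400, spec,
                          param_template(spec,
                                         c("const[minor]" = 0.2,
                                           "const[severe]" = -0.2)),
                          c(truck = 0.4), seed = 500 + i)
    fit <- ml_fit(d, spec)
    !retention_screen(fit)$retained[retention_screen(fit)$term == "truck[severe]"]
  }, logical(1))
  # binomial(40, 0.10): allow a wide band around the nominal rate
  expect_gte(mean(flags), 0.75)
  expect_lte(mean(flags), 0.99)
})

test_that("goodness-of-fit metrics follow the standard formulas", {
  fake <- list(loglik = -50, loglik_null = -100, n_params = 5, n_obs = 100)
  m <- fit_metrics(fake)
  expect_equal(m$mcfadden_rho2, 0.5)
  expect_equal(m$adjusted_rho2, 1 - (-50 - 5) / -100)
  fake2 <- list(loglik = -100, loglik_null = -150, n_params = 5, n_obs = 100)
  m2 <- fit_metrics(fake2)
  expect_equal(m2$aic, 210)
  expect_equal(m2$bic, 5 * log(100) + 200)
  expect_warning(fit_metrics(list(loglik = -1, loglik_null = 0,
                                  n_params = 1, n_obs = 10)),
                 "undefined")
})

test_that("random-coefficient parameters are recovered within reported SEs", {
  truth <- toy_params()
  d <- toy_data(2500, seed = 81)
  fit <- ml_fit(d, toy_spec(), n_draws = 120)
  expect_true(fit$converged)
  truth_abs <- truth
  truth_abs["vis[severe]:sd"] <- abs(truth_abs["vis[severe]:sd"])
  est <- fit$estimates
  est["vis[severe]:sd"] <- abs(est["vis[severe]:sd"])
  z <- abs(est - truth_abs) / fit$std_errors
  expect_true(all(is.finite(z)))
  expect_true(mean(z <= 3) >= 0.9)
})

test_that("the warm-started ladder has non-decreasing log-likelihood", {
  truth <- toy_params()
  d <- toy_data(1200, seed = 91)
  fits <- fit_ladder(d, toy_spec(), n_draws = 80, se = FALSE)
  lls <- purrr::map_dbl(fits, "loglik")
  expect_true(all(diff(lls) >= -1e-4))
  k <- purrr::map_dbl(fits, "n_params")
  expect_true(all(diff(k) > 0))
})

test_that("transfer likelihoods evaluate converged parameters elsewhere", {
  spec <- mnl_spec8()
  pair <- make_period_pair(
    list(n = 400, true_params = mnl_params8(),
         covariate_probs = mnl_probs8, seed = 1),
    list(n = 400, true_params = mnl_params8(1.0),
         covariate_probs = mnl_probs8, seed = 2),
    spec = spec)
  fa <- ml_fit(pair$a, spec, se = FALSE)
  tr_same <- transfer_loglik(fa, pair$a)
  expect_equal(tr_same$loglik, fa$loglik, tolerance = 1e-10)
  tr_other <- transfer_loglik(fa, pair$b)
  fb <- ml_fit(pair$b, spec, se = FALSE)
  expect_lt(tr_other$loglik, fb$loglik) # converged params fit better
})
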