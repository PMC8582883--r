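test_that("marginal effects sum to zero across severities per covariate", {
  d <- toy_data(400, seed = 3)
  fit <- ml_fit(d, toy_spec(), n_draws = 60, se = FALSE)
  me <- marginal_effects(fit)
  sums <- dplyr::summarise(dplyr::group_by(me, covariate),
                           s = sum(effect))
  expect_equal(sums$s, rep(0, nrow(sums)), tolerance = 1e-10)
  # link-only covariates (tc enters just the variance link) are included
  expect_true("tc" %in% me$covariate)
})

test_that("covariates outside the model yield flagged structural zeros", {
  d <- toy_data(150, seed = 5)
  fit <- ml_fit(d, ml_spec(fixed = "truck[severe]"), se = FALSE)
  me <- marginal_effects(fit, covariates = c("truck", "vis"))
  z <- me[me$covariate == "vis", ]
  expect_true(all(z$effect == 0))
  expect_false(any(z$in_model))
  expect_true(all(me$in_model[me$covariate == "truck"]))
})

test_that("discrete-change effects match the closed-form logit difference", {
  # one-covariate MNL: effects can be written down exactly
  spec <- ml_spec(fixed = "x[severe]")
  p <- param_template(spec, c("const[minor]" = 0.2, "const[severe]" = -0.4,
                              "const[fatal]" = -1, "x[severe]" = 0.9))
  d <- tibble::tibble(severity = rep(1:4, 5), x = rep(c(0, 1), 10))
  fit <- ml_fit(d, spec, se = FALSE)
  fit$estimates[] <- p # evaluate effects at known parameters
  me <- marginal_effects(fit)
  e <- exp(c(0, p[1], p[2], p[3]))
  p0 <- e / sum(e)
  e1 <- e; e1[3] <- exp(p[2] + p[4])
  p1 <- e1 / sum(e1)
  expect_equal(unname(me$effect), unname(p1 - p0), tolerance = 1e-10)
})

test_that("a positive severe-injury coefficient raises severe probability", {
  d <- toy_data(300, seed = 7)
  fit <- ml_fit(d, toy_spec(), n_draws = 60, se = FALSE)
  fit$estimates["truck[severe]"] <- abs(fit$estimates["truck[severe]"]) + 0.5
  me <- marginal_effects(fit)
  expect_gt(me$effect[me$covariate == "truck" & me$severity == "severe"], 0)
})

test_that("random-parameter summaries report the documented conventions", {
  spec <- ml_spec(random = list(
    ml_random("vis_100_200[severe]",
              mean_covariates = c("traffic_control", "no_lights_night"),
              variance_covariates = c("traffic_control", "no_lights_night"))))
  p <- param_template(spec, c(
    "vis_100_200[severe]:mean" = -3.127,
    "vis_100_200[severe]:sd" = 4.037,
    "vis_100_200[severe]:mean:traffic_control" = 1.418,
    "vis_100_200[severe]:mean:no_lights_night" = 3.067,
    "vis_100_200[severe]:sd:traffic_control" = 0.568,
    "vis_100_200[severe]:sd:no_lights_night" = 0.732))
  tc <- random_param_summary(p, profile = c(traffic_control = 1), spec = spec)
  expect_equal(tc$mean, -3.127 + 1.418)
  expect_equal(tc$additive_variance, 4.037^2 + 0.568)
  expect_equal(tc$sd, 4.037 * exp(0.568)) # multiplicative model variance
  expect_equal(tc$conditional_variance, tc$sd^2)
  nl <- random_param_summary(p, profile = c(no_lights_night = 1), spec = spec)
  expect_equal(nl$additive_variance, 4.037^2 + 0.732)
  # share below zero is Phi(-mu/sigma)
  spec2 <- ml_spec(random = list(ml_random("vis[severe]")))
  p2 <- param_template(spec2, c("vis[severe]:mean" = -2.181,
                                "vis[severe]:sd" = 2.348))
  s2 <- random_param_summary(p2, spec = spec2)
  expect_equal(s2$share_below_zero, pnorm(2.181 / 2.348))
  expect_equal(s2$share_below_zero + s2$share_above_zero, 1)
  p3 <- param_template(spec2, c("vis[severe]:mean" = 0,
                                "vis[severe]:sd" = 1.7))
  expect_equal(random_param_summary(p3, spec = spec2)$share_below_zero, 0.5)
  expect_message(random_param_summary(p2, profile = c(bogus = 1),
                                      spec = spec2), "ignored")
})

test_that("share below zero decreases in the conditional mean", {
  spec <- ml_spec(random = list(ml_random("vis[severe]")))
  shares <- vapply(seq(-2, 2, by = 0.5), function(mu) {
    p <- param_template(spec, c("vis[severe]:mean" = mu,
                                "vis[severe]:sd" = 1.3))
    random_param_summary(p, spec = spec)$share_below_zero
  }, numeric(1))
  expect_true(all(diff(shares) < 0))
  expect_equal(shares[5], 0.5) # mu = 0
})

test_that("density curves are proper normal densities on the grid", {
  spec <- ml_spec(random = list(
    ml_random("vis[severe]", mean_covariates = "seg")))
  p <- param_template(spec, c("vis[severe]:mean" = -2.117,
                              "vis[severe]:sd" = 2.294,
                              "vis[severe]:mean:seg" = -1.347))
  dc0 <- density_curve(p, spec = spec)
  area <- sum(diff(dc0$value) * (head(dc0$density, -1) + tail(dc0$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_equal(dc0$value[which.max(dc0$density)], -2.117, tolerance = 0.02)
  # a mean shift translates the curve without reshaping it
  dc1 <- density_curve(p, profile = c(seg = 1), spec = spec)
  expect_equal(dc1$value - (-3.464), dc0$value - (-2.117), tolerance = 1e-10)
  expect_equal(dc1$density, dc0$density, tolerance = 1e-12)
})

test_that("plot builders return ggplot objects", {
  d <- toy_data(150, seed = 15)
  fit <- ml_fit(d, toy_spec(), n_draws = 40)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(density_curve(fit)), "ggplot")
  expect_s3_class(plot_marginal_effects(fit), "ggplot")
})
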