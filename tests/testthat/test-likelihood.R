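test_that("heterogeneous coefficient construction reproduces worked shifts", {
  # base mean -2.117 shifted by a -1.347 mean link on road segments
  spec <- ml_spec(random = list(
    ml_random("vis_50_100[severe]", mean_covariates = "road_segments")))
  p <- param_template(spec, c(
    "vis_50_100[severe]:mean" = -2.117,
    "vis_50_100[severe]:sd" = 2.294,
    "vis_50_100[severe]:mean:road_segments" = -1.347))
  d <- tibble::tibble(vis_50_100 = c(1, 1), road_segments = c(1, 0))
  rc <- realize_coefficients(p, spec, d, gamma = 0)
  expect_equal(rc$coefficient, c(-3.464, -2.117))
  expect_equal(rc$mean, c(-3.464, -2.117))
  # base mean -3.275 shifted by +1.626 under traffic control
  spec2 <- ml_spec(random = list(
    ml_random("vis_100_200[severe]", mean_covariates = "traffic_control")))
  p2 <- param_template(spec2, c(
    "vis_100_200[severe]:mean" = -3.275,
    "vis_100_200[severe]:sd" = 3.946,
    "vis_100_200[severe]:mean:traffic_control" = 1.626))
  d2 <- tibble::tibble(vis_100_200 = 1, traffic_control = 1)
  expect_equal(realize_coefficients(p2, spec2, d2)$coefficient, -1.649)
})

test_that("a zero-sd random slot degenerates to its fixed mean", {
  spec <- ml_spec(random = list(ml_random("vis[severe]")))
  p <- param_template(spec, c("vis[severe]:mean" = -1.3))
  d <- tibble::tibble(vis = 1)
  for (g in c(-2, 0, 1.7)) {
    expect_equal(realize_coefficients(p, spec, d, gamma = g)$coefficient, -1.3)
  }
  # and the variance-scaled draw term responds multiplicatively to W
  p2 <- param_template(spec, c("vis[severe]:mean" = 0, "vis[severe]:sd" = 2))
  expect_equal(realize_coefficients(p2, spec, d, gamma = 1.5)$coefficient, 3)
})

test_that("zero parameters give uniform probabilities and ln(1/4) likelihood", {
  spec <- toy_spec()
  d <- toy_data(20, seed = 4)
  p <- param_template(spec)
  pr <- ml_probabilities(p, d, spec, n_draws = 25)
  expect_equal(as.matrix(pr[severity_labels()]),
               matrix(0.25, 20, 4, dimnames = list(NULL, severity_labels())),
               ignore_attr = TRUE)
  d1 <- d[1, ]
  expect_equal(ml_loglik(p, d1, toy_spec(), n_draws = 25), log(0.25))
})

test_that("without random content the kernel equals the closed-form MNL", {
  spec <- mnl_spec8()
  p <- mnl_params8()
  d <- simulate_crashes(150, spec, p, mnl_probs8, seed = 6)
  pr <- ml_probabilities(p, d, spec)
  expect_equal(as.matrix(pr[severity_labels()]),
               oracle_mnl_probs(p, d, spec), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ml_loglik(p, d, spec), oracle_mnl_loglik(p, d, spec),
               tolerance = 1e-10)
})

test_that("sigma -> 0 with zero links collapses onto the closed form", {
  spec <- toy_spec()
  p <- toy_params("vis[severe]:sd" = 0, "vis[severe]:sd:tc" = 0)
  d <- toy_data(100, seed = 8)
  pr <- ml_probabilities(p, d, spec, n_draws = 50)
  # oracle evaluates at gamma = 0, keeping the theta mean shift
  expect_equal(as.matrix(pr[severity_labels()]),
               oracle_mnl_probs(p, d, spec), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("probabilities are normalized per draw and after averaging", {
  spec <- toy_spec()
  p <- toy_params()
  d <- toy_data(60, seed = 12)
  pr <- ml_probabilities(p, d, spec, n_draws = 40, per_draw = TRUE)
  expect_equal(rowSums(as.matrix(pr[severity_labels()])), rep(1, 60),
               tolerance = 1e-12)
  per <- attr(pr, "per_draw")
  total <- per[[1]] + per[[2]] + per[[3]] + per[[4]]
  expect_equal(max(abs(total - 1)), 0, tolerance = 1e-12)
})

test_that("extreme parameters stay finite through the stabilized kernel", {
  spec <- toy_spec()
  p <- toy_params("const[severe]" = 500, "vis[severe]:sd" = 60)
  d <- toy_data(30, seed = 13)
  pr <- ml_probabilities(p, d, spec, n_draws = 20)
  expect_true(all(is.finite(as.matrix(pr[severity_labels()]))))
  ll <- ml_loglik(p, d, spec, n_draws = 20)
  expect_true(is.finite(ll))
})

test_that("simulated probabilities agree with Gauss-Hermite quadrature", {
  spec <- toy_spec()
  p <- toy_params()
  d <- toy_data(40, seed = 21)
  pr <- ml_probabilities(p, d, spec, n_draws = 200)
  ref <- oracle_gh_probs(p, d, spec, n_nodes = 64)
  expect_lt(max(abs(as.matrix(pr[severity_labels()]) - ref)), 0.005)
})

test_that("relabeling two non-baseline severities permutes nothing material", {
  spec <- ml_spec(fixed = c("truck[severe]", "truck[fatal]", "tc[minor]"))
  p <- param_template(spec, c(
    "const[minor]" = 0.3, "const[severe]" = -0.2, "const[fatal]" = -0.9,
    "truck[severe]" = 1.1, "truck[fatal]" = 0.4, "tc[minor]" = -0.5))
  d <- simulate_crashes(200, spec, p, c(truck = 0.3, tc = 0.2), seed = 31)
  # swap severe <-> fatal in both data and parameters
  d2 <- d
  d2$severity <- ifelse(d$severity == 3L, 4L,
                        ifelse(d$severity == 4L, 3L, d$severity))
  p2 <- p
  p2[c("const[severe]", "const[fatal]")] <- p[c("const[fatal]", "const[severe]")]
  p2[c("truck[severe]", "truck[fatal]")] <- p[c("truck[fatal]", "truck[severe]")]
  expect_equal(ml_loglik(p2, d2, spec), ml_loglik(p, d, spec),
               tolerance = 1e-12)
})

test_that("simulated likelihood stabilizes as the draw count doubles", {
  spec <- toy_spec()
  p <- toy_params()
  d <- toy_data(150, seed = 17)
  lls <- vapply(c(50, 100, 200, 400),
                function(R) ml_loglik(p, d, spec, n_draws = R), numeric(1))
  gaps <- abs(diff(lls))
  expect_lt(gaps[3], gaps[1]) # halving the quadrature error band
  expect_lt(gaps[3], 0.5)
})

test_that("analytic gradients and scores match central differences", {
  spec <- toy_spec()
  d <- toy_data(80, seed = 23)
  mf <- hmvlogit:::build_model_frame(d, spec)
  dr <- halton_draws(80, 30, 1)
  for (shift in c(0, 0.3)) {
    p0 <- unname(toy_params()) + shift
    ev <- hmvlogit:::ml_eval(p0, mf, dr, grad = TRUE, scores = TRUE)
    num <- vapply(seq_along(p0), function(j) {
      h <- 1e-6
      up <- p0; up[j] <- up[j] + h
      dn <- p0; dn[j] <- dn[j] - h
      (hmvlogit:::ml_eval(up, mf, dr)$loglik -
         hmvlogit:::ml_eval(dn, mf, dr)$loglik) / (2 * h)
    }, numeric(1))
    expect_equal(ev$grad, num, tolerance = 1e-5)
    expect_equal(colSums(ev$scores), ev$grad, tolerance = 1e-10)
  }
})
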