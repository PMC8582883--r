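# Independent oracles and small fixtures shared across tests. These are
# deliberately naive implementations (per-record loops, no stabilization,
# no shared code with the package kernel) so they can serve as references.

# Closed-form multinomial logit probabilities computed record by record
# directly from the parameter table. `params` is a named vector; random
# slots are treated at their mean (gamma = 0), i.e. this is the sigma -> 0
# collapse reference.
oracle_mnl_probs <- function(params, data, spec) {
  pt <- param_table(spec)
  labs <- severity_labels()
  n <- nrow(data)
  out <- matrix(0, n, 4, dimnames = list(NULL, labs))
  for (k in seq_len(n)) {
    util <- numeric(4) # baseline stays 0
    for (i in seq_len(nrow(pt))) {
      row <- pt[i, ]
      sev <- match(row$severity, labs)
      val <- switch(row$block,
                    constant = 1,
                    fixed = data[[row$covariate]][k],
                    rp_mean = data[[row$covariate]][k],
                    rp_theta = data[[row$covariate]][k] * data[[row$link]][k],
                    0) # rp_sd, rp_omega vanish at gamma = 0
      util[sev] <- util[sev] + params[[row$term]] * val
    }
    e <- exp(util)
    out[k, ] <- e / sum(e)
  }
  out
}

oracle_mnl_loglik <- function(params, data, spec, outcome = "severity") {
  p <- oracle_mnl_probs(params, data, spec)
  y <- as.integer(data[[outcome]])
  sum(log(p[cbind(seq_len(nrow(data)), y)]))
}

# Gauss-Hermite reference for the one-random-slot mixing integral:
# E_gamma[ logit kernel ] with gamma ~ N(0,1), per crash and severity.
oracle_gh_probs <- function(params, data, spec, n_nodes = 64) {
  gh <- pracma::gaussHermite(n_nodes)
  labs <- severity_labels()
  pt <- param_table(spec)
  stopifnot(sum(pt$block == "rp_mean") == 1)
  n <- nrow(data)
  out <- matrix(0, n, 4, dimnames = list(NULL, labs))
  for (j in seq_along(gh$x)) {
    gam <- sqrt(2) * gh$x[j]
    w <- gh$w[j] / sqrt(pi)
    for (k in seq_len(n)) {
      util <- numeric(4)
      for (i in seq_len(nrow(pt))) {
        row <- pt[i, ]
        sev <- match(row$severity, labs)
        val <- switch(row$block,
                      constant = 1,
                      fixed = data[[row$covariate]][k],
                      rp_mean = data[[row$covariate]][k],
                      rp_theta = data[[row$covariate]][k] * data[[row$link]][k],
                      rp_sd = data[[row$covariate]][k] * gam,
                      rp_omega = 0)
        if (row$block == "rp_omega") next
        util[sev] <- util[sev] + params[[row$term]] * val
      }
      # variance links scale sigma: fold exp(omega'W) into the sd term
      om <- pt$term[pt$block == "rp_omega"]
      if (length(om)) {
        scale_w <- exp(sum(vapply(om, function(tm) {
          lk <- pt$link[pt$term == tm]
          params[[tm]] * data[[lk]][k]
        }, numeric(1))))
        sd_term <- pt$term[pt$block == "rp_sd"]
        sevq <- match(pt$severity[pt$term == sd_term], labs)
        xq <- data[[pt$covariate[pt$term == sd_term]]][k]
        util[sevq] <- util[sevq] + params[[sd_term]] * xq * gam * (scale_w - 1)
      }
      e <- exp(util)
      out[k, ] <- out[k, ] + w * e / sum(e)
    }
  }
  out
}

# Small generic spec used in many tests: 2 fixed covariates + 1 random slot
# with one mean link and one variance link.
toy_spec <- function() {
  ml_spec(
    fixed = c("truck[severe]", "truck[fatal]", "downtown[minor]"),
    random = list(ml_random("vis[severe]",
                            mean_covariates = "seg",
                            variance_covariates = "tc"))
  )
}

toy_params <- function(...) {
  param_template(toy_spec(), c(
    "const[minor]" = 0.5, "const[severe]" = -0.5, "const[fatal]" = -1,
    "truck[severe]" = 1, "truck[fatal]" = 0.8, "downtown[minor]" = -0.6,
    "vis[severe]:mean" = -2, "vis[severe]:sd" = 2,
    "vis[severe]:mean:seg" = 1.5, "vis[severe]:sd:tc" = 0.5, ...))
}

toy_probs <- c(truck = 0.3, vis = 0.35, seg = 0.5, tc = 0.3, downtown = 0.45)

toy_data <- function(n, seed = 1, params = toy_params()) {
  simulate_crashes(n, toy_spec(), params, toy_probs, seed = seed)
}

# Fixed-coefficient spec for LR-test calibrations (8 parameters).
mnl_spec8 <- function() {
  ml_spec(fixed = c("truck[severe]", "truck[fatal]", "downtown[minor]",
                    "tc[severe]", "seg[severe]"))
}

# `shift` displaces the road-segment coefficient, a common covariate (70%
# prevalence) whose coefficient is well identified at moderate sample sizes,
# so a regime difference of the stated magnitude is actually detectable.
mnl_params8 <- function(shift = 0) {
  param_template(mnl_spec8(), c(
    "const[minor]" = 0.4, "const[severe]" = -0.4, "const[fatal]" = -1,
    "truck[severe]" = 0.8, "truck[fatal]" = 0.6,
    "downtown[minor]" = -0.5, "tc[severe]" = -0.7,
    "seg[severe]" = 0.9 + shift))
}

mnl_probs8 <- c(truck = 0.25, downtown = 0.45, tc = 0.2, seg = 0.7)
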