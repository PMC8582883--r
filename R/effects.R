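#' Average discrete-change marginal effects
#'
#' For each binary covariate in the model and each severity level, the
#' average over crashes of `P(level | covariate = 1) - P(level | covariate
#' = 0)`, holding every other covariate at its observed value and averaging
#' the logit kernel over the fit's Halton draws in both scenarios. A
#' covariate entering a random slot's mean or variance links is toggled
#' there too. Because probabilities sum to one in both scenarios, each
#' covariate's effects sum to zero across the four levels.
#'
#' @param fit an `ml_fit`.
#' @param data dataset to average over; defaults to the estimation sample.
#' @param covariates covariates to report; defaults to every covariate in
#'   the model. Covariates absent from the model get a structural zero row.
#' @return tibble with `covariate`, `severity`, `effect`, `in_model`.
#' @export
marginal_effects <- function(fit, data = NULL, covariates = NULL) {
  stopifnot(inherits(fit, "ml_fit"))
  if (is.null(data)) data <- fit$data
  data <- validate_crash_data(data, outcome = fit$outcome,
                              require_outcome = FALSE)
  model_covs <- spec_covariates(fit$spec)
  if (is.null(covariates)) covariates <- model_covs
  Q <- length(fit$spec$random)
  draws <- if (Q) halton_draws(nrow(data), fit$n_draws, Q, fit$burn) else NULL
  labs <- severity_labels()
  purrr::map_dfr(covariates, function(cv) {
    if (!cv %in% model_covs) {
      return(tibble::tibble(covariate = cv, severity = labs,
                            effect = 0, in_model = FALSE))
    }
    d1 <- data; d1[[cv]] <- 1
    d0 <- data; d0[[cv]] <- 0
    p1 <- ml_probabilities(fit$estimates, d1, fit$spec, draws = draws)
    p0 <- ml_probabilities(fit$estimates, d0, fit$spec, draws = draws)
    tibble::tibble(covariate = cv, severity = labs,
                   effect = colMeans(as.matrix(p1[labs])) -
                            colMeans(as.matrix(p0[labs])),
                   in_model = TRUE)
  })
}

#' Random-parameter distribution summary at a covariate profile
#'
#' For each random slot, the conditional normal distribution of the
#' coefficient at a given setting of the mean-link (Z) and variance-link (W)
#' covariates: conditional mean `mu_c = beta + theta' Z`, conditional SD
#' `sigma_c = |sigma| * exp(omega' W)`, and the population share with a
#' negative coefficient, `Phi(-mu_c / sigma_c)`. The additive figure
#' `sigma^2 + omega' W` is also reported: it is an additive reporting
#' convention seen in applied severity studies, not the model's conditional
#' variance (which is `sigma_c^2`), and is labelled accordingly.
#'
#' @param fit an `ml_fit` with at least one random slot (a named parameter
#'   vector plus `spec =` also works, for worked examples).
#' @param profile named 0/1 vector setting the link covariates; unnamed
#'   entries referencing covariates outside the slot's links are ignored
#'   with a notice. Missing links default to 0 (the reference category).
#' @param spec required when `fit` is a bare parameter vector.
#' @return tibble with one row per random slot: `term`, `severity`, `mean`,
#'   `sd`, `share_below_zero`, `share_above_zero`, `additive_variance`,
#'   `conditional_variance`.
#' @examples
#' spec <- ml_spec(random = list(
#'   ml_random("visibility_100_200[severe]",
#'             mean_covariates = "traffic_control",
#'             variance_covariates = "traffic_control")))
#' p <- param_template(spec, c(
#'   "visibility_100_200[severe]:mean" = -3.127,
#'   "visibility_100_200[severe]:sd" = 4.037,
#'   "visibility_100_200[severe]:mean:traffic_control" = 1.418,
#'   "visibility_100_200[severe]:sd:traffic_control" = 0.568))
#' random_param_summary(p, profile = c(traffic_control = 1), spec = spec)
#' @export
random_param_summary <- function(fit, profile = NULL, spec = NULL) {
  if (inherits(fit, "ml_fit")) {
    params <- fit$estimates
    spec <- fit$spec
  } else {
    stopifnot(!is.null(spec))
    params <- param_template(spec, fit)
  }
  if (!length(spec$random)) stop("spec has no random slots", call. = FALSE)
  profile <- profile %||% numeric(0)
  link_covs <- unique(c(unlist(purrr::map(spec$random, "mean_covariates")),
                        unlist(purrr::map(spec$random, "variance_covariates"))))
  extra <- setdiff(names(profile), link_covs)
  if (length(extra)) {
    message("profile entries ignored (not mean/variance links): ",
            paste(extra, collapse = ", "))
  }
  pt <- param_table(spec)
  labs <- severity_labels()
  purrr::map_dfr(spec$random, function(r) {
    term <- paste0(r$covariate, "[", labs[r$severity], "]")
    zval <- function(nm) if (nm %in% names(profile)) profile[[nm]] else 0
    theta <- params[pt$term[pt$block == "rp_theta" & pt$covariate == r$covariate &
                              pt$severity == labs[r$severity]]]
    omega <- params[pt$term[pt$block == "rp_omega" & pt$covariate == r$covariate &
                              pt$severity == labs[r$severity]]]
    zs <- purrr::map_dbl(r$mean_covariates, zval)
    ws <- purrr::map_dbl(r$variance_covariates, zval)
    mu <- unname(params[paste0(term, ":mean")]) + sum(theta * zs)
    sigma <- unname(params[paste0(term, ":sd")])
    sd_c <- abs(sigma) * exp(sum(omega * ws))
    share_neg <- if (sd_c > 0) stats::pnorm(-mu / sd_c) else as.numeric(mu < 0)
    tibble::tibble(term = term, severity = labs[r$severity],
                   mean = mu, sd = sd_c,
                   share_below_zero = share_neg,
                   share_above_zero = 1 - share_neg,
                   additive_variance = sigma^2 + sum(omega * ws),
                   conditional_variance = sd_c^2)
  })
}

#' Normal density curve of a random coefficient
#'
#' The conditional distribution `N(mu_c, sigma_c^2)` of a random slot at a
#' covariate profile, evaluated on a symmetric grid `mu_c +/- 4 sigma_c`
#' for plotting. A degenerate slot (`sigma_c = 0`) is returned as a
#' single-point mass.
#'
#' @inheritParams random_param_summary
#' @param slot slot term (`"covariate[severity]"`) or index; default the
#'   first random slot.
#' @param n_grid grid resolution.
#' @return tibble with `value`, `density`, plus the slot `term` and profile
#'   label; class `ml_density` for [ggplot2::autoplot()].
#' @export
density_curve <- function(fit, slot = 1, profile = NULL, spec = NULL,
                          n_grid = 512) {
  smry <- random_param_summary(fit, profile = profile, spec = spec)
  row <- if (is.numeric(slot)) smry[slot, ] else smry[smry$term == slot, ]
  if (nrow(row) != 1L) stop("random slot not found: ", slot, call. = FALSE)
  if (row$sd == 0) {
    out <- tibble::tibble(value = row$mean, density = Inf)
  } else {
    grid <- seq(row$mean - 4 * row$sd, row$mean + 4 * row$sd,
                length.out = n_grid)
    out <- tibble::tibble(value = grid,
                          density = stats::dnorm(grid, row$mean, row$sd))
  }
  out$term <- row$term
  out$profile <- paste(names(profile %||% numeric(0)),
                       profile %||% numeric(0),
                       sep = "=", collapse = ",")
  class(out) <- c("ml_density", class(out))
  out
}

#' @export
autoplot.ml_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "coefficient value", y = "density",
                  title = object$term[1],
                  subtitle = if (nzchar(object$profile[1]))
                    paste("profile:", object$profile[1]) else NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted model
#'
#' Point estimates with 90% normal-approximation intervals, faceted by
#' severity function.
#'
#' @param object an `ml_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ml_fit <- function(object, ...) {
  td <- tidy(object)
  z <- stats::qnorm(0.95)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - z * .data$std.error,
                   xmax = .data$estimate + z * .data$std.error),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~severity, scales = "free_y") +
    ggplot2::labs(x = "coefficient (90% interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot marginal effects
#'
#' @param fit an `ml_fit`.
#' @param ... passed to [marginal_effects()].
#' @return a ggplot object.
#' @export
plot_marginal_effects <- function(fit, ...) {
  me <- marginal_effects(fit, ...)
  me$severity <- factor(me$severity, levels = severity_labels())
  ggplot2::ggplot(me, ggplot2::aes(x = .data$effect, y = .data$covariate,
                                   fill = .data$severity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "average discrete-change effect", y = NULL) +
    ggplot2::theme_minimal()
}
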