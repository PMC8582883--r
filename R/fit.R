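#' Fit a mixed logit severity model by maximum simulated likelihood
#'
#' Maximizes the simulated log-likelihood with BFGS using analytic
#' gradients. The same deterministic Halton draw block is used at every
#' candidate parameter vector (common draws), so the simulated objective is
#' smooth and runs are exactly reproducible. When the specification contains
#' random slots, starting values default to a fixed-coefficient (MNL)
#' pre-fit: random-slot means start at the MNL estimates, standard
#' deviations at 0.1, and heterogeneity links at zero.
#'
#' Standard errors come from the inverse of the negative numerical Hessian
#' (central differences of the analytic gradient) at the optimum; when that
#' matrix is not positive definite, the BHHH outer product of per-crash
#' scores is used instead and the `vcov_method` field records it.
#'
#' @param data crash data frame (see [validate_crash_data()]).
#' @param spec an [ml_spec()].
#' @param n_draws Halton draws per crash (default 200).
#' @param burn Halton burn-in (default 10).
#' @param outcome outcome column name.
#' @param start optional named starting vector (see [param_template()]).
#' @param control passed to [stats::optim()]; `maxit` defaults to 2000 and
#'   `reltol` to 1e-10.
#' @param se compute the covariance matrix and standard errors?
#' @param prefit internal: skip the MNL warm start.
#' @return an object of class `ml_fit`; see [tidy.ml_fit()],
#'   [glance.ml_fit()], [retention_screen()], [marginal_effects()].
#' @examples
#' spec <- ml_spec(fixed = c("truck[severe]", "truck[fatal]"))
#' d <- simulate_crashes(500, spec,
#'                       true_params = c("truck[severe]" = 1),
#'                       covariate_probs = c(truck = 0.3), seed = 7)
#' fit <- ml_fit(d, spec)
#' glance(fit)
#' @export
ml_fit <- function(data, spec, n_draws = 200, burn = 10,
                   outcome = "severity", start = NULL,
                   control = list(), se = TRUE, prefit = TRUE) {
  mf <- build_model_frame(data, spec, outcome = outcome)
  if (!any(mf$y == spec$baseline)) {
    stop("no records in the baseline severity category; ",
         "constants are not estimable", call. = FALSE)
  }
  Q <- length(mf$slots)
  draws <- if (Q) halton_draws(mf$n, n_draws, Q, burn) else NULL
  if (!is.null(start)) {
    par0 <- if (is.null(names(start))) align_params(start, mf)
            else align_params(param_template(spec, start), mf)
  } else if (Q && prefit) {
    par0 <- mnl_warm_start(data, spec, mf, outcome, control)
  } else {
    par0 <- numeric(mf$n_params)
    if (Q) par0[purrr::map_int(mf$slots, "i_sd")] <- 0.1
  }
  control <- utils::modifyList(list(maxit = 2000, reltol = 1e-10), control)
  neg_fn <- function(p) {
    if (!all(is.finite(p))) return(1e300)
    -ml_eval(p, mf, draws)$loglik
  }
  neg_gr <- function(p) {
    g <- ml_eval(p, mf, draws, grad = TRUE)$grad
    if (!all(is.finite(g))) g[!is.finite(g)] <- 0
    -g
  }
  opt <- stats::optim(par0, neg_fn, neg_gr, method = "BFGS",
                      control = control)
  est <- stats::setNames(opt$par, mf$pt$term)
  ll <- -opt$value
  vc <- NULL; ses <- rep(NA_real_, mf$n_params); vcov_method <- "none"
  warnings_log <- character()
  if (se) {
    vc_res <- fit_vcov(opt$par, mf, draws)
    vc <- vc_res$vcov
    vcov_method <- vc_res$method
    warnings_log <- vc_res$warnings
    if (!is.null(vc)) {
      ses <- sqrt(pmax(diag(vc), 0))
      dimnames(vc) <- list(mf$pt$term, mf$pt$term)
    }
  }
  names(ses) <- mf$pt$term
  counts <- tabulate(mf$y, nbins = 4L)
  structure(list(
    spec = spec,
    estimates = est,
    vcov = vc,
    std_errors = ses,
    t_stats = est / ifelse(ses > 0, ses, NA_real_),
    loglik = ll,
    loglik_null = constants_only_loglik(counts),
    n_obs = mf$n,
    n_params = mf$n_params,
    n_draws = if (Q) n_draws else 1L,
    burn = burn,
    severity_counts = counts,
    converged = opt$convergence == 0L,
    optim_counts = opt$counts,
    vcov_method = vcov_method,
    warnings = warnings_log,
    outcome = outcome,
    data = mf$data
  ), class = "ml_fit")
}

# MNL pre-fit for starting values: random slots demoted to fixed.
mnl_warm_start <- function(data, spec, mf, outcome, control) {
  fspec <- as_fixed_spec(spec)
  pre <- ml_fit(data, fspec, outcome = outcome, se = FALSE,
                control = control, prefit = FALSE)
  fpt <- param_table(fspec)
  par0 <- numeric(mf$n_params)
  for (i in seq_len(nrow(mf$pt))) {
    row <- mf$pt[i, ]
    if (row$block %in% c("constant", "fixed", "rp_mean")) {
      j <- which(fpt$covariate == row$covariate & fpt$severity == row$severity)
      if (length(j) == 1L) par0[i] <- unname(pre$estimates[j])
    } else if (row$block == "rp_sd") {
      par0[i] <- 0.1
    }
  }
  par0
}

# Closed-form log-likelihood of the constants-only model: sum n_i log(n_i/n),
# the saturated-shares optimum (terms with n_i = 0 contribute 0).
constants_only_loglik <- function(counts) {
  n <- sum(counts)
  pos <- counts > 0
  sum(counts[pos] * log(counts[pos] / n))
}

# Covariance at the optimum: inverse of negative LL Hessian by central
# differences of the analytic gradient; BHHH fallback.
fit_vcov <- function(par, mf, draws) {
  p <- length(par)
  h <- 1e-4 * pmax(abs(par), 1)
  Hn <- matrix(0, p, p)
  for (j in seq_len(p)) {
    up <- par; up[j] <- up[j] + h[j]
    dn <- par; dn[j] <- dn[j] - h[j]
    Hn[, j] <- (ml_eval(up, mf, draws, grad = TRUE)$grad -
                ml_eval(dn, mf, draws, grad = TRUE)$grad) / (2 * h[j])
  }
  Hn <- -(Hn + t(Hn)) / 2  # negative Hessian of LL, symmetrized
  warn <- character()
  vc <- tryCatch(chol2inv(chol(Hn)), error = function(e) NULL)
  if (!is.null(vc)) return(list(vcov = vc, method = "hessian", warnings = warn))
  warn <- "negative Hessian not positive definite; using BHHH outer product"
  S <- ml_eval(par, mf, draws, scores = TRUE)$scores
  vc <- tryCatch(chol2inv(chol(crossprod(S))), error = function(e) NULL)
  if (is.null(vc)) {
    warn <- c(warn, "BHHH outer product singular; standard errors undefined")
    return(list(vcov = NULL, method = "undefined", warnings = warn))
  }
  list(vcov = vc, method = "bhhh", warnings = warn)
}

#' Evaluate a converged fit on another dataset
#'
#' Computes the log-likelihood of a fit's converged parameters on a
#' different dataset (same specification), the ingredient of the parameter
#' transferability test: how well one period's converged parameter structure
#' explains the other period's crashes, without re-estimation.
#'
#' @param fit an `ml_fit`.
#' @param data the other dataset.
#' @return an object of class `ml_transfer` holding `loglik`, `n_obs`,
#'   `n_params` and the source fit's spec; usable as the second argument of
#'   [lr_transferability()].
#' @export
transfer_loglik <- function(fit, data) {
  stopifnot(inherits(fit, "ml_fit"))
  ll <- ml_loglik(fit$estimates, data, fit$spec,
                  n_draws = fit$n_draws, burn = fit$burn,
                  outcome = fit$outcome)
  structure(list(loglik = ll, n_obs = nrow(data), n_params = fit$n_params,
                 spec = fit$spec, source_fit = TRUE),
            class = "ml_transfer")
}

#' Fit the three-model heterogeneity ladder
#'
#' Fits the [nested_ladder()] specifications sequentially with warm starts:
#' each rung initializes the next (new link parameters start at zero), which
#' stabilizes convergence and guarantees the log-likelihood at convergence
#' is non-decreasing along the ladder up to optimizer tolerance.
#'
#' @inheritParams ml_fit
#' @param spec the full mean--variance heterogeneity specification.
#' @return named list of three `ml_fit` objects in ladder order.
#' @export
fit_ladder <- function(data, spec, n_draws = 200, burn = 10,
                       outcome = "severity", control = list(), se = TRUE) {
  ladder <- nested_ladder(spec)
  fits <- vector("list", 3)
  names(fits) <- names(ladder)
  prev <- NULL
  for (i in seq_along(ladder)) {
    start <- NULL
    if (!is.null(prev)) {
      start <- param_template(ladder[[i]])
      shared <- intersect(names(start), names(prev$estimates))
      start[shared] <- prev$estimates[shared]
    }
    fits[[i]] <- ml_fit(data, ladder[[i]], n_draws = n_draws, burn = burn,
                        outcome = outcome, start = start,
                        control = control, se = se)
    prev <- fits[[i]]
  }
  fits
}

#' Significance retention screen
#'
#' The conventional specification screen for this literature: a parameter is
#' retained when its two-tailed t-statistic reaches the given confidence
#' level (1.645 at 90%). Random-slot standard deviations are screened the
#' same way. Parameters with undefined standard errors are marked
#' unscreenable rather than silently dropped.
#'
#' @param fit an `ml_fit`.
#' @param confidence two-tailed confidence level, default 0.90.
#' @return tibble with `term`, `block`, `estimate`, `std.error`,
#'   `statistic`, `retained` (logical, `NA` when unscreenable).
#' @export
retention_screen <- function(fit, confidence = 0.90) {
  stopifnot(inherits(fit, "ml_fit"), confidence > 0, confidence < 1)
  zcrit <- stats::qnorm(1 - (1 - confidence) / 2)
  out <- tidy(fit)
  out$retained <- ifelse(is.na(out$statistic), NA,
                         abs(out$statistic) >= zcrit)
  attr(out, "z_critical") <- zcrit
  out[, c("term", "block", "estimate", "std.error", "statistic", "retained")]
}

#' @export
print.ml_fit <- function(x, ...) {
  cat("<ml_fit> mixed logit severity model\n")
  cat("  n =", x$n_obs, "; parameters =", x$n_params,
      "; draws =", x$n_draws, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "(constants-only:", format(x$loglik_null, digits = 8), ")\n")
  cat("  converged:", x$converged, "; vcov:", x$vcov_method, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy coefficient table of a fitted model
#'
#' @param x an `ml_fit`.
#' @param ... unused.
#' @return tibble with `term`, `block`, `covariate`, `severity`, `link`,
#'   `estimate`, `std.error`, `statistic` (t), `p.value` (normal
#'   approximation). Random-slot standard deviations are reported as
#'   absolute values (their sign is not identified).
#' @export
tidy.ml_fit <- function(x, ...) {
  pt <- param_table(x$spec)
  est <- x$estimates
  sdrows <- pt$block == "rp_sd"
  est[sdrows] <- abs(est[sdrows])
  out <- dplyr::mutate(pt,
                       estimate = unname(est),
                       std.error = unname(x$std_errors),
                       statistic = unname(est / x$std_errors),
                       p.value = 2 * stats::pnorm(-abs(.data$statistic)))
  tibble::as_tibble(out)
}

#' One-row goodness-of-fit summary
#'
#' McFadden rho-squared `1 - LL/LL0`, its adjusted version
#' `1 - (LL - K)/LL0`, `AIC = 2K - 2LL` and `BIC = K log(n) - 2LL`, where
#' `LL0` is the constants-only log-likelihood.
#'
#' @param x an `ml_fit`.
#' @param ... unused.
#' @return one-row tibble: `logLik`, `logLik_null`, `mcfadden_rho2`,
#'   `adj_rho2`, `AIC`, `BIC`, `nobs`, `n_params`, `n_draws`, `converged`.
#' @export
glance.ml_fit <- function(x, ...) {
  m <- fit_metrics(x)
  tibble::tibble(logLik = x$loglik, logLik_null = x$loglik_null,
                 mcfadden_rho2 = m$mcfadden_rho2, adj_rho2 = m$adjusted_rho2,
                 AIC = m$aic, BIC = m$bic, nobs = x$n_obs,
                 n_params = x$n_params, n_draws = x$n_draws,
                 converged = x$converged)
}

#' Goodness-of-fit metrics
#'
#' @param fit an `ml_fit` (or any list with `loglik`, `loglik_null`,
#'   `n_params`, `n_obs`).
#' @return tibble with `mcfadden_rho2`, `adjusted_rho2`, `aic`, `bic`.
#' @export
fit_metrics <- function(fit) {
  ll <- fit$loglik; ll0 <- fit$loglik_null
  K <- fit$n_params; n <- fit$n_obs
  if (!is.finite(ll0) || ll0 == 0) {
    warning("constants-only log-likelihood is zero; rho-squared undefined")
    rho <- NA_real_; adj <- NA_real_
  } else {
    rho <- 1 - ll / ll0
    adj <- 1 - (ll - K) / ll0
  }
  tibble::tibble(mcfadden_rho2 = rho, adjusted_rho2 = adj,
                 aic = 2 * K - 2 * ll, bic = K * log(n) - 2 * ll)
}

#' @export
logLik.ml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}
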