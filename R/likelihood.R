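# Internal model frame: everything the likelihood needs, precomputed once
# per (data, spec) pair. Parameter positions follow param_table() order:
# constants, fixed slots, random-slot means, sds, thetas, omegas.
build_model_frame <- function(data, spec, outcome = "severity",
                              require_outcome = TRUE) {
  data <- validate_crash_data(data, outcome = outcome,
                              require_outcome = require_outcome)
  validate_spec(spec, data)
  n <- nrow(data)
  nonbase <- setdiff(1:4, spec$baseline)
  nf <- nrow(spec$fixed)
  Q <- length(spec$random)
  # constants + fixed design matrix and per-column severity codes
  Xf <- cbind(matrix(1, n, 3),
              if (nf) as.matrix(data[spec$fixed$covariate]) else NULL)
  sev_f <- c(nonbase, spec$fixed$severity)
  i_fixed <- seq_len(3 + nf)
  off <- 3 + nf
  n_theta <- purrr::map_int(spec$random, ~ length(.x$mean_covariates))
  n_omega <- purrr::map_int(spec$random, ~ length(.x$variance_covariates))
  theta_off <- off + 2 * Q + c(0, cumsum(n_theta))[seq_len(max(Q, 1))]
  omega_off <- off + 2 * Q + sum(n_theta) + c(0, cumsum(n_omega))[seq_len(max(Q, 1))]
  slots <- purrr::imap(spec$random, function(r, q) {
    list(covariate = r$covariate,
         sev = r$severity,
         j = match(r$severity, nonbase),
         x = data[[r$covariate]],
         Z = if (length(r$mean_covariates))
           as.matrix(data[r$mean_covariates]) else NULL,
         W = if (length(r$variance_covariates))
           as.matrix(data[r$variance_covariates]) else NULL,
         i_mean = off + q,
         i_sd = off + Q + q,
         i_theta = if (n_theta[q]) theta_off[q] + seq_len(n_theta[q]) else integer(0),
         i_omega = if (n_omega[q]) omega_off[q] + seq_len(n_omega[q]) else integer(0))
  })
  y <- if (require_outcome) data[[outcome]] else NULL
  list(data = data, y = y, n = n, nonbase = nonbase, Xf = Xf, sev_f = sev_f,
       i_fixed = i_fixed, slots = slots, n_params = n_params(spec),
       pt = param_table(spec), spec = spec, outcome = outcome)
}

# Simulated-likelihood kernel. For each draw the four severity functions are
# evaluated (baseline fixed at zero), max-utility stabilization is applied,
# and the logit kernel gives per-draw probabilities; averaging over draws
# approximates the mixing integral. Analytic gradient and per-observation
# scores come from the standard simulated-likelihood derivative
#   dLL/dp = sum_k sum_r w_kr [1(y_k = i_p) - P_kr(i_p)] dU_{i_p}/dp,
# with w_kr = P_kr(y_k) / (R * Pbar_k).
ml_eval <- function(par, mf, draws = NULL, grad = FALSE, probs = FALSE,
                    scores = FALSE, per_draw = FALSE) {
  n <- mf$n
  Q <- length(mf$slots)
  R <- if (Q > 0) draws$n_draws else 1L
  if (Q > 0) {
    stopifnot(inherits(draws, "halton_draws"),
              draws$n_obs == n, length(draws$gammas) >= Q)
  }
  if (length(par) != mf$n_params) {
    stop("parameter vector has length ", length(par), ", expected ",
         mf$n_params, call. = FALSE)
  }
  beta_f <- par[mf$i_fixed]
  U <- vector("list", 3)
  for (j in 1:3) {
    cols <- mf$sev_f == mf$nonbase[j]
    v <- as.vector(mf$Xf[, cols, drop = FALSE] %*% beta_f[cols])
    U[[j]] <- matrix(v, n, R)
  }
  slot_state <- vector("list", Q)
  for (q in seq_len(Q)) {
    s <- mf$slots[[q]]
    gam <- draws$gammas[[q]]
    eW <- if (is.null(s$W)) rep(1, n)
          else as.vector(exp(s$W %*% par[s$i_omega]))
    mu <- par[s$i_mean] +
      if (is.null(s$Z)) 0 else as.vector(s$Z %*% par[s$i_theta])
    sd_k <- par[s$i_sd] * eW
    U[[s$j]] <- U[[s$j]] + (mu + sd_k * gam) * s$x
    slot_state[[q]] <- list(gam = gam, eW = eW, sd_k = sd_k)
  }
  M <- pmax(U[[1]], U[[2]], U[[3]], 0)
  E0 <- exp(-M)
  E1 <- exp(U[[1]] - M); E2 <- exp(U[[2]] - M); E3 <- exp(U[[3]] - M)
  D <- E0 + E1 + E2 + E3
  P <- vector("list", 4)
  P[[mf$spec$baseline]] <- E0 / D
  P[[mf$nonbase[1]]] <- E1 / D
  P[[mf$nonbase[2]]] <- E2 / D
  P[[mf$nonbase[3]]] <- E3 / D
  out <- list()
  if (probs) {
    avg <- vapply(P, rowMeans, numeric(n))
    colnames(avg) <- severity_labels()
    out$probs <- avg
    if (per_draw) out$per_draw <- P
  }
  if (!is.null(mf$y)) {
    Psel <- matrix(0, n, R)
    for (c in 1:4) {
      rows <- mf$y == c
      if (any(rows)) Psel[rows, ] <- P[[c]][rows, , drop = FALSE]
    }
    pbar <- pmax(rowMeans(Psel), .Machine$double.xmin)
    out$loglik <- sum(log(pbar))
    if (grad || scores) {
      Wt <- Psel / (R * pbar)
      g_list <- vector("list", 3)
      G_list <- vector("list", 3)
      for (j in 1:3) {
        c <- mf$nonbase[j]
        G_list[[j]] <- Wt * (as.numeric(mf$y == c) - P[[c]])
        g_list[[j]] <- rowSums(G_list[[j]])
      }
      S <- matrix(0, n, mf$n_params)
      for (j in 1:3) {
        cols <- which(mf$sev_f == mf$nonbase[j])
        S[, mf$i_fixed[cols]] <- mf$Xf[, cols, drop = FALSE] * g_list[[j]]
      }
      for (q in seq_len(Q)) {
        s <- mf$slots[[q]]
        st <- slot_state[[q]]
        g <- g_list[[s$j]]
        H <- rowSums(G_list[[s$j]] * st$gam)
        S[, s$i_mean] <- g * s$x
        if (!is.null(s$Z)) S[, s$i_theta] <- s$Z * (g * s$x)
        S[, s$i_sd] <- H * s$x * st$eW
        if (!is.null(s$W)) S[, s$i_omega] <- s$W * (H * s$x * st$sd_k)
      }
      if (grad) out$grad <- colSums(S)
      if (scores) out$scores <- S
    }
  }
  out
}

#' Realize crash-specific coefficients under heterogeneity
#'
#' Applies the heterogeneous-coefficient construction of the model: for a
#' random slot the crash-specific coefficient is
#' `beta + theta' Z + sigma * exp(omega' W) * gamma`, where `Z` shifts the
#' mean, `W` scales the standard deviation, and `gamma` is the crash's
#' standard-normal deviate. With `gamma = 0` this returns each crash's
#' conditional mean -- the quantity usually discussed when reporting
#' heterogeneity in means (e.g. a base mean of -2.117 plus a -1.347 shift
#' gives -3.464 on the shifted subpopulation).
#'
#' @param params named parameter vector (see [param_template()]).
#' @param spec an [ml_spec()] with at least one random slot.
#' @param data crash covariate data (outcome not required).
#' @param gamma matrix of standard-normal deviates, `nrow(data)` rows and
#'   one column per random slot; a single number is recycled. Default 0.
#' @return tibble with one row per crash and random slot: `id`, `term`,
#'   `mean` (conditional mean), `sd` (conditional SD `|sigma| exp(omega'W)`),
#'   `gamma`, and the realized `coefficient`.
#' @export
realize_coefficients <- function(params, spec, data, gamma = 0) {
  mf <- build_model_frame(data, spec, require_outcome = FALSE)
  params <- align_params(params, mf)
  Q <- length(mf$slots)
  if (Q == 0L) stop("spec has no random slots", call. = FALSE)
  if (is.matrix(gamma)) {
    stopifnot(nrow(gamma) == mf$n, ncol(gamma) == Q)
    gmat <- gamma
  } else {
    gmat <- matrix(gamma, mf$n, Q)
  }
  purrr::map_dfr(seq_len(Q), function(q) {
    s <- mf$slots[[q]]
    mu <- params[s$i_mean] +
      if (is.null(s$Z)) 0 else as.vector(s$Z %*% params[s$i_theta])
    scale_w <- if (is.null(s$W)) rep(1, mf$n)
               else as.vector(exp(s$W %*% params[s$i_omega]))
    gq <- gmat[, q]
    tibble::tibble(id = mf$data$id,
                   term = mf$pt$term[s$i_mean],
                   mean = mu,
                   sd = abs(params[s$i_sd]) * scale_w,
                   gamma = gq,
                   coefficient = mu + params[s$i_sd] * scale_w * gq)
  })
}

# Accept a named vector in any order (or unnamed in canonical order).
align_params <- function(params, mf) {
  if (!is.null(names(params)) && all(nzchar(names(params)))) {
    missing_p <- setdiff(mf$pt$term, names(params))
    if (length(missing_p)) {
      stop("parameter vector is missing term(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    }
    params <- params[mf$pt$term]
  } else if (length(params) != mf$n_params) {
    stop("unnamed parameter vector must have length ", mf$n_params,
         call. = FALSE)
  }
  unname(params)
}

#' Simulated choice probabilities
#'
#' Per-crash probabilities of the four severity outcomes: for each Halton
#' draw the multinomial-logit kernel is evaluated over the four severity
#' functions (baseline fixed at zero, max-utility stabilized) and the
#' results are averaged over draws. With no random slots this is the exact
#' closed-form multinomial logit.
#'
#' @inheritParams realize_coefficients
#' @param draws a [halton_draws()] block; built automatically when `NULL`.
#' @param n_draws,burn draw settings used when `draws` is `NULL`.
#' @param per_draw keep the per-draw probability matrices (as the
#'   `"per_draw"` attribute, a list of `n x R` matrices in severity-code
#'   order)?
#' @return tibble with `id` and one probability column per severity label;
#'   each row sums to one.
#' @export
ml_probabilities <- function(params, data, spec, draws = NULL,
                             n_draws = 200, burn = 10, per_draw = FALSE) {
  mf <- build_model_frame(data, spec, require_outcome = FALSE)
  params <- align_params(params, mf)
  if (is.null(draws) && length(mf$slots)) {
    draws <- halton_draws(mf$n, n_draws, length(mf$slots), burn)
  }
  ev <- ml_eval(params, mf, draws, probs = TRUE, per_draw = per_draw)
  out <- dplyr::bind_cols(tibble::tibble(id = mf$data$id),
                          tibble::as_tibble(ev$probs))
  if (per_draw) attr(out, "per_draw") <- ev$per_draw
  out
}

#' Simulated log-likelihood at given parameters
#'
#' `sum(log Pbar_k(y_k))` over the dataset, where `Pbar` is the draw-average
#' of the logit kernel. Underflowing averaged probabilities are floored at
#' the smallest positive normal double before the log, so the value is
#' finite for any finite parameter vector.
#'
#' @inheritParams ml_probabilities
#' @param outcome outcome column name.
#' @return scalar log-likelihood.
#' @export
ml_loglik <- function(params, data, spec, draws = NULL, n_draws = 200,
                      burn = 10, outcome = "severity") {
  mf <- build_model_frame(data, spec, outcome = outcome)
  params <- align_params(params, mf)
  if (is.null(draws) && length(mf$slots)) {
    draws <- halton_draws(mf$n, n_draws, length(mf$slots), burn)
  }
  ml_eval(params, mf, draws)$loglik
}
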