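#' Likelihood-ratio model separation test
#'
#' Tests whether two data subsets (e.g. peak and off-peak crashes) warrant
#' separate models. With the same variable set fitted to the pooled data and
#' to each subset, the statistic is
#' `-2 * (LL_overall - LL_a - LL_b)`, chi-square distributed with degrees of
#' freedom equal to the subset models' parameter counts minus the overall
#' model's.
#'
#' @param overall fit on the pooled data.
#' @param part_a,part_b fits on the two subsets; all three must share the
#'   same parameter structure.
#' @return one-row tibble: `kind`, `statistic`, `df`, `p.value`.
#' @export
lr_separation <- function(overall, part_a, part_b) {
  stopifnot(inherits(overall, "ml_fit"), inherits(part_a, "ml_fit"),
            inherits(part_b, "ml_fit"))
  terms_o <- names(overall$estimates)
  if (!identical(terms_o, names(part_a$estimates)) ||
      !identical(terms_o, names(part_b$estimates))) {
    stop("separation test requires identical parameter structures ",
         "across the three fits", call. = FALSE)
  }
  stat <- -2 * (overall$loglik - part_a$loglik - part_b$loglik)
  df <- part_a$n_params + part_b$n_params - overall$n_params
  lr_result("separation", stat, df)
}

#' Likelihood-ratio parameter transferability test
#'
#' Tests whether one subset's converged parameter structure transfers to the
#' other subset. `restricted` holds the log-likelihood of model a's
#' converged parameters evaluated on subset b's data (see
#' [transfer_loglik()]); `unrestricted` is the model estimated on that same
#' data. The statistic `-2 * (LL_restricted - LL_unrestricted)` is
#' chi-square with degrees of freedom equal to the number of estimated
#' parameters.
#'
#' @param unrestricted `ml_fit` estimated on the target subset.
#' @param restricted an `ml_transfer` (or `ml_fit`) whose parameters were
#'   converged elsewhere and evaluated on the target subset.
#' @return one-row tibble: `kind`, `statistic`, `df`, `p.value`.
#' @export
lr_transferability <- function(unrestricted, restricted) {
  stopifnot(inherits(unrestricted, "ml_fit"),
            inherits(restricted, c("ml_fit", "ml_transfer")))
  if (!identical(param_table(unrestricted$spec)$term,
                 param_table(restricted$spec)$term)) {
    stop("transferability test requires the same specification", call. = FALSE)
  }
  stat <- -2 * (restricted$loglik - unrestricted$loglik)
  lr_result("transferability", stat, restricted$n_params)
}

#' Likelihood-ratio test between nested ladder fits
#'
#' Compares two rungs of the heterogeneity ladder (or any nested pair fitted
#' on the same data): `-2 * (LL_restricted - LL_unrestricted)` with degrees
#' of freedom equal to the difference in parameter counts.
#'
#' @param restricted,unrestricted nested `ml_fit` objects on the same data.
#' @return one-row tibble: `kind`, `statistic`, `df`, `p.value`.
#' @export
lr_nested <- function(restricted, unrestricted) {
  stopifnot(inherits(restricted, "ml_fit"), inherits(unrestricted, "ml_fit"))
  if (unrestricted$n_params <= restricted$n_params) {
    stop("`unrestricted` must have more free parameters", call. = FALSE)
  }
  if (!all(names(restricted$estimates) %in% names(unrestricted$estimates))) {
    stop("models are not nested by parameter set", call. = FALSE)
  }
  stat <- -2 * (restricted$loglik - unrestricted$loglik)
  lr_result("nested_ladder", stat,
            unrestricted$n_params - restricted$n_params)
}

lr_result <- function(kind, stat, df) {
  if (stat < -1e-4) {
    stop("negative likelihood-ratio statistic (", format(stat),
         "); the restricted model fits better than the unrestricted one, ",
         "check convergence of the fits", call. = FALSE)
  }
  stat <- max(stat, 0)
  if (df < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  tibble::tibble(kind = kind, statistic = stat, df = as.integer(df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}
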