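#' Halton low-discrepancy sequence
#'
#' The radical-inverse sequence of a prime base: index `i` is written in
#' base-`b` digits and the digits are mirrored about the radix point, giving
#' points that fill (0, 1) far more evenly than pseudo-random numbers. These
#' are the standard quasi-Monte-Carlo nodes for simulated-likelihood
#' estimation of mixed logit models.
#'
#' @param base prime base (>= 2).
#' @param count number of points to return.
#' @param burn number of initial points to discard; the returned points are
#'   indices `burn + 1, ..., burn + count`.
#' @return numeric vector of `count` points strictly inside (0, 1).
#' @examples
#' halton_sequence(2, 3) # 1/2, 1/4, 3/4
#' @export
halton_sequence <- function(base, count, burn = 0) {
  if (length(base) != 1L || base < 2 || base %% 1 != 0 || !is_prime(base)) {
    stop("`base` must be a prime integer >= 2", call. = FALSE)
  }
  if (length(count) != 1L || count < 1 || count %% 1 != 0) {
    stop("`count` must be a positive integer", call. = FALSE)
  }
  if (burn < 0 || burn %% 1 != 0) stop("`burn` must be a non-negative integer",
                                       call. = FALSE)
  i <- (burn + 1):(burn + count)
  r <- numeric(count)
  f <- 1
  while (any(i > 0)) {
    f <- f / base
    r <- r + f * (i %% base)
    i <- i %/% base
  }
  r
}

is_prime <- function(p) {
  p <- as.integer(p)
  if (p < 2L) return(FALSE)
  if (p < 4L) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= p) {
    if (p %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

# first `k` primes, extended on demand
halton_primes <- function(k) {
  out <- integer(0)
  cand <- 2L
  while (length(out) < k) {
    if (is_prime(cand)) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

#' Standard-normal Halton draws for simulated likelihood
#'
#' Builds the deterministic draw block shared by every likelihood evaluation
#' of a fit: for random slot `q` the `q`-th prime's Halton stream (after a
#' burn-in) is transformed through the inverse normal CDF, and the
#' `n_obs * n_draws` points are partitioned consecutively by crash — crash
#' `k` receives points `(k-1) * n_draws + 1` through `k * n_draws`. There is
#' no random state: identical settings always reproduce the identical
#' matrix, which keeps the simulated objective smooth across optimizer steps
#' and runs exactly reproducible.
#'
#' @param n_obs number of crashes.
#' @param n_draws draws per crash (R). The package default of 200 follows
#'   common practice for Halton-based mixed logit estimation.
#' @param n_slots number of random coefficients (one prime base per slot).
#' @param burn initial points discarded per sequence; default 10 removes the
#'   degenerate early run of small fractions.
#' @return object of class `halton_draws`: list with `gammas` (a list of
#'   `n_obs x n_draws` matrices of standard-normal deviates, one per slot),
#'   `primes`, `n_obs`, `n_draws`, `burn`.
#' @examples
#' d <- halton_draws(n_obs = 2, n_draws = 4, n_slots = 1)
#' d$gammas[[1]]
#' @export
halton_draws <- function(n_obs, n_draws = 200, n_slots = 1, burn = 10) {
  stopifnot(n_obs >= 1, n_draws >= 1, n_slots >= 0)
  primes <- if (n_slots > 0) halton_primes(n_slots) else integer(0)
  gammas <- purrr::map(seq_len(n_slots), function(q) {
    u <- halton_sequence(primes[q], n_obs * n_draws, burn = burn)
    matrix(stats::qnorm(u), nrow = n_obs, ncol = n_draws, byrow = TRUE)
  })
  structure(list(gammas = gammas, primes = primes, n_obs = n_obs,
                 n_draws = n_draws, burn = burn),
            class = "halton_draws")
}

#' @export
print.halton_draws <- function(x, ...) {
  cat("<halton_draws>", x$n_obs, "crashes x", x$n_draws, "draws,",
      length(x$gammas), "slot(s); primes:",
      paste(x$primes, collapse = ", "), "; burn:", x$burn, "\n")
  invisible(x)
}
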