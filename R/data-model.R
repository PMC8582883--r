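#' Validate a crash data frame
#'
#' A crash dataset is an ordinary data frame with one row per crash, an
#' outcome column on the four-level severity scale, and binary 0/1 indicator
#' covariates. `validate_crash_data()` checks the contract and returns the
#' data as a tibble with the outcome coerced to integer codes 1--4 and an
#' `id` column (created from the row number when absent).
#'
#' @param data data frame of crash records.
#' @param covariates character vector of covariate column names; `NULL`
#'   (default) takes every column other than the outcome and `id`.
#' @param outcome name of the outcome column (default `"severity"`).
#' @param require_outcome set `FALSE` when validating covariate-only data
#'   (e.g. for prediction).
#' @return a tibble with columns `id`, the outcome (integer codes), and the
#'   declared covariates, row order preserved. The covariate names are kept
#'   in the `"covariates"` attribute.
#' @export
validate_crash_data <- function(data, covariates = NULL,
                                outcome = "severity",
                                require_outcome = TRUE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("crash dataset must contain at least one record",
                            call. = FALSE)
  data <- tibble::as_tibble(data)
  has_outcome <- outcome %in% names(data)
  if (require_outcome && !has_outcome) {
    stop("missing outcome column '", outcome, "'", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(outcome, "id"))
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(data)) {
    data$id <- as.character(seq_len(nrow(data)))
  } else {
    data$id <- as.character(data$id)
  }
  for (cv in covariates) {
    v <- data[[cv]]
    if (anyNA(v)) {
      stop("missing values in covariate '", cv, "' (row id ",
           data$id[which(is.na(v))[1]], "); missing data are rejected, not imputed",
           call. = FALSE)
    }
    if (!is.numeric(v) || any(v != 0 & v != 1)) {
      bad <- if (is.numeric(v)) which(v != 0 & v != 1)[1] else 1L
      stop("covariate '", cv, "' is not binary 0/1 (row id ", data$id[bad], ")",
           call. = FALSE)
    }
  }
  if (has_outcome) data[[outcome]] <- as_severity_code(data[[outcome]])
  out <- data[, c("id", if (has_outcome) outcome, covariates)]
  attr(out, "covariates") <- covariates
  attr(out, "outcome") <- if (has_outcome) outcome else NULL
  out
}

#' Read and write crash-record CSV files
#'
#' Comma-separated UTF-8 files with a mandatory header row; the severity
#' outcome may be coded as integers 1--4 or as the canonical labels
#' (`no_injury`, `minor`, `severe`, `fatal`). Covariates must be 0/1
#' indicators. Row order is preserved.
#'
#' @param path file path.
#' @param covariates covariate columns to keep; `NULL` keeps all non-outcome,
#'   non-id columns.
#' @inheritParams validate_crash_data
#' @return `read_crash_csv()` returns a validated crash tibble (see
#'   [validate_crash_data()]); `write_crash_csv()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' d <- tibble::tibble(severity = c(1, 2, 4), truck = c(0, 1, 1))
#' write_crash_csv(d, tf)
#' read_crash_csv(tf)
#' @export
read_crash_csv <- function(path, covariates = NULL, outcome = "severity") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_crash_data(raw, covariates = covariates, outcome = outcome)
}

#' @param data crash data frame to write.
#' @rdname read_crash_csv
#' @export
write_crash_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Descriptive summary of a crash dataset
#'
#' Per-covariate proportion of ones and its population standard deviation
#' `sqrt(p * (1 - p))` (the divide-by-n convention, which is the identity a
#' binary indicator satisfies), plus severity-level counts. This mirrors the
#' descriptive table usually reported alongside severity models.
#'
#' @inheritParams validate_crash_data
#' @return an object of class `crash_summary`: a list with tibbles
#'   `covariates` (`variable`, `mean`, `sd`), `severity` (`code`, `label`,
#'   `count`, `proportion`) and the sample size `n`.
#' @examples
#' d <- simulate_crashes(200, seed = 1)
#' summarize_crashes(d)
#' @export
summarize_crashes <- function(data, covariates = NULL, outcome = "severity") {
  data <- validate_crash_data(data, covariates, outcome)
  covs <- attr(data, "covariates")
  n <- nrow(data)
  cov_tbl <- purrr::map_dfr(covs, function(cv) {
    p <- mean(data[[cv]])
    tibble::tibble(variable = cv, mean = p, sd = sqrt(p * (1 - p)))
  })
  counts <- tabulate(data[[outcome]], nbins = 4L)
  sev_tbl <- dplyr::mutate(severity_levels(),
                           count = counts,
                           proportion = counts / n)
  structure(list(covariates = cov_tbl, severity = sev_tbl, n = n),
            class = "crash_summary")
}

#' @export
print.crash_summary <- function(x, ...) {
  cat("Crash dataset summary: n =", x$n, "\n\nSeverity counts:\n")
  print(x$severity, n = 4)
  cat("\nCovariates:\n")
  print(x$covariates, n = Inf)
  invisible(x)
}

#' @export
tidy.crash_summary <- function(x, ...) x$covariates

#' Export a descriptive summary as CSV
#'
#' Writes the covariate block (Variable, Mean, SD) of a [summarize_crashes()]
#' result; the severity counts go to a companion file when `severity_path`
#' is given.
#'
#' @param x a `crash_summary`.
#' @param path output CSV path for the covariate table.
#' @param severity_path optional CSV path for the severity counts.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path, severity_path = NULL) {
  stopifnot(inherits(x, "crash_summary"))
  out <- x$covariates
  names(out) <- c("Variable", "Mean", "SD")
  readr::write_csv(out, path)
  if (!is.null(severity_path)) readr::write_csv(x$severity, severity_path)
  invisible(path)
}
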