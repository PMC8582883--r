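#' Declare a severity-model specification
#'
#' A specification maps covariates into the severity functions of the three
#' non-baseline outcomes, as fixed coefficients or as normally distributed
#' random coefficients whose mean and standard deviation may shift with
#' further covariates. Slots are written in the field's bracket notation
#' `"covariate[severity]"`, e.g. `"truck[severe]"`. Alternative-specific
#' constants are always included for every non-baseline severity.
#'
#' @param fixed character vector of fixed slots (`"covariate[severity]"`), or
#'   a data frame with columns `covariate` and `severity`.
#' @param random list of random-coefficient declarations from [ml_random()].
#' @param baseline the baseline severity (label or code); its severity
#'   function is constrained to zero. Defaults to `no_injury`, the modal
#'   category in typical crash data.
#' @return an object of class `ml_spec`.
#' @examples
#' spec <- ml_spec(
#'   fixed = c("truck[severe]", "truck[fatal]"),
#'   random = list(
#'     ml_random("visibility_50_100[severe]",
#'               mean_covariates = "road_segments",
#'               variance_covariates = "traffic_control")
#'   )
#' )
#' n_params(spec)
#' @export
ml_spec <- function(fixed = character(), random = list(),
                    baseline = "no_injury") {
  base_code <- as_severity_code(baseline)
  fixed_tbl <- parse_slots(fixed)
  if (any(fixed_tbl$severity == base_code)) {
    stop("fixed slot declared on the baseline severity; the baseline ",
         "severity function is constrained to zero", call. = FALSE)
  }
  if (!is.list(random) || (length(random) && !all(purrr::map_lgl(random, inherits, "ml_random")))) {
    stop("`random` must be a list of ml_random() declarations", call. = FALSE)
  }
  for (r in random) {
    if (r$severity == base_code) {
      stop("random slot declared on the baseline severity", call. = FALSE)
    }
  }
  pairs <- c(paste(fixed_tbl$covariate, fixed_tbl$severity),
             purrr::map_chr(random, ~ paste(.x$covariate, .x$severity)))
  if (anyDuplicated(pairs)) {
    stop("duplicate (covariate, severity) slot: ",
         pairs[duplicated(pairs)][1], call. = FALSE)
  }
  spec <- structure(list(baseline = base_code,
                         fixed = fixed_tbl,
                         random = random),
                    class = "ml_spec")
  spec
}

#' Declare a random coefficient with heterogeneity links
#'
#' The coefficient of `slot` is normally distributed across crashes:
#' mean `beta + theta' Z` and standard deviation `sigma * exp(omega' W)`,
#' where `Z` (`mean_covariates`) and `W` (`variance_covariates`) are binary
#' covariates of the crash. Empty link sets give a plain random parameter.
#'
#' @param slot a single `"covariate[severity]"` string.
#' @param mean_covariates covariates shifting the mean (the Z set).
#' @param variance_covariates covariates scaling the SD (the W set).
#' @param distribution mixing distribution; only `"normal"` is supported.
#' @return an object of class `ml_random`.
#' @export
ml_random <- function(slot, mean_covariates = character(),
                      variance_covariates = character(),
                      distribution = "normal") {
  distribution <- match.arg(distribution, "normal")
  s <- parse_slots(slot)
  if (nrow(s) != 1L) stop("`slot` must be a single covariate[severity] string",
                          call. = FALSE)
  structure(list(covariate = s$covariate, severity = s$severity,
                 mean_covariates = unique(as.character(mean_covariates)),
                 variance_covariates = unique(as.character(variance_covariates)),
                 distribution = distribution),
            class = "ml_random")
}

# "covariate[severity]" strings (or a covariate/severity data frame)
# -> tibble(covariate, severity code)
parse_slots <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("covariate", "severity") %in% names(x)))
    return(tibble::tibble(covariate = as.character(x$covariate),
                          severity = as_severity_code(x$severity)))
  }
  x <- as.character(x)
  if (!length(x)) {
    return(tibble::tibble(covariate = character(), severity = integer()))
  }
  m <- regmatches(x, regexec("^\\s*([^][]+)\\[([^][]+)\\]\\s*$", x))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("cannot parse slot '", x[bad][1],
         "'; expected \"covariate[severity]\"", call. = FALSE)
  }
  tibble::tibble(covariate = trimws(purrr::map_chr(m, 2)),
                 severity = as_severity_code(purrr::map_chr(m, 3)))
}

#' @export
print.ml_spec <- function(x, ...) {
  labs <- severity_labels()
  cat("<ml_spec> baseline:", labs[x$baseline], "\n")
  cat("  constants:", paste0("const[", labs[setdiff(1:4, x$baseline)], "]",
                             collapse = ", "), "\n")
  if (nrow(x$fixed)) {
    cat("  fixed slots:", nrow(x$fixed), "\n")
  }
  for (r in x$random) {
    cat("  random:", paste0(r$covariate, "[", labs[r$severity], "]"),
        "~ normal")
    if (length(r$mean_covariates))
      cat("; mean ~", paste(r$mean_covariates, collapse = "+"))
    if (length(r$variance_covariates))
      cat("; variance ~", paste(r$variance_covariates, collapse = "+"))
    cat("\n")
  }
  cat("  free parameters:", n_params(x), "\n")
  invisible(x)
}

#' Parameter table of a specification
#'
#' Enumerates the free parameters in their canonical order: the three
#' alternative-specific constants, fixed slots in declaration order, then
#' random-slot means, standard deviations, mean links (theta) and variance
#' links (omega). This ordering is total and stable, so parameter vectors,
#' warm starts and reports line up across runs.
#'
#' @param spec an [ml_spec()].
#' @return tibble with columns `term`, `block` (`constant`, `fixed`,
#'   `rp_mean`, `rp_sd`, `rp_theta`, `rp_omega`), `covariate`, `severity`
#'   (label), and `link` (the Z/W covariate for link parameters, else `NA`).
#' @export
param_table <- function(spec) {
  stopifnot(inherits(spec, "ml_spec"))
  labs <- severity_labels()
  nonbase <- setdiff(1:4, spec$baseline)
  rows <- list(
    tibble::tibble(block = "constant", covariate = "const",
                   severity = labs[nonbase], link = NA_character_)
  )
  if (nrow(spec$fixed)) {
    rows <- c(rows, list(
      tibble::tibble(block = "fixed", covariate = spec$fixed$covariate,
                     severity = labs[spec$fixed$severity],
                     link = NA_character_)
    ))
  }
  for (blk in c("rp_mean", "rp_sd", "rp_theta", "rp_omega")) {
    for (r in spec$random) {
      links <- switch(blk,
                      rp_mean = NA_character_,
                      rp_sd = NA_character_,
                      rp_theta = r$mean_covariates,
                      rp_omega = r$variance_covariates)
      if (blk %in% c("rp_theta", "rp_omega") && !length(links)) next
      rows <- c(rows, list(
        tibble::tibble(block = blk, covariate = r$covariate,
                       severity = labs[r$severity], link = links)
      ))
    }
  }
  tbl <- dplyr::bind_rows(rows)
  suffix <- dplyr::case_when(
    tbl$block == "rp_mean" ~ ":mean",
    tbl$block == "rp_sd" ~ ":sd",
    tbl$block == "rp_theta" ~ paste0(":mean:", tbl$link),
    tbl$block == "rp_omega" ~ paste0(":sd:", tbl$link),
    TRUE ~ ""
  )
  tbl$term <- paste0(tbl$covariate, "[", tbl$severity, "]", suffix)
  tbl[, c("term", "block", "covariate", "severity", "link")]
}

#' @rdname param_table
#' @export
n_params <- function(spec) nrow(param_table(spec))

#' Named zero parameter vector for a specification
#'
#' @inheritParams param_table
#' @param values optional named values to fill in (names must be terms of
#'   [param_table()]).
#' @return named numeric vector in canonical parameter order.
#' @export
param_template <- function(spec, values = NULL) {
  pt <- param_table(spec)
  out <- stats::setNames(numeric(nrow(pt)), pt$term)
  if (!is.null(values)) {
    unknown <- setdiff(names(values), names(out))
    if (length(unknown)) {
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(values)] <- values
  }
  out
}

#' Covariates referenced by a specification
#' @inheritParams param_table
#' @return character vector of covariate names (slots plus Z/W links).
#' @export
spec_covariates <- function(spec) {
  unique(c(spec$fixed$covariate,
           purrr::map_chr(spec$random, "covariate"),
           unlist(purrr::map(spec$random, "mean_covariates")),
           unlist(purrr::map(spec$random, "variance_covariates"))))
}

#' Check a specification against a dataset
#' @inheritParams param_table
#' @param data validated crash data (or any data frame with the covariates).
#' @return `spec`, invisibly; errors name any covariate absent from `data`.
#' @export
validate_spec <- function(spec, data) {
  missing_cov <- setdiff(spec_covariates(spec), names(data))
  if (length(missing_cov)) {
    stop("spec references covariate(s) absent from data: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

#' The three-model heterogeneity ladder
#'
#' From a full mean--variance heterogeneity specification, build the nested
#' ladder typically reported side by side: (1) no mean--variance
#' heterogeneity (all Z and W links removed), (2) heterogeneity in means
#' only (W links removed), (3) the full model. The members are nested by
#' construction, so likelihood-ratio comparisons between adjacent rungs are
#' valid.
#'
#' @inheritParams param_table
#' @return named list of three `ml_spec` objects:
#'   `no_heterogeneity`, `mean_heterogeneity`, `mean_variance_heterogeneity`.
#' @export
nested_ladder <- function(spec) {
  stopifnot(inherits(spec, "ml_spec"))
  strip <- function(s, drop_mean, drop_var) {
    s$random <- purrr::map(s$random, function(r) {
      if (drop_mean) r$mean_covariates <- character()
      if (drop_var) r$variance_covariates <- character()
      r
    })
    s
  }
  list(no_heterogeneity = strip(spec, TRUE, TRUE),
       mean_heterogeneity = strip(spec, FALSE, TRUE),
       mean_variance_heterogeneity = spec)
}

# Random slots demoted to fixed slots: the spec of the MNL used for warm
# starts. Link parameters disappear with the random slots.
as_fixed_spec <- function(spec) {
  labs <- severity_labels()
  extra <- purrr::map_chr(spec$random,
                          ~ paste0(.x$covariate, "[", labs[.x$severity], "]"))
  ml_spec(fixed = c(paste0(spec$fixed$covariate, "[",
                           labs[spec$fixed$severity], "]"), extra),
          baseline = labs[spec$baseline])
}

#' Build a specification from a configuration list or YAML file
#'
#' The config schema is:
#' ```yaml
#' baseline: no_injury
#' fixed: ["truck[severe]", "truck[fatal]"]
#' random:
#'   - slot: "visibility_100_200[severe]"
#'     mean_covariates: [traffic_control]
#'     variance_covariates: [no_lights_night]
#' ```
#'
#' @param config a list with elements `fixed`, `random`, `baseline`, or the
#'   path of a YAML file holding one.
#' @param data optional dataset to validate covariates against.
#' @return an [ml_spec()].
#' @export
spec_from_config <- function(config, data = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  random <- purrr::map(config$random %||% list(), function(r) {
    ml_random(r$slot,
              mean_covariates = unlist(r$mean_covariates) %||% character(),
              variance_covariates = unlist(r$variance_covariates) %||% character())
  })
  spec <- ml_spec(fixed = unlist(config$fixed) %||% character(),
                  random = random,
                  baseline = config$baseline %||% "no_injury")
  if (!is.null(data)) validate_spec(spec, data)
  spec
}
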