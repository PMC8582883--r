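#' The four-level injury-severity scale
#'
#' Crash outcomes are recorded on a four-category KABCO-like scale:
#' no injury (property damage only), minor (visible but non-incapacitating)
#' injury, severe (incapacitating) injury, and fatal injury. The categories
#' are treated as unordered alternatives in the choice model, with
#' `no_injury` as the designated baseline whose severity function is
#' constrained to zero.
#'
#' @return `severity_levels()` returns a tibble with integer `code` (1--4)
#'   and canonical `label`; `severity_labels()` returns the labels in code
#'   order.
#' @examples
#' severity_levels()
#' @export
severity_levels <- function() {
  tibble::tibble(
    code = 1:4,
    label = c("no_injury", "minor", "severe", "fatal")
  )
}

#' @rdname severity_levels
#' @export
severity_labels <- function() {
  c("no_injury", "minor", "severe", "fatal")
}

#' Coerce severity codes or labels to integer codes 1--4
#'
#' Accepts integer codes `1:4`, numeric equivalents, or the canonical labels
#' (case-insensitive). Anything else is an error naming the offending value.
#'
#' @param x vector of codes or labels.
#' @return integer vector of codes in `1:4`.
#' @keywords internal
as_severity_code <- function(x) {
  labs <- severity_labels()
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    low <- tolower(trimws(x))
    out <- match(low, labs)
    num <- suppressWarnings(as.integer(low))
    out[is.na(out)] <- num[is.na(out)]
  } else {
    out <- suppressWarnings(as.integer(x))
    out[!is.na(out) & (x %% 1 != 0)] <- NA_integer_
  }
  bad <- is.na(out) | out < 1L | out > 4L
  if (any(bad)) {
    stop("unknown severity label/code: ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected 1-4 or ", paste(labs, collapse = "/"), ")",
         call. = FALSE)
  }
  as.integer(out)
}
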