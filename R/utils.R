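#' @keywords internal
#' @importFrom rlang abort warn inform %||% .data := inject
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Internal validation helpers. All user-facing errors carry class
# "thetakin_error" so callers (and the CLI) can distinguish input problems
# from programming errors.

stop_input <- function(msg, ...) {
  rlang::abort(msg, class = "thetakin_error", ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) != 1L) ||
      anyNA(x) || any(!is.finite(x))) {
    stop_input(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    stop_input(sprintf("`%s` must be in [%g, %g] (got %g).",
                       name, lower, upper, x[1]))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_input(sprintf("`%s` must be finite numeric.", name))
  }
  if (any(x < lower)) {
    stop_input(sprintf("`%s` must be >= %g.", name, lower))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_input(sprintf("%s is missing required column(s): %s.",
                       what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Format doubles so that write -> read -> write round-trips bit-identically.
fmt_dbl <- function(x) {
  out <- sprintf("%.17g", x)
  # trim to shortest representation that still parses back exactly
  for (digits in 1:16) {
    cand <- sprintf(paste0("%.", digits, "g"), x)
    ok <- as.numeric(cand) == x
    out[ok & out == sprintf("%.17g", x)] <- cand[ok & out == sprintf("%.17g", x)]
  }
  out
}
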