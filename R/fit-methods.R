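#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> model = %s\n", x$model))
  cat(sprintf("  kon  = %.4g M^-1 s^-1 (se %.2g)\n", x$rates$kon, x$se$kon))
  if (x$reversible) {
    cat(sprintf("  koff = %.4g s^-1 (se %.2g)\n", x$rates$koff, x$se$koff))
    cat(sprintf("  KD   = %.4g M\n", x$kd))
  } else {
    cat("  koff fixed at 0 (irreversible)\n")
  }
  cat(sprintf("  alphas: %s\n",
              paste(sprintf("%s=%.3f", x$alphas$burst_id, x$alphas$alpha),
                    collapse = ", ")))
  cat(sprintf("  rss = %.5g over %d spectra, %d parameters\n",
              x$rss, x$n_points, x$n_params))
  invisible(x)
}

#' Tidy a kinetic fit into a parameter table
#'
#' One row per estimated parameter (`kon`, `koff` if reversible, `kd`, and
#' one `alpha` per burst) with Jacobian-based standard errors; the `kd`
#' standard error is propagated from the log-space covariance of the two
#' rate constants.
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  se_kd <- if (x$reversible && is.finite(x$se$log10_kd)) {
    x$kd * log(10) * x$se$log10_kd
  } else {
    NA_real_
  }
  rows <- list(
    tibble::tibble(term = "kon", estimate = x$rates$kon,
                   std.error = x$se$kon)
  )
  if (x$reversible) {
    rows <- c(rows, list(
      tibble::tibble(term = "koff", estimate = x$rates$koff,
                     std.error = x$se$koff),
      tibble::tibble(term = "kd", estimate = x$kd, std.error = se_kd)
    ))
  }
  rows <- c(rows, list(
    tibble::tibble(term = paste0("alpha[", x$alphas$burst_id, "]"),
                   estimate = x$alphas$alpha,
                   std.error = if (length(x$se$alpha) == nrow(x$alphas)) {
                     x$se$alpha
                   } else {
                     rep(x$se$alpha[1], nrow(x$alphas))
                   })
  ))
  dplyr::bind_rows(rows)
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fitted constants, residual sum of
#'   squares and bookkeeping counts.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(model = x$model, kon = x$rates$kon, koff = x$rates$koff,
                 kd = x$kd, rss = x$rss, n_points = x$n_points,
                 n_params = x$n_params, n_bursts = nrow(x$alphas),
                 n_dropped = nrow(x$dropped),
                 converged = x$convergence$info %in% 1:4)
}

#' Plot observed and fitted kinetic curves per burst
#'
#' Observed analyte bound fractions against their assigned mixing times,
#' coloured by burst, with the fitted model curve drawn per burst at that
#' burst's mixing factor.
#'
#' @param object A `kinetic_fit`.
#' @param n_curve Points per model curve. Default 128.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_fit <- function(object, n_curve = 128, ...) {
  fitted <- object$fitted
  t_max <- max(fitted$time_s)
  curves <- dplyr::bind_rows(lapply(seq_len(nrow(object$alphas)), function(i) {
    a <- object$alphas$alpha[i]
    tt <- seq(0, t_max, length.out = n_curve)
    tibble::tibble(burst_id = object$alphas$burst_id[i], time_s = tt,
                   f_model = analyte_fraction(tt, a, object$p_total,
                                              object$l_total,
                                              object$rates$kon,
                                              object$rates$koff))
  }))
  ggplot2::ggplot(fitted,
                  ggplot2::aes(.data$time_s, .data$f_analyte,
                               colour = .data$burst_id)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$f_model)) +
    ggplot2::labs(x = "mixing time (s)", y = "analyte bound fraction",
                  colour = "burst",
                  title = sprintf("Global 1:1 kinetic fit (%s)", object$model),
                  subtitle = sprintf("kon = %.3g M^-1 s^-1, koff = %.3g s^-1",
                                     object$rates$kon, object$rates$koff))
}
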