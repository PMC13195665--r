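#' Internal-standard timer system
#'
#' The mixing timer is a binding pair with known kinetics -- typically a
#' nanobody recognising an epitope tag -- loaded in the two channels of a
#' theta emitter. The epitope-bearing protein travels in the protein
#' channel and the nanobody in the other, so after mixing with factor
#' `alpha` the initial concentrations are `alpha * epitope_total` and
#' `(1 - alpha) * nb_total`.
#'
#' @param epitope_total Epitope-protein concentration in its channel, M.
#' @param nb_total Nanobody concentration in the opposite channel, M.
#' @param rates Known [rate_constants] of the timer pair. `koff = 0` is
#'   allowed for effectively irreversible timers (ALFA-tag-like pairs whose
#'   dissociation is unmeasurable on the experiment's time scale).
#' @return An object of class `timer_system`.
#' @examples
#' # the GFP(EPEA)-NbAS style timer: 1 uM epitope protein vs 2 uM nanobody
#' tm <- timer_system(1e-6, 2e-6, rate_constants(3.6e5, 9.4e-6))
#' build_curve(tm, alpha = 0.5)
#' @export
timer_system <- function(epitope_total, nb_total, rates) {
  check_number(epitope_total, "epitope_total")
  check_number(nb_total, "nb_total")
  if (epitope_total <= 0 || nb_total <= 0) {
    stop_input("Timer channel concentrations must be positive.")
  }
  stopifnot(inherits(rates, "rate_constants"))
  structure(list(epitope_total = epitope_total, nb_total = nb_total,
                 rates = rates),
            class = "timer_system")
}

#' @export
print.timer_system <- function(x, ...) {
  cat(sprintf("<timer_system> epitope %.4g M | nanobody %.4g M\n",
              x$epitope_total, x$nb_total))
  print(x$rates)
  invisible(x)
}

#' Theoretical timer binding curve under a mixing factor
#'
#' Builds the calibration curve mapping droplet lifetime (mixing time) to
#' the timer protein's bound fraction, given the mixing factor `alpha`:
#' `P0 = alpha * epitope_total`, `L0 = (1 - alpha) * nb_total`, and
#' `f(t) = [PL](t) / P0` from the closed-form 1:1 solution. The curve starts
#' at 0, increases strictly, and approaches the equilibrium plateau
#' `equilibrium_bound(P0, L0, KD) / P0` (or `min(P0, L0)/P0` for an
#' irreversible timer).
#'
#' @param timer A [timer_system].
#' @param alpha Mixing factor in (0, 1); 0.5 is ideal 1:1 mixing.
#' @return An object of class `calibration_curve` with fields `alpha`,
#'   `p0`, `l0`, `rates`, `plateau_fraction` and `evaluator` (a vectorised
#'   function of time).
#' @export
build_curve <- function(timer, alpha) {
  stopifnot(inherits(timer, "timer_system"))
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) {
    stop_input("`alpha` must lie strictly inside (0, 1).")
  }
  p0 <- alpha * timer$epitope_total
  l0 <- (1 - alpha) * timer$nb_total
  kon <- timer$rates$kon
  koff <- timer$rates$koff
  kd <- koff / kon
  plateau <- equilibrium_bound(p0, l0, kd) / p0
  evaluator <- function(t) complex_cf(t, p0, l0, kon, koff) / p0
  structure(list(alpha = alpha, p0 = p0, l0 = l0,
                 rates = timer$rates, kd = kd,
                 plateau_fraction = plateau, evaluator = evaluator),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> alpha = %.3g, P0 = %.4g M, L0 = %.4g M, plateau = %.4g\n",
    x$alpha, x$p0, x$l0, x$plateau_fraction))
  invisible(x)
}

# Exact analytic inverse of the closed-form curve. f must be < plateau.
invert_time_analytic <- function(curve, f) {
  p0 <- curve$p0
  l0 <- curve$l0
  kon <- curve$rates$kon
  kd <- curve$kd
  cc <- f * p0
  if (kd == 0 && abs(p0 - l0) < 1e-9 * max(p0, l0)) {
    # degenerate second-order branch: C = P0^2 kon t / (1 + P0 kon t)
    return(cc / (p0 * kon * (p0 - cc)))
  }
  r <- complex_roots(p0, l0, kd)
  r1 <- r[["r1"]]
  r2 <- r[["r2"]]
  e <- r2 * (r1 - cc) / (r1 * (r2 - cc))
  -log(e) / (kon * (r2 - r1))
}

#' Assign a mixing time from an observed timer bound fraction
#'
#' Inverts a [build_curve()] calibration curve: finds the droplet lifetime
#' `t` at which the theoretical timer bound fraction equals the observed
#' one. The closed-form curve is inverted analytically (exactly); a
#' bracketed root-finding route (`method = "bisection"`, geometric bracket
#' expansion + `stats::uniroot`) is available for cross-checking.
#'
#' Observed fractions at (or numerically indistinguishable from) the
#' equilibrium plateau carry no time information: the spectrum has fully
#' equilibrated. Those are rejected (default) or returned as `NA` so the
#' caller can drop them; they are never assigned a capped time, which would
#' bias downstream fits.
#'
#' @param curve A `calibration_curve`.
#' @param f_obs Observed timer bound fraction(s), >= 0. Vectorised.
#' @param eps Plateau tolerance: fractions >= `plateau * (1 - eps)` are
#'   treated as equilibrated. Default 0.01.
#' @param on_equilibrated `"error"` (default) or `"na"` (return `NA_real_`
#'   with a warning).
#' @param method `"analytic"` (default) or `"bisection"`.
#' @return Mixing time(s), s.
#' @export
invert_time <- function(curve, f_obs, eps = 0.01,
                        on_equilibrated = c("error", "na"),
                        method = c("analytic", "bisection")) {
  stopifnot(inherits(curve, "calibration_curve"))
  on_equilibrated <- match.arg(on_equilibrated)
  method <- match.arg(method)
  check_numeric_vec(f_obs, "f_obs")
  if (any(f_obs < 0)) stop_input("`f_obs` must be non-negative.")
  plateau <- curve$plateau_fraction
  eq <- f_obs >= plateau * (1 - eps)
  if (any(eq)) {
    if (on_equilibrated == "error") {
      stop_input(sprintf(
        "equilibrated spectrum: %d observed fraction(s) within %g of the plateau (%.4g); time unresolvable",
        sum(eq), eps, plateau))
    }
    rlang::warn(sprintf(
      "%d equilibrated spectrum/spectra (timer at plateau); returning NA.",
      sum(eq)))
  }
  out <- rep(NA_real_, length(f_obs))
  ok <- !eq
  if (any(ok)) {
    if (method == "analytic") {
      out[ok] <- invert_time_analytic(curve, f_obs[ok])
    } else {
      out[ok] <- vapply(f_obs[ok], function(f) {
        if (f == 0) return(0)
        hi <- 1
        while (curve$evaluator(hi) < f) hi <- hi * 2
        stats::uniroot(function(t) curve$evaluator(t) - f,
                       lower = 0, upper = hi, tol = 1e-12)$root
      }, numeric(1))
    }
  }
  out
}

#' Time window over which a timer resolves mixing times
#'
#' The usable window of a calibration curve: the times at which the bound
#' fraction reaches `lo` and `hi` of its equilibrium plateau. Outside this
#' window the curve is too flat (early) or too close to equilibrium (late)
#' for the observed fraction to pin down a time accurately.
#'
#' @param curve A `calibration_curve`.
#' @param lo,hi Plateau fractions defining the window, `0 < lo < hi < 1`.
#'   Defaults 0.05 and 0.95.
#' @return A tibble with columns `t_lo` and `t_hi` (seconds).
#' @export
sensitivity_window <- function(curve, lo = 0.05, hi = 0.95) {
  stopifnot(inherits(curve, "calibration_curve"))
  check_number(lo, "lo")
  check_number(hi, "hi")
  if (!(lo > 0 && lo < hi && hi < 1)) {
    stop_input("Need 0 < lo < hi < 1.")
  }
  plateau <- curve$plateau_fraction
  t_lo <- invert_time(curve, lo * plateau, eps = 0)
  t_hi <- invert_time(curve, hi * plateau, eps = 0)
  tibble::tibble(t_lo = t_lo, t_hi = t_hi)
}

#' Plot a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param t_max Right edge of the plotted time axis, s. Defaults to a little
#'   past the 95% sensitivity window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_curve <- function(object, t_max = NULL, ...) {
  if (is.null(t_max)) {
    t_max <- 1.2 * sensitivity_window(object)$t_hi
  }
  tt <- seq(0, t_max, length.out = 256)
  df <- tibble::tibble(time = tt, bound_fraction = object$evaluator(tt))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$bound_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$plateau_fraction,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "mixing time (s)", y = "timer bound fraction",
      title = sprintf("Timer calibration curve (alpha = %.2f)", object$alpha)
    )
}
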