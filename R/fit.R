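#' Options controlling the global kinetic fit
#'
#' @param kon_bounds,koff_bounds Box constraints for the rate constants
#'   (M^-1 s^-1 and s^-1). Optimisation runs in log10 space inside these.
#' @param alpha_bounds Box constraints for mixing factors.
#' @param eps_equilibrated Plateau tolerance passed to the time inversion:
#'   spectra whose timer fraction is within this relative distance of the
#'   calibration plateau are excluded from the objective (they carry no
#'   time information).
#' @param alpha_start Starting mixing factor, also the reference alpha used
#'   to pre-screen equilibrated spectra. Default 0.5 (ideal mixing).
#' @param starts Data frame of deterministic multi-start values with
#'   columns `kon` and `koff`; the best final residual sum of squares wins.
#'   The default is the 3 x 2 grid kon in {1e4, 1e5, 1e6} by koff in
#'   {1e-3, 1e-1}.
#' @param min_spectra_per_burst Bursts with fewer usable spectra are
#'   dropped with a warning. Default 3.
#' @param recompute_times If `TRUE` (default) mixing times are re-inverted
#'   from the timer margin at the current alpha on every objective
#'   evaluation; `FALSE` caches times at `alpha_start` (an approximation,
#'   off by default).
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(kon_bounds = c(1e2, 1e10),
                        koff_bounds = c(1e-6, 1e3),
                        alpha_bounds = c(0.05, 0.95),
                        eps_equilibrated = 0.01,
                        alpha_start = 0.5,
                        starts = NULL,
                        min_spectra_per_burst = 3,
                        recompute_times = TRUE,
                        maxiter = 200) {
  if (is.null(starts)) {
    starts <- expand.grid(kon = c(1e4, 1e5, 1e6), koff = c(1e-3, 1e-1))
  }
  check_columns(starts, c("kon", "koff"), "`starts`")
  structure(list(kon_bounds = kon_bounds, koff_bounds = koff_bounds,
                 alpha_bounds = alpha_bounds,
                 eps_equilibrated = eps_equilibrated,
                 alpha_start = alpha_start, starts = starts,
                 min_spectra_per_burst = min_spectra_per_burst,
                 recompute_times = recompute_times, maxiter = maxiter),
            class = "fit_options")
}

# Split validated fraction data into per-burst lists used by the objective.
prepare_fit_data <- function(fractions, timer, options) {
  check_columns(fractions, c("burst_id", "scan_index", "f_timer",
                             "f_analyte"), "`fractions`")
  if (!"emitter_id" %in% names(fractions)) {
    fractions$emitter_id <- "E1"
  }
  check_numeric_vec(fractions$f_timer, "f_timer", lower = 0)
  check_numeric_vec(fractions$f_analyte, "f_analyte", lower = 0)
  screen <- build_curve(timer, options$alpha_start)
  eps <- options$eps_equilibrated
  fractions <- dplyr::arrange(fractions, .data$emitter_id, .data$burst_id,
                              .data$scan_index)
  fractions$usable <-
    fractions$f_timer < screen$plateau_fraction * (1 - eps)
  dropped <- fractions[!fractions$usable, ]
  if (nrow(dropped) > 0) {
    rlang::inform(sprintf(
      "Excluding %d equilibrated spectrum/spectra (timer at plateau).",
      nrow(dropped)))
  }
  usable <- fractions[fractions$usable, ]
  counts <- dplyr::count(usable, .data$burst_id)
  thin <- counts$burst_id[counts$n < options$min_spectra_per_burst]
  if (length(thin) > 0) {
    rlang::warn(sprintf(
      "Dropping burst(s) with fewer than %d usable spectra: %s",
      options$min_spectra_per_burst, paste(thin, collapse = ", ")))
    dropped <- dplyr::bind_rows(dropped,
                                usable[usable$burst_id %in% thin, ])
    usable <- usable[!usable$burst_id %in% thin, ]
  }
  if (nrow(usable) == 0) stop_input("No usable spectra remain.")
  burst_ids <- unique(usable$burst_id)
  bursts <- lapply(burst_ids, function(b) {
    sub <- usable[usable$burst_id == b, ]
    list(burst_id = b, f_timer = sub$f_timer, f_analyte = sub$f_analyte,
         meta = sub[, c("emitter_id", "burst_id", "scan_index")])
  })
  list(bursts = bursts, burst_ids = burst_ids, usable = usable,
       dropped = dropped)
}

# Timer fractions -> times at mixing factor alpha, vectorised, with the
# near-plateau region clamped so the objective stays finite and continuous
# while alpha moves during optimisation.
times_at_alpha <- function(timer, alpha, f_timer) {
  curve <- build_curve(timer, alpha)
  cap <- curve$plateau_fraction * (1 - 1e-9)
  invert_time_analytic(curve, pmin(f_timer, cap))
}

# Model analyte bound fraction at times t under mixing factor alpha.
analyte_fraction <- function(t, alpha, p_total, l_total, kon, koff) {
  p0 <- alpha * p_total
  l0 <- (1 - alpha) * l_total
  complex_cf(t, p0, l0, kon, koff) / p0
}

#' Globally fit 1:1 binding kinetics across bursts
#'
#' Fits the association and dissociation rate constants of the analyte
#' interaction to all spectra at once. Each spectrum contributes one
#' residual: the observed analyte bound fraction minus the model bound
#' fraction at that spectrum's mixing time. The mixing time itself is
#' obtained by inverting the timer calibration curve at the burst's mixing
#' factor, and is recomputed whenever the mixing factor moves, so the
#' factor enters the objective both through the calibration curve and
#' through the model's initial concentrations.
#'
#' With `model = "shared_alpha"` one mixing factor is shared by every
#' burst; with `"per_burst_alpha"` each burst gets its own (the model the
#' nested F-test compares against). Optimisation is bounded
#' Levenberg-Marquardt (`minpack.lm::nls.lm`) over (log10 kon, log10 koff,
#' alphas), started from a deterministic multi-start grid; the fit is fully
#' deterministic.
#'
#' @param fractions Per-spectrum bound fractions: a tibble with columns
#'   `burst_id`, `scan_index`, `f_timer`, `f_analyte` (and optionally
#'   `emitter_id`), as produced by [mole_fractions()].
#' @param timer The [timer_system()] with known rate constants.
#' @param p_total,l_total Analyte protein and ligand concentrations in
#'   their channels, M.
#' @param model `"per_burst_alpha"` (default) or `"shared_alpha"`.
#' @param reversible If `FALSE`, `koff` is fixed at 0 and only `kon` and
#'   the mixing factor(s) are estimated (covalent/irreversible ligands).
#' @param options A [fit_options()] list.
#' @param extra_starts Optional data frame of additional starts with
#'   columns `kon`, `koff` and optionally `alpha` (a single shared value or
#'   `NA`); used e.g. to seed the per-burst model from the shared optimum.
#' @return An object of class `kinetic_fit`; see [tidy.kinetic_fit()],
#'   [glance.kinetic_fit()], [autoplot.kinetic_fit()].
#' @examples
#' cfg <- simulation_config(seed = 7, noise_sigma = 0)
#' sim <- simulate_dataset(cfg)
#' fr <- mole_fractions(sim$records)
#' fit <- fit_global(fr, cfg$timer, cfg$p_total, cfg$l_total)
#' glance(fit)
#' @export
fit_global <- function(fractions, timer, p_total, l_total,
                       model = c("per_burst_alpha", "shared_alpha"),
                       reversible = TRUE,
                       options = fit_options(),
                       extra_starts = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(timer, "timer_system"))
  check_number(p_total, "p_total")
  check_number(l_total, "l_total")
  if (p_total <= 0) stop_input("`p_total` must be positive.")
  if (l_total <= 0) {
    stop_input("`l_total` must be positive: with no ligand the association rate is unidentifiable.")
  }
  data <- prepare_fit_data(fractions, timer, options)
  bursts <- data$bursts
  n_bursts <- length(bursts)
  n_alpha <- if (model == "per_burst_alpha") n_bursts else 1L
  n_kin <- if (reversible) 2L else 1L
  n_params <- n_kin + n_alpha
  n_points <- sum(vapply(bursts, function(b) length(b$f_timer), integer(1)))
  if (n_points <= n_params) {
    stop_input(sprintf(
      "Underdetermined fit: %d usable spectra for %d parameters.",
      n_points, n_params))
  }

  cached_times <- NULL
  if (!options$recompute_times) {
    cached_times <- lapply(bursts, function(b) {
      times_at_alpha(timer, options$alpha_start, b$f_timer)
    })
  }

  residual_fn <- function(par) {
    kon <- 10^par[1]
    koff <- if (reversible) 10^par[2] else 0
    alphas <- par[(n_kin + 1):(n_kin + n_alpha)]
    unlist(lapply(seq_len(n_bursts), function(i) {
      a <- if (n_alpha == 1L) alphas[1] else alphas[i]
      t <- if (is.null(cached_times)) {
        times_at_alpha(timer, a, bursts[[i]]$f_timer)
      } else {
        cached_times[[i]]
      }
      bursts[[i]]$f_analyte -
        analyte_fraction(t, a, p_total, l_total, kon, koff)
    }), use.names = FALSE)
  }

  lower <- c(log10(options$kon_bounds[1]),
             if (reversible) log10(options$koff_bounds[1]),
             rep(options$alpha_bounds[1], n_alpha))
  upper <- c(log10(options$kon_bounds[2]),
             if (reversible) log10(options$koff_bounds[2]),
             rep(options$alpha_bounds[2], n_alpha))

  starts <- options$starts
  starts$alpha <- NA_real_
  if (!is.null(extra_starts)) {
    extra_starts <- dplyr::as_tibble(extra_starts)
    if (!"alpha" %in% names(extra_starts)) extra_starts$alpha <- NA_real_
    starts <- dplyr::bind_rows(starts[, c("kon", "koff", "alpha")],
                               extra_starts[, c("kon", "koff", "alpha")])
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    a0 <- if (is.na(starts$alpha[s])) options$alpha_start else starts$alpha[s]
    par0 <- c(log10(starts$kon[s]),
              if (reversible) log10(max(starts$koff[s],
                                        options$koff_bounds[1])),
              rep(a0, n_alpha))
    par0 <- pmin(pmax(par0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$maxiter, ftol = 1e-12,
                           ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(fit = res, rss = rss, start = s)
    }
  }
  if (is.null(best)) {
    stop_input("Global fit failed to converge from every start.")
  }

  par <- best$fit$par
  kon <- 10^par[1]
  koff <- if (reversible) 10^par[2] else 0
  alphas <- par[(n_kin + 1):(n_kin + n_alpha)]
  alpha_by_burst <- if (n_alpha == 1L) rep(alphas, n_bursts) else alphas

  fitted <- dplyr::bind_rows(lapply(seq_len(n_bursts), function(i) {
    a <- alpha_by_burst[i]
    t <- times_at_alpha(timer, a, bursts[[i]]$f_timer)
    fm <- analyte_fraction(t, a, p_total, l_total, kon, koff)
    dplyr::bind_cols(bursts[[i]]$meta,
                     tibble::tibble(alpha = a, time_s = t,
                                    f_timer = bursts[[i]]$f_timer,
                                    f_analyte = bursts[[i]]$f_analyte,
                                    f_model = fm,
                                    residual = bursts[[i]]$f_analyte - fm))
  }))

  se <- fit_std_errors(residual_fn, par, best$rss, n_points, n_params,
                       reversible, n_alpha)

  structure(list(
    rates = rate_constants(kon, koff),
    kd = koff / kon,
    alphas = tibble::tibble(burst_id = data$burst_ids,
                            alpha = alpha_by_burst),
    model = if (!reversible) "irreversible" else model,
    reversible = reversible,
    rss = best$rss,
    n_points = n_points,
    n_params = n_params,
    fitted = fitted,
    dropped = data$dropped,
    se = se,
    timer = timer,
    p_total = p_total, l_total = l_total,
    convergence = list(info = best$fit$info,
                       message = best$fit$message,
                       niter = best$fit$niter,
                       start_index = best$start)
  ), class = "kinetic_fit")
}

# Jacobian-based standard errors at the optimum (finite differences on the
# residual vector); returned in natural units via the delta method.
fit_std_errors <- function(residual_fn, par, rss, n, p, reversible,
                           n_alpha) {
  r0 <- residual_fn(par)
  jac <- vapply(seq_along(par), function(j) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    (residual_fn(`[<-`(par, j, par[j] + h)) - r0) / h
  }, numeric(length(r0)))
  sigma2 <- rss / (n - p)
  vcov <- tryCatch(sigma2 * solve(crossprod(jac)),
                   error = function(e) NULL)
  if (is.null(vcov)) {
    return(list(kon = NA_real_, koff = NA_real_,
                log10_kd = NA_real_, alpha = rep(NA_real_, n_alpha)))
  }
  sd_par <- sqrt(pmax(diag(vcov), 0))
  kon <- 10^par[1]
  se_kon <- kon * log(10) * sd_par[1]
  if (reversible) {
    koff <- 10^par[2]
    se_koff <- koff * log(10) * sd_par[2]
    v_lkd <- vcov[1, 1] + vcov[2, 2] - 2 * vcov[1, 2]
    se_lkd <- sqrt(max(v_lkd, 0))
    ia <- 3:(2 + n_alpha)
  } else {
    se_koff <- 0
    se_lkd <- NA_real_
    ia <- 2:(1 + n_alpha)
  }
  list(kon = se_kon, koff = se_koff, log10_kd = se_lkd,
       alpha = sd_par[ia])
}

#' Fit an irreversible (covalent) binding interaction
#'
#' Convenience wrapper around [fit_global()] with `koff` fixed at 0: only
#' the association rate constant and the mixing factor(s) are estimated.
#' Appropriate when the complex never dissociates on the experimental time
#' scale, e.g. a covalent inhibitor whose rate-limiting step is
#' irreversible (the reversible encounter complex and the covalent adduct
#' have the same mass and cannot be distinguished in the spectrum).
#'
#' @inheritParams fit_global
#' @return A `kinetic_fit` with `model = "irreversible"`.
#' @export
fit_irreversible <- function(fractions, timer, p_total, l_total,
                             model = c("per_burst_alpha", "shared_alpha"),
                             options = fit_options(),
                             extra_starts = NULL) {
  fit_global(fractions, timer, p_total, l_total, model = match.arg(model),
             reversible = FALSE, options = options,
             extra_starts = extra_starts)
}

#' Nested-model F-test between two kinetic fits
#'
#' Classical extra-sum-of-squares F-test comparing a reduced model (e.g.
#' one mixing factor shared by all bursts) against a full model that nests
#' it (e.g. one mixing factor per burst):
#' `F = ((RSS_r - RSS_f) / (p_f - p_r)) / (RSS_f / (n - p_f))`,
#' with the p-value from the F distribution on `(p_f - p_r, n - p_f)`
#' degrees of freedom. If the full model's RSS is not smaller, F is clamped
#' at 0 (p = 1).
#'
#' @param reduced,full `kinetic_fit` objects on the same data, with
#'   `full$n_params > reduced$n_params`.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`,
#'   `rss_reduced`, `rss_full`.
#' @export
f_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "kinetic_fit"), inherits(full, "kinetic_fit"))
  if (reduced$n_points != full$n_points) {
    stop_input("The two fits use different numbers of spectra; they must be fitted on the same dataset.")
  }
  n <- full$n_points
  p_r <- reduced$n_params
  p_f <- full$n_params
  if (p_f <= p_r) stop_input("`full` must have more parameters than `reduced`.")
  if (n <= p_f) stop_input("Not enough points for the comparison (n <= p_full).")
  df1 <- p_f - p_r
  df2 <- n - p_f
  f_stat <- max(0, ((reduced$rss - full$rss) / df1) / (full$rss / df2))
  tibble::tibble(statistic = f_stat, df1 = df1, df2 = df2,
                 p.value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 rss_reduced = reduced$rss, rss_full = full$rss)
}

#' Fit both mixing-factor models and select by F-test
#'
#' Fits the shared-alpha model, then the per-burst-alpha model (seeded
#' additionally from the shared optimum, so the nested models can never
#' invert), applies [f_test()] at `signif`, and reports the statistically
#' justified model.
#'
#' @inheritParams fit_global
#' @param signif Significance level for preferring the per-burst model.
#' @return List of class `alpha_model_comparison` with elements `shared`,
#'   `per_burst`, `f_test`, `selected` (`"shared_alpha"` or
#'   `"per_burst_alpha"`) and `fit` (the selected `kinetic_fit`).
#' @export
compare_alpha_models <- function(fractions, timer, p_total, l_total,
                                 reversible = TRUE,
                                 options = fit_options(),
                                 signif = 0.05) {
  shared <- fit_global(fractions, timer, p_total, l_total,
                       model = "shared_alpha", reversible = reversible,
                       options = options)
  seed <- tibble::tibble(kon = shared$rates$kon,
                         koff = max(shared$rates$koff, 1e-6),
                         alpha = shared$alphas$alpha[1])
  per_burst <- fit_global(fractions, timer, p_total, l_total,
                          model = "per_burst_alpha",
                          reversible = reversible, options = options,
                          extra_starts = seed)
  ft <- f_test(shared, per_burst)
  selected <- if (ft$p.value < signif) "per_burst_alpha" else "shared_alpha"
  structure(list(shared = shared, per_burst = per_burst, f_test = ft,
                 selected = selected,
                 fit = if (selected == "per_burst_alpha") per_burst else shared),
            class = "alpha_model_comparison")
}

#' @export
print.alpha_model_comparison <- function(x, ...) {
  cat("<alpha_model_comparison>\n")
  cat(sprintf("  shared alpha   : rss %.5g (%d params)\n",
              x$shared$rss, x$shared$n_params))
  cat(sprintf("  per-burst alpha: rss %.5g (%d params)\n",
              x$per_burst$rss, x$per_burst$n_params))
  cat(sprintf("  F = %.3g on (%d, %d) df, p = %.3g -> %s\n",
              x$f_test$statistic, x$f_test$df1, x$f_test$df2,
              x$f_test$p.value, x$selected))
  invisible(x)
}

#' Flag bursts that deviate from the global fit
#'
#' Computes each burst's root-mean-square residual and flags bursts whose
#' RMS exceeds `threshold` times the RMS pooled over the *other* bursts
#' (leave-one-out pooling, so a single grossly deviating burst cannot mask
#' itself by inflating the reference scale). Flags are advisory: deciding
#' to exclude a burst and refit is an explicit user action, as when curves
#' deviating markedly from the fitted kinetics are discarded after
#' inspection.
#'
#' @param fit A `kinetic_fit`.
#' @param threshold Multiplier on the leave-one-out pooled RMS residual.
#'   Default 3.
#' @return Tibble: `burst_id`, `n`, `rms_residual`, `ratio`, `flag`.
#' @export
flag_outlier_bursts <- function(fit, threshold = 3) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    stop_input("`threshold` must be a non-negative number (Inf allowed).")
  }
  per <- fit$fitted |>
    dplyr::group_by(.data$burst_id) |>
    dplyr::summarise(n = dplyr::n(),
                     ss = sum(.data$residual^2),
                     rms_residual = sqrt(mean(.data$residual^2)),
                     .groups = "drop")
  tot_ss <- sum(per$ss)
  tot_n <- sum(per$n)
  per |>
    dplyr::mutate(
      loo_rms = sqrt((tot_ss - .data$ss) / pmax(tot_n - .data$n, 1)),
      ratio = ifelse(.data$loo_rms > 0,
                     .data$rms_residual / .data$loo_rms, Inf),
      flag = .data$loo_rms > 0 & .data$rms_residual > 0 &
        .data$rms_residual > threshold * .data$loo_rms) |>
    dplyr::select("burst_id", "n", "rms_residual", "ratio", "flag")
}

#' Aggregate kinetic fits across emitter replicates
#'
#' Headline rate constants and their uncertainties are reported as the mean
#' and sample standard deviation across independent emitter replicates.
#' The dissociation constant is computed per replicate as that replicate's
#' `koff / kon` and then averaged -- never as the ratio of the averaged
#' rates.
#'
#' @param fits A named list of `kinetic_fit` objects, one per emitter
#'   replicate (names are the emitter ids).
#' @return Object of class `replicate_summary`: a list with
#'   `per_replicate` (one row per emitter: kon, koff, kd, rss, n_points)
#'   and `summary` (one row per parameter: mean, sd, n). With a single
#'   replicate the mean is reported and the SD is `NA` with a warning.
#' @export
summarize_replicates <- function(fits) {
  if (!is.list(fits) || length(fits) == 0 ||
      !all(vapply(fits, inherits, logical(1), "kinetic_fit"))) {
    stop_input("`fits` must be a non-empty list of kinetic_fit objects.")
  }
  ids <- names(fits) %||% paste0("replicate_", seq_along(fits))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    ids <- paste0("replicate_", seq_along(fits))
  }
  per <- dplyr::bind_rows(lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tibble::tibble(emitter_id = ids[i], kon = f$rates$kon,
                   koff = f$rates$koff, kd = f$kd, rss = f$rss,
                   n_points = f$n_points, model = f$model)
  }))
  single <- nrow(per) == 1
  if (single) {
    rlang::warn("Single replicate: standard deviations are undefined (NA).")
  }
  summ <- per |>
    tidyr::pivot_longer(c("kon", "koff", "kd"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (single) NA_real_ else stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$parameter, c("kon", "koff", "kd")))
  structure(list(per_replicate = per, summary = summ,
                 sd_defined = !single),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %d replicate(s)\n",
              nrow(x$per_replicate)))
  print(x$summary)
  invisible(x)
}

#' @rdname summarize_replicates
#' @param x A `replicate_summary`.
#' @param ... Unused.
#' @export
tidy.replicate_summary <- function(x, ...) {
  x$summary
}
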