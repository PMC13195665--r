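#' Configuration for the synthetic-data generator
#'
#' Describes a simulated time-resolved native MS experiment: bursts of
#' spectra whose latent mixing times, timer occupancies and analyte
#' occupancies follow the 1:1 kinetic model under per-burst mixing factors,
#' with additive truncated Gaussian noise on the bound fractions.
#'
#' The defaults emulate the benchmark GFP-Nb15 regime timed by the
#' GFP(EPEA)-NbAS pair: analyte truth kon 1.3e5 M^-1 s^-1 and koff 1.3e-2
#' s^-1; channel totals 1.6 uM protein and 4 uM nanobody (0.8 and 2 uM
#' after ideal 2-fold dilution); a timer with 1 uM epitope protein, 2 uM
#' nanobody, kon 3.6e5 and koff 9.4e-6; five bursts of fifteen spectra;
#' latent times log-uniform over 0.1-40 s, matching the observed 0-40 s
#' span with burst decay toward short times; mixing factors drawn per burst
#' from [0.4, 0.6]; and fraction noise sigma 0.02.
#'
#' @param kon,koff Ground-truth analyte rate constants (M^-1 s^-1, s^-1).
#'   `koff = 0` simulates an irreversible ligand.
#' @param p_total,l_total Analyte channel totals, M.
#' @param timer A [timer_system()] (known rates).
#' @param n_bursts,spectra_per_burst Burst structure.
#' @param alpha Explicit mixing factor(s): scalar (shared) or one value per
#'   burst. Overrides `alpha_range` when given.
#' @param alpha_range Length-2 range from which per-burst mixing factors
#'   are drawn uniformly. Default `c(0.4, 0.6)`.
#' @param time_range Length-2 bounds of the latent mixing-time
#'   distribution, s.
#' @param time_schedule `"log_uniform"` (default) or `"exp_decay"`
#'   (`t_s = t_max * exp(-s / tau)` within each burst, mimicking the decay
#'   of mixing times over a voltage cycle).
#' @param tau Decay constant (in scans) for the `"exp_decay"` schedule.
#' @param noise_sigma SD of the additive Gaussian noise on bound fractions
#'   (truncated to `[0, plateau]`).
#' @param mode `"nonfusion"` or `"fusion"` species layout.
#' @param total_intensity Nominal per-margin intensity scale of the emitted
#'   abundances.
#' @param emitter_id Emitter label for the generated records.
#' @param seed Integer seed; mandatory, every draw is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(kon = 1.3e5, koff = 1.3e-2,
                              p_total = 1.6e-6, l_total = 4e-6,
                              timer = timer_system(1e-6, 2e-6,
                                                   rate_constants(3.6e5, 9.4e-6)),
                              n_bursts = 5, spectra_per_burst = 15,
                              alpha = NULL, alpha_range = c(0.4, 0.6),
                              time_range = c(0.1, 40),
                              time_schedule = c("log_uniform", "exp_decay"),
                              tau = 5,
                              noise_sigma = 0.02,
                              mode = c("nonfusion", "fusion"),
                              total_intensity = 1000,
                              emitter_id = "E1",
                              seed) {
  time_schedule <- match.arg(time_schedule)
  mode <- match.arg(mode)
  if (missing(seed)) stop_input("`seed` is mandatory.")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    stop_input("`seed` must be a single integer.")
  }
  rates <- rate_constants(kon, koff)
  stopifnot(inherits(timer, "timer_system"))
  check_number(p_total, "p_total")
  check_number(l_total, "l_total")
  if (p_total <= 0 || l_total <= 0) {
    stop_input("Channel totals must be positive.")
  }
  check_number(n_bursts, "n_bursts", lower = 1)
  check_number(spectra_per_burst, "spectra_per_burst", lower = 1)
  if (!is.null(alpha)) {
    check_numeric_vec(alpha, "alpha")
    if (!length(alpha) %in% c(1L, n_bursts)) {
      stop_input("`alpha` must be a scalar or one value per burst.")
    }
    if (any(alpha <= 0 | alpha >= 1)) stop_input("`alpha` must be in (0, 1).")
  }
  check_numeric_vec(alpha_range, "alpha_range")
  check_numeric_vec(time_range, "time_range")
  if (length(time_range) != 2 || time_range[1] <= 0 ||
      time_range[2] <= time_range[1]) {
    stop_input("`time_range` must be positive and increasing.")
  }
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(tau, "tau")
  structure(list(rates = rates, p_total = p_total, l_total = l_total,
                 timer = timer, n_bursts = as.integer(n_bursts),
                 spectra_per_burst = as.integer(spectra_per_burst),
                 alpha = alpha, alpha_range = alpha_range,
                 time_range = time_range, time_schedule = time_schedule,
                 tau = tau, noise_sigma = noise_sigma, mode = mode,
                 total_intensity = total_intensity,
                 emitter_id = emitter_id, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d burst(s) x %d spectra, %s, seed %d\n",
    x$n_bursts, x$spectra_per_burst, x$mode, x$seed))
  print(x$rates)
  invisible(x)
}

truncnorm_clip <- function(x, sigma, lo, hi) {
  pmin(pmax(x + stats::rnorm(length(x), 0, sigma), lo), hi)
}

#' Simulate a time-resolved native MS dataset with known ground truth
#'
#' Forward model of the experiment: for each spectrum a latent mixing time
#' is drawn from the configured schedule, the timer and analyte bound
#' fractions are evaluated from the 1:1 closed-form model at the burst's
#' mixing factor, independent Gaussian noise (truncated to `[0, plateau]`)
#' is added to each fraction, and species abundances are emitted as the
#' fractions scaled to a nominal total intensity. Fully reproducible from
#' `config$seed`; the global RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_dataset`: `records` (canonical
#'   species-abundance tibble), `truth` (list with `rates`, `alphas` tibble
#'   and per-spectrum `spectra` tibble holding latent times and noise-free
#'   fractions), and `config`.
#' @examples
#' sim <- simulate_dataset(simulation_config(seed = 1))
#' dplyr::count(sim$records, burst_id)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  nb <- config$n_bursts
  ns <- config$spectra_per_burst
  burst_ids <- sprintf("burst_%02d", seq_len(nb))

  alphas <- if (!is.null(config$alpha)) {
    rep(config$alpha, length.out = nb)
  } else {
    stats::runif(nb, config$alpha_range[1], config$alpha_range[2])
  }

  # warn when the timer cannot resolve any of the latent times
  screen <- build_curve(config$timer, 0.5)
  win <- sensitivity_window(screen)
  if (win$t_lo > config$time_range[2] || win$t_hi < config$time_range[1]) {
    rlang::warn("Timer sensitivity window does not overlap the latent time distribution: the timer is uninformative for this configuration.")
  }

  kon <- config$rates$kon
  koff <- config$rates$koff

  per_burst <- lapply(seq_len(nb), function(i) {
    a <- alphas[i]
    t <- switch(config$time_schedule,
      log_uniform = exp(stats::runif(ns, log(config$time_range[1]),
                                     log(config$time_range[2]))),
      exp_decay = config$time_range[2] *
        exp(-(seq_len(ns) - 1) / config$tau)
    )
    curve <- build_curve(config$timer, a)
    f_timer_true <- curve$evaluator(t)
    p0 <- a * config$p_total
    l0 <- (1 - a) * config$l_total
    f_analyte_true <- complex_cf(t, p0, l0, kon, koff) / p0
    plateau_analyte <- if (koff > 0) {
      equilibrium_bound(p0, l0, koff / kon) / p0
    } else {
      min(p0, l0) / p0
    }
    sigma <- config$noise_sigma
    f_timer_obs <- if (sigma > 0) {
      truncnorm_clip(f_timer_true, sigma, 0, curve$plateau_fraction)
    } else {
      f_timer_true
    }
    f_analyte_obs <- if (sigma > 0) {
      truncnorm_clip(f_analyte_true, sigma, 0, plateau_analyte)
    } else {
      f_analyte_true
    }
    tibble::tibble(
      emitter_id = config$emitter_id, burst_id = burst_ids[i],
      scan_index = seq_len(ns), time_s = t, alpha = a,
      f_timer_true = f_timer_true, f_analyte_true = f_analyte_true,
      f_timer = f_timer_obs, f_analyte = f_analyte_obs
    )
  })
  spectra <- dplyr::bind_rows(per_burst)

  records <- fractions_to_records(spectra, config$mode,
                                  config$total_intensity)

  truth <- list(
    rates = config$rates,
    alphas = tibble::tibble(burst_id = burst_ids, alpha = alphas),
    spectra = spectra
  )
  structure(list(records = records, truth = truth, config = config),
            class = "simulated_dataset")
}

# Emit species abundances whose margins reproduce the observed fractions.
# Fusion mode assumes independent occupancy of the two sites, so the joint
# state abundances factorise.
fractions_to_records <- function(spectra, mode, total_intensity) {
  long <- if (mode == "nonfusion") {
    spectra |>
      dplyr::reframe(
        species = c("timer_apo", "timer_bound", "analyte_apo",
                    "analyte_bound"),
        abundance = total_intensity *
          c((1 - .data$f_timer), .data$f_timer,
            (1 - .data$f_analyte), .data$f_analyte),
        .by = c("emitter_id", "burst_id", "scan_index"))
  } else {
    spectra |>
      dplyr::reframe(
        species = c("apo", "timer_bound", "analyte_bound", "both_bound"),
        abundance = total_intensity *
          c((1 - .data$f_timer) * (1 - .data$f_analyte),
            .data$f_timer * (1 - .data$f_analyte),
            (1 - .data$f_timer) * .data$f_analyte,
            .data$f_timer * .data$f_analyte),
        .by = c("emitter_id", "burst_id", "scan_index"))
  }
  dplyr::arrange(long, .data$emitter_id, .data$burst_id, .data$scan_index,
                 .data$species)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d spectra in %d burst(s)\n",
              nrow(x$truth$spectra), nrow(x$truth$alphas)))
  print(x$config$rates)
  invisible(x)
}

#' Write a simulated dataset to fixture files
#'
#' Writes the canonical species-abundance table
#' (`<prefix>_species.tsv`) and a ground-truth sidecar
#' (`<prefix>_truth.tsv`) with per-spectrum latent time, per-burst mixing
#' factor and the global rate constants. Both files round-trip exactly:
#' write, read, write produces identical bytes.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix. Default `"dataset"`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_fixture <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  species_path <- file.path(dir, paste0(prefix, "_species.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_species_table(dataset$records, species_path)
  truth <- dataset$truth$spectra |>
    dplyr::select("emitter_id", "burst_id", "scan_index", "time_s",
                  "alpha", "f_timer_true", "f_analyte_true") |>
    dplyr::mutate(kon = dataset$truth$rates$kon,
                  koff = dataset$truth$rates$koff,
                  dplyr::across(dplyr::where(is.double), fmt_dbl))
  readr::write_tsv(truth, truth_path, progress = FALSE)
  invisible(c(species = species_path, truth = truth_path))
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir Directory containing the fixture.
#' @param prefix File-name prefix used when writing.
#' @param mode Species vocabulary of the records.
#' @return List with `records` and `truth` tibbles.
#' @export
read_fixture <- function(dir, prefix = "dataset",
                         mode = c("nonfusion", "fusion")) {
  mode <- match.arg(mode)
  species_path <- file.path(dir, paste0(prefix, "_species.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  records <- read_species_table(species_path, mode = mode)
  truth <- readr::read_tsv(truth_path, progress = FALSE,
                           col_types = readr::cols(
                             emitter_id = readr::col_character(),
                             burst_id = readr::col_character(),
                             scan_index = readr::col_integer(),
                             .default = readr::col_character()))
  for (nm in setdiff(names(truth),
                     c("emitter_id", "burst_id", "scan_index"))) {
    truth[[nm]] <- as.numeric(truth[[nm]])
  }
  list(records = records, truth = truth)
}
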