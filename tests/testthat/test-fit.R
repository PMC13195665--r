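fit_quiet <- function(...) suppressWarnings(suppressMessages(fit_global(...)))

test_that("noise-free data yields exact recovery with a shared alpha", {
  cfg <- simulation_config(seed = 31, alpha = 0.5, noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- fit_quiet(fr, cfg$timer, cfg$p_total, cfg$l_total,
                   model = "shared_alpha")
  expect_equal(fit$rates$kon, 1.3e5, tolerance = 1e-6)
  expect_equal(fit$rates$koff, 1.3e-2, tolerance = 1e-6)
  expect_equal(unique(fit$alphas$alpha), 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("noise-free data yields exact per-burst alpha recovery", {
  cfg <- simulation_config(seed = 32, alpha = c(0.4, 0.5, 0.6),
                           n_bursts = 3, noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- fit_quiet(fr, cfg$timer, cfg$p_total, cfg$l_total,
                   model = "per_burst_alpha")
  expect_equal(fit$alphas$alpha, c(0.4, 0.5, 0.6), tolerance = 1e-5)
  expect_equal(fit$rates$kon, 1.3e5, tolerance = 1e-5)
  expect_equal(fit$rates$koff, 1.3e-2, tolerance = 1e-5)
})

test_that("recovered kinetics do not depend on which timer clocked them", {
  # same analyte, two very different (valid) timers, noise-free data with
  # times inside each timer's sensitivity window
  base <- list(kon = 1.3e5, koff = 1.3e-2, p_total = 1.6e-6,
               l_total = 4e-6)
  fast <- timer_system(1e-6, 2e-6, rate_constants(3.6e5, 9.4e-6))
  slow <- timer_system(1e-6, 4e-6, rate_constants(8.6e4, 0)) # ALFA-like
  fits <- lapply(list(fast, slow), function(tm) {
    cfg <- simulation_config(kon = base$kon, koff = base$koff,
                             p_total = base$p_total, l_total = base$l_total,
                             timer = tm, alpha = 0.5, noise_sigma = 0,
                             time_range = c(0.5, 8), seed = 33)
    sim <- simulate_dataset(cfg)
    fr <- mole_fractions(sim$records)
    fit_quiet(fr, tm, cfg$p_total, cfg$l_total, model = "shared_alpha")
  })
  expect_equal(fits[[1]]$rates$kon, fits[[2]]$rates$kon, tolerance = 1e-4)
  expect_equal(fits[[1]]$rates$koff, fits[[2]]$rates$koff, tolerance = 1e-4)
})

test_that("equilibrated spectra are excluded from the objective", {
  cfg <- simulation_config(seed = 34, noise_sigma = 0,
                           time_range = c(0.5, 200))
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- fit_quiet(fr, cfg$timer, cfg$p_total, cfg$l_total)
  cv <- build_curve(cfg$timer, 0.5)
  expect_gt(nrow(fit$dropped), 0)
  expect_true(all(fit$dropped$f_timer >= cv$plateau_fraction * 0.99))
  expect_true(all(fit$fitted$f_timer < cv$plateau_fraction * 0.99))
  expect_equal(nrow(fit$fitted) + nrow(fit$dropped), 75)
})

test_that("irreversible fits recover kon with koff fixed at zero", {
  tm <- timer_system(1e-6, 4e-6, rate_constants(8.6e4, 1.41e-3))
  cfg <- simulation_config(kon = 8e5, koff = 0, p_total = 8e-6,
                           l_total = 8e-6, timer = tm, alpha = 0.5,
                           noise_sigma = 0, seed = 35)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- suppressWarnings(suppressMessages(
    fit_irreversible(fr, tm, cfg$p_total, cfg$l_total,
                     model = "shared_alpha")))
  expect_equal(fit$rates$kon, 8e5, tolerance = 1e-4)
  expect_identical(fit$rates$koff, 0)
  expect_equal(fit$model, "irreversible")
  expect_equal(fit$n_params, 1 + 1)
})

test_that("fitting reversible data as irreversible leaves late-time bias", {
  cfg <- simulation_config(seed = 36, alpha = 0.5, noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- suppressWarnings(suppressMessages(
    fit_irreversible(fr, cfg$timer, cfg$p_total, cfg$l_total,
                     model = "shared_alpha")))
  late <- fit$fitted[fit$fitted$time_s >
                       stats::median(fit$fitted$time_s), ]
  # the irreversible model saturates at full occupancy, above the true
  # reversible plateau, so late observed fractions sit below the model
  expect_lt(mean(late$residual), 0)
})

test_that("degenerate inputs are rejected with informative errors", {
  cfg <- simulation_config(seed = 37, n_bursts = 1, spectra_per_burst = 3,
                           noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  # zero ligand: kon unidentifiable
  expect_error(fit_quiet(fr, cfg$timer, cfg$p_total, 0),
               class = "thetakin_error")
  # 3 usable spectra cannot constrain 2 + 1 parameters... underdetermined
  expect_error(
    suppressWarnings(suppressMessages(
      fit_global(fr, cfg$timer, cfg$p_total, cfg$l_total,
                 model = "per_burst_alpha",
                 options = fit_options(min_spectra_per_burst = 3)))),
    class = "thetakin_error")
})

test_that("the F statistic follows the extra-sum-of-squares formula", {
  # worked arithmetic: rss 2.0 -> 1.0, p 3 -> 7, n = 57:
  # F = ((2-1)/4) / (1/50) = 12.5
  red <- fake_fit(2.0, 57, 3)
  full <- fake_fit(1.0, 57, 7)
  ft <- f_test(red, full)
  expect_equal(ft$statistic, 12.5)
  expect_equal(ft$df1, 4)
  expect_equal(ft$df2, 50)
  expect_equal(ft$p.value, stats::pf(12.5, 4, 50, lower.tail = FALSE))
  # identical models: F clamps to 0, p = 1
  ft0 <- f_test(fake_fit(1.0, 57, 3), fake_fit(1.0, 57, 7))
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p.value, 1)
  # a "full" model that fits worse also clamps
  ftw <- f_test(fake_fit(1.0, 57, 3), fake_fit(1.2, 57, 7))
  expect_equal(ftw$statistic, 0)
  expect_error(f_test(full, red), class = "thetakin_error")
  expect_error(f_test(fake_fit(2, 8, 3), fake_fit(1, 8, 9)),
               class = "thetakin_error")
})

test_that("the per-burst model never fits worse than the shared model", {
  for (s in 41:44) {
    cfg <- simulation_config(seed = s, n_bursts = 3)
    sim <- simulate_dataset(cfg)
    fr <- mole_fractions(sim$records)
    cmp <- suppressWarnings(suppressMessages(
      compare_alpha_models(fr, cfg$timer, cfg$p_total, cfg$l_total)))
    expect_lte(cmp$per_burst$rss, cmp$shared$rss + 1e-12)
    expect_equal(cmp$shared$n_points, cmp$per_burst$n_points)
  }
})

test_that("corrupted bursts are flagged and clean ones are not", {
  cfg <- simulation_config(seed = 45, noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  clean <- fit_quiet(fr, cfg$timer, cfg$p_total, cfg$l_total)
  expect_false(any(flag_outlier_bursts(clean)$flag))
  # shuffle one burst's analyte fractions: kinetics scrambled
  fr2 <- fr
  idx <- which(fr2$burst_id == "burst_03")
  set.seed(1)
  fr2$f_analyte[idx] <- sample(fr2$f_analyte[idx])
  bad <- fit_quiet(fr2, cfg$timer, cfg$p_total, cfg$l_total)
  flags <- flag_outlier_bursts(bad)
  expect_true(flags$flag[flags$burst_id == "burst_03"])
  # an infinite threshold flags nothing
  expect_false(any(flag_outlier_bursts(bad, threshold = Inf)$flag))
})

test_that("replicate summaries average KD per replicate, not rates", {
  mk <- function(kon, koff) {
    structure(list(rates = rate_constants(kon, koff), kd = koff / kon,
                   rss = 0.01, n_points = 60, model = "per_burst_alpha"),
              class = "kinetic_fit")
  }
  fits <- list(E1 = mk(1.0e5, 1.0e-2), E2 = mk(1.2e5, 1.8e-2),
               E3 = mk(1.4e5, 1.1e-2))
  rs <- summarize_replicates(fits)
  summ <- rs$summary
  expect_equal(summ$mean[summ$parameter == "kon"], 1.2e5)
  expect_equal(summ$sd[summ$parameter == "kon"], sd(c(1.0, 1.2, 1.4) * 1e5))
  kds <- c(1.0e-2 / 1.0e5, 1.8e-2 / 1.2e5, 1.1e-2 / 1.4e5)
  expect_equal(summ$mean[summ$parameter == "kd"], mean(kds))
  # the wrong branch (ratio of means) would give a different number
  expect_false(isTRUE(all.equal(summ$mean[summ$parameter == "kd"],
                                mean(c(1.0, 1.8, 1.1) * 1e-2) / 1.2e5)))
  # identical replicates: zero SD
  rs2 <- summarize_replicates(list(A = mk(1e5, 1e-2), B = mk(1e5, 1e-2)))
  expect_equal(rs2$summary$sd, rep(0, 3))
  # single replicate: SD undefined
  expect_warning(rs1 <- summarize_replicates(list(A = mk(1e5, 1e-2))),
                 "Single replicate")
  expect_true(all(is.na(rs1$summary$sd)))
  expect_false(rs1$sd_defined)
})

test_that("tidiers and plots expose the fitted quantities", {
  cfg <- simulation_config(seed = 46, n_bursts = 2, noise_sigma = 0)
  sim <- simulate_dataset(cfg)
  fr <- mole_fractions(sim$records)
  fit <- fit_quiet(fr, cfg$timer, cfg$p_total, cfg$l_total)
  td <- tidy(fit)
  expect_setequal(td$term,
                  c("kon", "koff", "kd", "alpha[burst_01]",
                    "alpha[burst_02]"))
  gl <- glance(fit)
  expect_equal(gl$kon, fit$rates$kon)
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(build_curve(cfg$timer, 0.5))
  expect_s3_class(p2, "ggplot")
})
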