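test_that("species tables round-trip through write and read", {
  sim <- simulate_dataset(simulation_config(seed = 11, n_bursts = 2,
                                            spectra_per_burst = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_species_table(sim$records, path)
  back <- read_species_table(path)
  expect_equal(back, sim$records)
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_species_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("reading groups records by emitter, burst and scan", {
  rec <- dplyr::bind_rows(lapply(1:2, function(b) {
    dplyr::bind_rows(lapply(1:3, function(s) {
      nonfusion_record(0.2 * s, 0.1 * s, burst = paste0("b", b), scan = s)
    }))
  }))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_species_table(rec[sample(nrow(rec)), ], path) # shuffled on disk
  back <- read_species_table(path)
  spectra <- dplyr::distinct(back, burst_id, scan_index)
  expect_equal(nrow(spectra), 6)
  expect_false(is.unsorted(order(spectra$burst_id, spectra$scan_index)))
})

test_that("malformed species tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  file.create(path)
  expect_warning(out <- read_species_table(path), "Empty")
  expect_equal(nrow(out), 0)

  bad_species <- nonfusion_record(0.5, 0.5)
  bad_species$species[1] <- "mystery_peak"
  write_species_table(bad_species, path)
  expect_error(read_species_table(path), class = "thetakin_error")

  dup <- dplyr::bind_rows(nonfusion_record(0.5, 0.5),
                          nonfusion_record(0.6, 0.4))
  write_species_table(dup, path)
  expect_error(read_species_table(path), "Duplicate",
               class = "thetakin_error")

  neg <- nonfusion_record(0.5, 0.5)
  neg$abundance[1] <- -5
  write_species_table(neg, path)
  expect_error(read_species_table(path), class = "thetakin_error")

  expect_error(read_species_table(tempfile()), class = "thetakin_error")
})

test_that("mole fractions implement the corrected bound/total rule", {
  rec <- nonfusion_record(0.5, 0.2)
  fr <- mole_fractions(rec)
  expect_equal(fr$f_timer, 0.5)
  expect_equal(fr$f_analyte, 0.2)
  # response factor 2 on the timer-bound species: 100/(50 + 100) = 2/3
  fr2 <- mole_fractions(rec, rf = response_factors(timer_bound = 2))
  expect_equal(fr2$f_timer, 2 / 3)
  expect_equal(fr2$f_analyte, 0.2) # other margin untouched
  # unit response factors are the identity
  fr3 <- mole_fractions(rec, rf = response_factors(timer_bound = 1,
                                                   analyte_bound = 1))
  expect_equal(fr3, fr)
})

test_that("fusion-mode ternary species count on both margins", {
  # hand-enumerated 4-species contingency: apo 10, +Nb(timer) 20,
  # +ligand(analyte) 30, ternary 40
  rec <- tibble::tibble(
    emitter_id = "E1", burst_id = "b1", scan_index = 1L,
    species = c("apo", "timer_bound", "analyte_bound", "both_bound"),
    abundance = c(10, 20, 30, 40))
  fr <- mole_fractions(rec, mode = "fusion")
  expect_equal(fr$f_timer, (20 + 40) / 100)
  expect_equal(fr$f_analyte, (30 + 40) / 100)
})

test_that("zero-intensity margins are uninformative", {
  rec <- nonfusion_record(0.5, 0.2)
  rec$abundance[rec$species %in% c("analyte_apo", "analyte_bound")] <- 0
  expect_error(mole_fractions(rec), "uninformative",
               class = "thetakin_error")
  expect_warning(out <- mole_fractions(rec, on_empty = "drop"), "Dropped")
  expect_equal(nrow(out), 0)
})

test_that("response factors recover from synthetic mixtures", {
  k <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # perfect agreement -> r = 1
  rf1 <- estimate_response_factors(
    tibble::tibble(known_fraction = k, observed_fraction = k))
  expect_equal(as.numeric(rf1), 1, tolerance = 1e-5)
  # forward-generate with r = 1.2, invert
  obs <- 1.2 * k / (1.2 * k + (1 - k))
  rf2 <- estimate_response_factors(
    tibble::tibble(known_fraction = k, observed_fraction = obs))
  expect_equal(as.numeric(rf2), 1.2, tolerance = 1e-5)
  expect_named(rf2, "timer_bound")
  # a single mixture cannot identify the factor
  expect_error(estimate_response_factors(
    tibble::tibble(known_fraction = 0.5, observed_fraction = 0.55)),
    class = "thetakin_error")
  expect_error(estimate_response_factors(
    tibble::tibble(known_fraction = c(0.5, 0.5),
                   observed_fraction = c(0.55, 0.56))),
    class = "thetakin_error")
})

test_that("fractions convert to concentrations through the dilution", {
  expect_equal(fraction_to_concentration(0, 1e-6, 0.5), 0)
  expect_equal(fraction_to_concentration(1, 1e-6, 0.5), 0.5e-6)
  expect_equal(fraction_to_concentration(0.3, 0.8e-6, 0.4), 9.6e-8)
  expect_error(fraction_to_concentration(1.2, 1e-6, 0.5),
               class = "thetakin_error")
  expect_error(fraction_to_concentration(0.5, 1e-6, 1),
               class = "thetakin_error")
})
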