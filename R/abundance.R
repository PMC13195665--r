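#' Species vocabulary for a timing strategy
#'
#' In the *nonfusion* strategy the timer pair and the analyte are distinct
#' proteins, so each spectrum carries four independent species: the timer
#' protein with and without its nanobody, and the analyte protein with and
#' without its ligand. In the *fusion* strategy the timer epitope is fused
#' to the analyte itself, so one protein carries both occupancy margins and
#' the four species are the joint states: apo, nanobody-only, ligand-only,
#' and the ternary complex carrying both. The ternary species contributes
#' to the bound side of *both* margins.
#'
#' @param mode `"nonfusion"` or `"fusion"`.
#' @return Character vector of allowed species labels.
#' @export
species_vocabulary <- function(mode = c("nonfusion", "fusion")) {
  mode <- match.arg(mode)
  if (mode == "nonfusion") {
    c("timer_apo", "timer_bound", "analyte_apo", "analyte_bound")
  } else {
    c("apo", "timer_bound", "analyte_bound", "both_bound")
  }
}

# abundance is read as text and converted with base R's correctly rounded
# strtod so that write -> read round-trips are bit-exact
species_cols <- readr::cols(
  emitter_id = readr::col_character(),
  burst_id = readr::col_character(),
  scan_index = readr::col_integer(),
  species = readr::col_character(),
  abundance = readr::col_character()
)

#' Read a per-spectrum species-abundance table
#'
#' Reads the canonical deconvoluted-abundance format: delimited text with a
#' header row and columns `emitter_id`, `burst_id`, `scan_index`, `species`,
#' `abundance` -- one row per (spectrum, species). Spectral deconvolution
#' itself is upstream of this package; any deconvolution tool whose
#' per-species abundances can be exported to this layout is supported.
#'
#' @param path Path to a tab- (default) or comma-delimited file; `.csv`
#'   extension selects comma.
#' @param mode Timing strategy, fixes the allowed species vocabulary.
#' @return A tibble ordered by emitter, burst and scan.
#' @export
read_species_table <- function(path, mode = c("nonfusion", "fusion")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop_input(sprintf("No such file: %s", path))
  empty <- tibble::tibble(emitter_id = character(), burst_id = character(),
                          scan_index = integer(), species = character(),
                          abundance = double())
  if (file.size(path) == 0) {
    rlang::warn(sprintf("Empty species table: %s", path))
    return(empty)
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = species_cols,
                          progress = FALSE)
  check_columns(df, names(empty), "Species table")
  df <- dplyr::select(df, dplyr::all_of(names(empty)))
  df$abundance <- as.numeric(df$abundance)
  if (nrow(df) == 0) {
    rlang::warn(sprintf("Species table has no rows: %s", path))
    return(empty)
  }
  validate_species_records(df, mode)
}

validate_species_records <- function(df, mode) {
  vocab <- species_vocabulary(mode)
  bad <- setdiff(unique(df$species), vocab)
  if (length(bad) > 0) {
    stop_input(sprintf("Unknown species label(s) for %s mode: %s",
                       mode, paste(bad, collapse = ", ")))
  }
  if (anyNA(df$abundance) || any(df$abundance < 0)) {
    stop_input("Abundances must be non-negative and non-missing.")
  }
  if (anyNA(df$scan_index)) stop_input("`scan_index` must be integer.")
  dup <- df |>
    dplyr::count(.data$emitter_id, .data$burst_id, .data$scan_index,
                 .data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_input(sprintf(
      "Duplicate (emitter, burst, scan, species) rows, e.g. %s/%s/%d/%s.",
      dup$emitter_id[1], dup$burst_id[1], dup$scan_index[1], dup$species[1]))
  }
  dplyr::arrange(df, .data$emitter_id, .data$burst_id, .data$scan_index,
                 .data$species)
}

#' Write a species-abundance table
#'
#' Writes the canonical format read by [read_species_table()]. Numeric
#' abundances are written with enough digits that a write/read/write cycle
#' is byte-identical.
#'
#' @param records Tibble with the canonical columns.
#' @param path Output path (`.csv` selects comma-delimited).
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path) {
  check_columns(records, c("emitter_id", "burst_id", "scan_index",
                           "species", "abundance"), "`records`")
  out <- records |>
    dplyr::mutate(abundance = fmt_dbl(.data$abundance))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Response-factor corrections
#'
#' Multiplicative per-species corrections for unequal MS signal per mole
#' between apo and complexed species. A factor of 1 (the default for every
#' species) leaves abundances untouched.
#'
#' @param ... Named positive factors, e.g. `response_factors(timer_bound = 1.2)`.
#' @return A named numeric vector of class `response_factors`.
#' @export
response_factors <- function(...) {
  rf <- c(...)
  if (length(rf) > 0) {
    if (is.null(names(rf)) || any(names(rf) == "")) {
      stop_input("All response factors must be named by species.")
    }
    check_numeric_vec(unname(rf), "response factors")
    if (any(rf <= 0)) stop_input("Response factors must be positive.")
  }
  structure(as.numeric(rf), names = names(rf), class = "response_factors")
}

rf_for <- function(rf, species) {
  out <- rep(1, length(species))
  if (length(rf) > 0) {
    hit <- match(species, names(rf))
    out[!is.na(hit)] <- as.numeric(rf)[hit[!is.na(hit)]]
  }
  out
}

margin_map <- function(mode) {
  if (mode == "nonfusion") {
    list(timer = list(bound = "timer_bound", all = c("timer_apo", "timer_bound")),
         analyte = list(bound = "analyte_bound",
                        all = c("analyte_apo", "analyte_bound")))
  } else {
    vocab <- species_vocabulary("fusion")
    list(timer = list(bound = c("timer_bound", "both_bound"), all = vocab),
         analyte = list(bound = c("analyte_bound", "both_bound"), all = vocab))
  }
}

#' Per-spectrum bound mole fractions
#'
#' Converts species abundances into the dimensionless observables the
#' kinetic fit uses: for every spectrum, the timer margin's bound fraction
#' (response-factor-corrected bound intensity over corrected apo + bound)
#' and likewise for the analyte margin. In fusion mode the ternary species
#' counts as bound on both margins.
#'
#' @param records Tibble in the canonical species-table layout.
#' @param mode Timing strategy; fixes species vocabulary and margin pooling.
#' @param rf Optional [response_factors()].
#' @param on_empty What to do with a spectrum whose margin has zero total
#'   corrected intensity (an uninformative spectrum): `"error"` (default)
#'   or `"drop"` with a warning.
#' @return Tibble with columns `emitter_id`, `burst_id`, `scan_index`,
#'   `f_timer`, `f_analyte`.
#' @examples
#' rec <- tibble::tibble(
#'   emitter_id = "E1", burst_id = "b1", scan_index = 1L,
#'   species = c("timer_apo", "timer_bound", "analyte_apo", "analyte_bound"),
#'   abundance = c(50, 50, 80, 20)
#' )
#' mole_fractions(rec)
#' @export
mole_fractions <- function(records, mode = c("nonfusion", "fusion"),
                           rf = NULL, on_empty = c("error", "drop")) {
  mode <- match.arg(mode)
  on_empty <- match.arg(on_empty)
  records <- validate_species_records(records, mode)
  rf <- rf %||% response_factors()
  mm <- margin_map(mode)
  corrected <- records |>
    dplyr::mutate(corrected = .data$abundance * rf_for(rf, .data$species))
  one_margin <- function(margin) {
    corrected |>
      dplyr::filter(.data$species %in% mm[[margin]]$all) |>
      dplyr::group_by(.data$emitter_id, .data$burst_id, .data$scan_index) |>
      dplyr::summarise(
        total = sum(.data$corrected),
        bound = sum(.data$corrected[.data$species %in% mm[[margin]]$bound]),
        .groups = "drop") |>
      dplyr::mutate(!!paste0("f_", margin) :=
                      ifelse(.data$total > 0, .data$bound / .data$total,
                             NA_real_)) |>
      dplyr::select(-"total", -"bound")
  }
  out <- dplyr::full_join(one_margin("timer"), one_margin("analyte"),
                          by = c("emitter_id", "burst_id", "scan_index"))
  bad <- !stats::complete.cases(out[, c("f_timer", "f_analyte")])
  if (any(bad)) {
    msg <- sprintf("%d uninformative spectrum/spectra with a zero-intensity margin.",
                   sum(bad))
    if (on_empty == "error") stop_input(msg)
    rlang::warn(paste(msg, "Dropped."))
    out <- out[!bad, ]
  }
  dplyr::arrange(out, .data$emitter_id, .data$burst_id, .data$scan_index)
}

#' Estimate a bound-species response factor from calibration mixtures
#'
#' Given mixtures with known solution bound fractions and the bound
#' fractions observed by MS (the mixing experiment that varies the ratio of
#' apo protein to purified complex), estimates the single multiplicative
#' factor `r` for the bound species by least squares on
#' `observed = r k / (r k + (1 - k))` where `k` is the known fraction.
#'
#' @param mixtures Data frame with numeric columns `known_fraction` and
#'   `observed_fraction`, both in `[0, 1]`, at two or more distinct known
#'   fractions.
#' @param species Species label the factor applies to (names the returned
#'   factor). Default `"timer_bound"`.
#' @return A [response_factors()] vector of length one.
#' @examples
#' k <- c(0.2, 0.4, 0.6, 0.8)
#' obs <- 1.2 * k / (1.2 * k + (1 - k))
#' estimate_response_factors(
#'   tibble::tibble(known_fraction = k, observed_fraction = obs)
#' )
#' @export
estimate_response_factors <- function(mixtures, species = "timer_bound") {
  check_columns(mixtures, c("known_fraction", "observed_fraction"),
                "`mixtures`")
  k <- mixtures$known_fraction
  obs <- mixtures$observed_fraction
  check_numeric_vec(k, "known_fraction")
  check_numeric_vec(obs, "observed_fraction")
  if (any(k < 0 | k > 1) || any(obs < 0 | obs > 1)) {
    stop_input("Fractions must lie in [0, 1].")
  }
  if (length(unique(k)) < 2) {
    stop_input("Need >= 2 mixtures at distinct known fractions; the response factor is unidentifiable otherwise.")
  }
  sse <- function(logr) {
    r <- exp(logr)
    pred <- r * k / (r * k + (1 - k))
    sum((obs - pred)^2)
  }
  opt <- stats::optimize(sse, interval = c(-12, 12), tol = 1e-12)
  do.call(response_factors, stats::setNames(list(exp(opt$minimum)), species))
}

#' Convert a bound fraction to a concentration
#'
#' A species in the protein channel is diluted by the mixing factor, so its
#' bound concentration in the droplet is `f * alpha * total`.
#'
#' @param f Bound mole fraction(s) in `[0, 1]`.
#' @param total Channel total concentration, M.
#' @param alpha Mixing factor in (0, 1).
#' @return Bound concentration(s), M.
#' @export
fraction_to_concentration <- function(f, total, alpha) {
  check_numeric_vec(f, "f")
  if (any(f < 0 | f > 1)) stop_input("`f` must lie in [0, 1].")
  check_number(total, "total")
  if (total <= 0) stop_input("`total` must be positive.")
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_input("`alpha` must be in (0, 1).")
  f * alpha * total
}
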