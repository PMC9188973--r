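#' Cohort composition for the accelerated longitudinal design
#'
#' @param n_by_scan_count named integer vector: number of participants with
#'   1, 2 and 3 scans. The default (40/31/27) yields 98 participants and 183
#'   scans.
#' @param age_range starting-age range in years.
#' @param interval inter-scan interval in years (default 1.5, i.e. 18 months).
#' @param scanner_by_wave named character vector mapping wave to scanner label;
#'   by default wave 3 is acquired on a different scanner.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_by_scan_count = c(`1` = 40, `2` = 31, `3` = 27),
                          age_range = c(4, 22), interval = 1.5,
                          scanner_by_wave = c(`1` = "scanner_A",
                                              `2` = "scanner_A",
                                              `3` = "scanner_B")) {
  assert_that(length(n_by_scan_count) >= 1 && all(n_by_scan_count >= 0) &&
                sum(n_by_scan_count) > 0,
              "cohort composition must contain at least one participant")
  assert_that(length(age_range) == 2 && diff(age_range) > 0,
              "`age_range` must be an increasing pair of ages")
  structure(list(n_by_scan_count = n_by_scan_count, age_range = age_range,
                 interval = interval, scanner_by_wave = scanner_by_wave),
            class = "cohort_config")
}

#' Generate an accelerated longitudinal cohort table
#'
#' Starting ages are drawn uniformly over the age range; each later wave adds
#' the inter-scan interval, truncated at the top of the range. Wave 3 is
#' assigned a different scanner label; block order is counterbalanced across
#' participants.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @param n_prev_analyzed number of participants whose wave-1 scan is flagged
#'   `prev_analyzed` (a subsample reported on in earlier work, exposed as an
#'   include/exclude fork; default 42, capped at the cohort size).
#' @return Tibble with one row per scan: `participant_id`, `wave`,
#'   `age_at_scan`, `scanner`, `block_order`, `prev_analyzed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            n_prev_analyzed = 42) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  counts <- config$n_by_scan_count
  n_participants <- sum(counts)
  scans_per <- rep(as.integer(names(counts)), counts)
  with_seed(seed, {
    scans_per <- sample(scans_per) # shuffle so id order carries no structure
    start_age <- runif(n_participants, config$age_range[1], config$age_range[2])
    rows <- lapply(seq_len(n_participants), function(i) {
      waves <- seq_len(scans_per[i])
      age <- pmin(start_age[i] + (waves - 1) * config$interval,
                  config$age_range[2])
      tibble::tibble(
        participant_id = sprintf("sub-%03d", i),
        wave = waves,
        age_at_scan = age,
        scanner = unname(config$scanner_by_wave[as.character(waves)]),
        block_order = sprintf("order_%d", 1 + (i - 1) %% 3)
      )
    })
    out <- dplyr::bind_rows(rows)
    prev_ids <- sample(unique(out$participant_id),
                       min(n_prev_analyzed, n_participants))
    out$prev_analyzed <- out$participant_id %in% prev_ids & out$wave == 1
    out
  })
}

#' Generative parameters for synthetic scans
#'
#' Defaults are read from the packaged configuration
#' (`extdata/default_generative_params.yaml`); any field can be overridden by
#' name. See the methods vignette for the meaning and units of each parameter.
#'
#' @param ... named overrides of the packaged defaults.
#' @return A `generative_params` list.
#' @examples
#' p <- generative_params(noise_sd = 0.5)
#' p$age_slope[["fear"]]
#' @export
generative_params <- function(...) {
  path <- system.file("extdata", "default_generative_params.yaml",
                      package = "specfmri")
  defaults <- yaml::read_yaml(path)
  defaults$baseline_amplitude <- unlist(defaults$baseline_amplitude)
  defaults$age_slope <- unlist(defaults$age_slope)
  defaults$coupling_rho <- unlist(defaults$coupling_rho)
  defaults$drift_coefs <- as.numeric(defaults$drift_coefs)
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    assert_that(length(bad) == 0,
                paste("unknown generative parameter(s):", paste(bad, collapse = ", ")))
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  assert_that(all(abs(p$coupling_rho) <= 1), "|coupling_rho| must be <= 1")
  assert_that(p$ar1_coef >= 0 && p$ar1_coef < 1, "ar1_coef must be in [0, 1)")
  assert_that(p$noise_sd > 0, "noise_sd must be positive")
  structure(p, class = "generative_params")
}

# age-dependent habituation slope (units per within-condition trial)
habituation_slope_at <- function(params, age) {
  params$habituation_slope + params$habituation_age_slope * (age - 12)
}

#' Simulate parent-report anxiety scores for a cohort
#'
#' Raw separation-anxiety scores decrease with age at `anxiety_age_slope`
#' points/year; standardized (t) scores are age-invariant by construction.
#' Item-level SCARED responses (8 items summing to the raw score) are
#' generated so a configurable fraction can be set missing for imputation
#' exercises. Participants aged 18+ at their first scan are treated as adults
#' without parent reports (scores missing), mirroring a parent-report
#' instrument.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param params [generative_params()].
#' @param seed integer seed.
#' @param missing_frac fraction of item cells set missing (defaults to the
#'   packaged `anxiety_item_missing_frac`).
#' @return List with `scores` (tibble: `participant_id`, `wave`, `age_at_scan`,
#'   `rcads_raw`, `scared_raw`, `scared_t`, `adult`) and `scared_items`
#'   (tibble of 8 item columns with possible `NA`s).
#' @export
generate_anxiety_scores <- function(cohort, params = generative_params(),
                                    seed = 1, missing_frac = NULL) {
  missing_frac <- missing_frac %||% params$anxiety_item_missing_frac
  n_items <- 8L
  with_seed(seed, {
    first_age <- stats::ave(cohort$age_at_scan, cohort$participant_id,
                            FUN = min)
    adult <- first_age >= 18
    pid <- match(cohort$participant_id, unique(cohort$participant_id))
    trait <- rnorm(length(unique(pid)), 0, params$anxiety_sd)
    mu <- 8 + params$anxiety_age_slope * (cohort$age_at_scan - 12) + trait[pid]
    rcads_raw <- pmax(0, mu + rnorm(nrow(cohort), 0, params$anxiety_sd / 2))
    scared_raw_target <- pmax(0, mu + rnorm(nrow(cohort), 0, params$anxiety_sd / 2))
    scared_t <- 50 + 10 * scale(trait)[pid, 1] + rnorm(nrow(cohort), 0, 3)
    # spread the raw score over items (0..2-ish ordinal scale)
    items <- t(vapply(scared_raw_target, function(s) {
      w <- runif(n_items)
      pmax(0, round(s * w / sum(w), 1))
    }, numeric(n_items)))
    colnames(items) <- sprintf("item_%d", seq_len(n_items))
    if (missing_frac > 0) {
      mask <- matrix(runif(length(items)) < missing_frac, nrow = nrow(items))
      # never blank out a full row
      full <- rowSums(!mask) == 0
      mask[full, 1] <- FALSE
      items[mask] <- NA
    }
    scores <- tibble::tibble(
      participant_id = cohort$participant_id,
      wave = cohort$wave,
      age_at_scan = cohort$age_at_scan,
      rcads_raw = ifelse(adult, NA_real_, rcads_raw),
      scared_raw = ifelse(adult, NA_real_, rowSums(items, na.rm = TRUE)),
      scared_t = ifelse(adult, NA_real_, scared_t),
      adult = adult
    )
    items[adult, ] <- NA
    list(scores = scores,
         scared_items = tibble::as_tibble(cbind(scores[, c("participant_id", "wave")],
                                                as.data.frame(items))))
  })
}
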