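#' ROI panel produced by the synthetic scan generator
#'
#' Amygdala seed variants (native bilateral/left/right, high/low-signal, and
#' atlas-space re-extractions), three mPFC sphere targets plus a large vmPFC
#' mask, a global-signal column and two tissue-signal columns.
#' @export
roi_panel <- function() {
  c("amyg_bilateral", "amyg_left", "amyg_right", "amyg_high", "amyg_low",
    "amyg_ho_bilateral", "amyg_ho_left", "amyg_ho_right",
    "mpfc1", "mpfc2", "mpfc3", "vmpfc", "global_signal", "wm", "csf")
}

# stable participant-level amplitude shift, derived deterministically from
# the participant id so all of a participant's scans share it
participant_effect <- function(participant_id, what = "amp") {
  seed <- digest::digest2int(paste(participant_id, what)) %% 2147483629L
  withr::with_seed(abs(seed) + 1L, rnorm(1))
}

# per-trial neural amplitudes for seed and target, with condition-dependent
# coupling rho between the two via a shared standard-normal component
draw_trial_amplitudes <- function(design, age, params, participant_id = NULL) {
  e <- design$events
  n <- nrow(e)
  hab <- habituation_slope_at(params, age)
  shift <- if (is.null(participant_id) || params$participant_amp_sd == 0) 0 else
    params$participant_amp_sd * participant_effect(participant_id)
  amp_mean <- function(role) {
    base <- params$baseline_amplitude[e$trial_type]
    slope <- params$age_slope[e$trial_type]
    scale_role <- if (role == "target") 0.8 else 1
    scale_role * (base + slope * (age - 12) + shift) + hab * (e$trial_index - 1)
  }
  rho <- pmin(1, pmax(-1, params$coupling_rho[e$trial_type] +
                        params$coupling_age_slope * (age - 12)))
  z <- rnorm(n)
  s <- params$trial_amp_sd
  seed_amp <- amp_mean("seed") +
    s * (sqrt(abs(rho)) * z + sqrt(1 - abs(rho)) * rnorm(n))
  target_amp <- amp_mean("target") +
    s * (sign(rho) * sqrt(abs(rho)) * z + sqrt(1 - abs(rho)) * rnorm(n))
  tibble::tibble(trial = seq_len(n), condition = e$trial_type,
                 trial_index = e$trial_index,
                 amp_seed = seed_amp, amp_target = target_amp)
}

ar1_noise <- function(n, rho, sd) {
  if (sd <= 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(rnorm(n, 0, innov_sd), rho, method = "recursive"))
}

# 6-column realignment-parameter random walk whose summed absolute increments
# average to `target_mean_fd` mm, with occasional large spikes. Rotations are
# stored in radians; FD conversion uses a 50 mm head radius.
simulate_realignment <- function(n_volumes, target_mean_fd, spike_rate) {
  sigma <- target_mean_fd / (6 * sqrt(2 / pi))
  inc <- matrix(rnorm((n_volumes - 1) * 6, 0, sigma), ncol = 6)
  spikes <- runif(n_volumes - 1) < spike_rate
  inc[spikes, ] <- inc[spikes, ] * 8
  rp <- apply(rbind(0, inc), 2, cumsum)
  rp[, 4:6] <- rp[, 4:6] / 50 # radians; mm-equivalent on a 50 mm radius
  colnames(rp) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  rp
}

#' Framewise displacement from realignment parameters
#'
#' Sum of absolute backward differences of the six realignment parameters,
#' with rotations (radians) converted to mm of arc on a `radius` mm sphere.
#' The first volume is assigned 0.
#'
#' @param rp n_volumes x 6 matrix with columns `trans_x..rot_z`.
#' @param radius head radius in mm used to convert rotations.
#' @return numeric vector of length `nrow(rp)`.
#' @export
fd_from_realignment <- function(rp, radius = 50) {
  stopifnot(ncol(rp) == 6)
  d <- abs(diff(rp))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rowSums(d[, 4:6, drop = FALSE]) * radius
  c(0, fd)
}

#' Simulate one scan's ROI timeseries from known generative parameters
#'
#' Per-trial neural amplitudes follow
#' `baseline_c + age_slope_c * (age - 12) + habituation(trial, age) + noise`,
#' with the seed and target trial-amplitude noise correlated at
#' `coupling_rho_c` within condition. Amplitude-weighted event impulses are
#' convolved with the double-gamma HRF; AR(1) noise, polynomial drift, a
#' shared low-frequency global component and FD-coupled motion artifacts are
#' added on top. The drawn amplitudes are returned so downstream estimators
#' can be checked against the generative truth.
#'
#' @param design a [generate_task_design()] object.
#' @param meta one cohort row (needs `participant_id`, `wave`, `age_at_scan`,
#'   `scanner`, `block_order`).
#' @param params [generative_params()].
#' @param seed integer seed.
#' @return A `scan_record`: list with `meta`, `roi_timeseries` (tibble,
#'   n_volumes x ROI panel), `realignment_params`, `fd_series`, `mean_fd`,
#'   `amplitudes` (generative per-trial amplitudes) and the `design`.
#' @export
simulate_scan <- function(design, meta, params = generative_params(), seed = 1) {
  nv <- design$n_volumes
  tr <- design$tr
  age <- meta$age_at_scan
  hrf <- make_hrf("double_gamma", dt = 0.1)
  with_seed(seed, {
    amps <- draw_trial_amplitudes(design, age, params, meta$participant_id)
    e <- design$events
    seed_sig <- convolve_events(e$onset, e$duration, hrf, tr, nv,
                                amplitudes = amps$amp_seed)
    target_sig <- convolve_events(e$onset, e$duration, hrf, tr, nv,
                                  amplitudes = amps$amp_target)

    s <- seq(-1, 1, length.out = nv)
    drift <- params$drift_coefs[1] + params$drift_coefs[2] * s +
      params$drift_coefs[3] * s^2
    tsec <- (seq_len(nv) - 1) * tr
    g <- sin(2 * pi * tsec / 90 + runif(1, 0, 2 * pi)) +
      0.6 * sin(2 * pi * tsec / 150 + runif(1, 0, 2 * pi))
    g <- as.numeric(scale(g))

    fd_trait <- params$fd_between_sd *
      participant_effect(meta$participant_id, "fd")
    target_fd <- max(0.05, params$fd_base + fd_trait +
                       rnorm(1, 0, params$fd_within_sd) +
                       params$motion_age_slope * (age - 12))
    rp <- simulate_realignment(nv, target_fd, params$fd_spike_rate)
    fd <- fd_from_realignment(rp)
    motion_art <- params$motion_artifact_gain * fd

    common <- drift + params$global_amp * g + motion_art
    noise <- function(scale = 1) ar1_noise(nv, params$ar1_coef,
                                           params$noise_sd * scale)
    split <- function() rnorm(nv, 0, params$roi_split_noise_sd)

    amyg_left <- seed_sig + common + noise() + split()
    amyg_right <- seed_sig + common + noise() + split()
    amyg_bilateral <- (amyg_left + amyg_right) / 2
    amyg_high <- seed_sig + common + noise(0.6)
    amyg_low <- 0.6 * seed_sig + common + noise(1.4)
    amyg_ho_bilateral <- amyg_bilateral + split()
    amyg_ho_left <- amyg_left + split()
    amyg_ho_right <- amyg_right + split()

    sh <- params$target_share
    shared_t <- noise()
    mpfc <- lapply(1:3, function(k)
      target_sig + common + sqrt(sh) * shared_t + sqrt(1 - sh) * noise())
    vmpfc <- 0.8 * target_sig + common + sqrt(sh) * shared_t +
      sqrt(1 - sh) * noise()

    global_col <- g + rnorm(nv, 0, 0.1)
    wm <- 0.3 * params$global_amp * g + motion_art + noise(0.8)
    csf <- 0.3 * params$global_amp * g + motion_art + noise(0.8)

    ts <- tibble::tibble(
      amyg_bilateral = amyg_bilateral, amyg_left = amyg_left,
      amyg_right = amyg_right, amyg_high = amyg_high, amyg_low = amyg_low,
      amyg_ho_bilateral = amyg_ho_bilateral, amyg_ho_left = amyg_ho_left,
      amyg_ho_right = amyg_ho_right,
      mpfc1 = mpfc[[1]], mpfc2 = mpfc[[2]], mpfc3 = mpfc[[3]], vmpfc = vmpfc,
      global_signal = global_col, wm = wm, csf = csf
    )
    structure(list(meta = meta, design = design, roi_timeseries = ts,
                   realignment_params = rp, fd_series = fd,
                   mean_fd = mean(fd), amplitudes = amps),
              class = "scan_record")
  })
}

#' @export
print.scan_record <- function(x, ...) {
  cat(sprintf("<scan_record> %s wave %d, age %.1f, %d volumes, mean FD %.3f mm\n",
              x$meta$participant_id, x$meta$wave, x$meta$age_at_scan,
              nrow(x$roi_timeseries), x$mean_fd))
  invisible(x)
}

#' Simulate all scans of a cohort
#'
#' @param cohort tibble from [generate_cohort()].
#' @param design shared [generate_task_design()]; the study used fixed stimulus
#'   orders across participants.
#' @param params [generative_params()].
#' @param seed integer seed; each scan gets a derived child seed.
#' @return Named list of `scan_record`s keyed by `scan_id`
#'   (`participant_id` x wave).
#' @export
simulate_cohort_scans <- function(cohort, design = generate_task_design(),
                                  params = generative_params(), seed = 1) {
  scans <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- simulate_scan(design, cohort[i, ], params,
                         seed = child_seed(seed, i))
    rec$scan_id <- sprintf("%s_w%d", cohort$participant_id[i], cohort$wave[i])
    rec
  })
  names(scans) <- vapply(scans, `[[`, "", "scan_id")
  scans
}

#' Simulate scan-level measures directly from a multilevel generative model
#'
#' Bypasses BOLD synthesis: draws a scan-level outcome
#' `intercept + slope * (age - 12) + fd_beta * mean_fd + u_participant + e`
#' on a cohort table, for calibration and recovery studies of the group-model
#' layer. Within/between age structure can differ via `slope_within`.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param slope between-participant age effect per year (also the within effect
#'   unless `slope_within` is given).
#' @param slope_within optional distinct within-participant slope.
#' @param intercept outcome at age 12 with zero motion.
#' @param sd_between,sd_within participant and scan noise SDs.
#' @param fd_beta coefficient tying the outcome to mean FD.
#' @param params [generative_params()] (for the motion-age trend).
#' @param seed integer seed.
#' @return Scan-level tibble with `outcome`, `mean_fd` and cohort columns.
#' @export
simulate_measure_table <- function(cohort, slope = -0.05, slope_within = NULL,
                                   intercept = 1, sd_between = 0.5,
                                   sd_within = 0.5, fd_beta = 0,
                                   params = generative_params(), seed = 1) {
  with_seed(seed, {
    pid <- match(cohort$participant_id, unique(cohort$participant_id))
    u <- rnorm(length(unique(pid)), 0, sd_between)
    mean_age <- stats::ave(cohort$age_at_scan, cohort$participant_id)
    b_b <- slope
    b_w <- slope_within %||% slope
    mean_fd <- pmax(0.03, params$fd_base +
                      params$motion_age_slope * (cohort$age_at_scan - 12) +
                      rnorm(nrow(cohort), 0, 0.05))
    outcome <- intercept + b_b * (mean_age - 12) +
      b_w * (cohort$age_at_scan - mean_age) + fd_beta * mean_fd +
      u[pid] + rnorm(nrow(cohort), 0, sd_within)
    dplyr::mutate(cohort, mean_fd = mean_fd, outcome = outcome,
                  scan_id = sprintf("%s_w%d", .data$participant_id, .data$wave))
  })
}

#' Simulate single-trial beta tables directly from the generative amplitudes
#'
#' Draws per-trial seed/target amplitudes for every scan of a cohort (exactly
#' the quantities an LSS estimator targets) plus optional measurement noise,
#' without synthesizing BOLD. Used for trial-dynamics and beta-series
#' correlation recovery studies at scale.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param design task design shared across scans.
#' @param params [generative_params()].
#' @param meas_noise_sd SD of additive estimation noise on each beta.
#' @param global_offset_sd SD of a per-trial offset added to both ROIs
#'   (emulates a shared global artifact; 0 disables).
#' @param seed integer seed.
#' @return Trial-level tibble: cohort columns, `scan_id`, `mean_fd`,
#'   `condition`, `trial_index`, `beta_seed`, `beta_target`.
#' @export
simulate_trial_table <- function(cohort, design = generate_task_design(),
                                 params = generative_params(),
                                 meas_noise_sd = 0.2, global_offset_sd = 0,
                                 seed = 1) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    with_seed(child_seed(seed, i), {
      amps <- draw_trial_amplitudes(design, cohort$age_at_scan[i], params,
                                    cohort$participant_id[i])
      n <- nrow(amps)
      off <- if (global_offset_sd > 0) rnorm(n, 0, global_offset_sd) else numeric(n)
      tibble::tibble(
        participant_id = cohort$participant_id[i],
        wave = cohort$wave[i],
        age_at_scan = cohort$age_at_scan[i],
        scan_id = sprintf("%s_w%d", cohort$participant_id[i], cohort$wave[i]),
        mean_fd = max(0.03, params$fd_base +
                        params$fd_between_sd *
                          participant_effect(cohort$participant_id[i], "fd") +
                        rnorm(1, 0, params$fd_within_sd) +
                        params$motion_age_slope * (cohort$age_at_scan[i] - 12)),
        condition = amps$condition,
        trial_index = amps$trial_index,
        beta_seed = amps$amp_seed + rnorm(n, 0, meas_noise_sd) + off,
        beta_target = amps$amp_target + rnorm(n, 0, meas_noise_sd) + off
      )
    })
  })
  dplyr::bind_rows(rows)
}
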