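# shared fixtures, built once per test run

quiet_params <- function(...) {
  # clean generative regime: no drift/global/motion artifacts, white noise
  generative_params(drift_coefs = c(0, 0, 0), global_amp = 0,
                    motion_artifact_gain = 0, ar1_coef = 0,
                    fd_spike_rate = 0, roi_split_noise_sd = 0, ...)
}

noiseless_params <- function(...) {
  quiet_params(noise_sd = 1e-10, participant_amp_sd = 0, ...)
}

tiny_cohort <- function(n1 = 4, n2 = 3, n3 = 3, seed = 11) {
  generate_cohort(cohort_config(
    n_by_scan_count = c(`1` = n1, `2` = n2, `3` = n3)), seed = seed)
}

default_design <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- generate_task_design(seed = 1)
    d
  }
})

# a design with widely spaced trials (no HRF overlap), few trials
spaced_design <- function(n_per_cond = 3, gap = 34, tr = 2) {
  n <- 2 * n_per_cond
  onsets <- 4 + (seq_len(n) - 1) * gap
  nv <- ceiling((max(onsets) + 36) / tr)
  events <- tibble::tibble(
    onset = onsets, duration = 0.35,
    trial_type = rep(c("fear", "neutral"), n_per_cond))
  events$trial_index <- stats::ave(seq_len(n), events$trial_type, FUN = seq_along)
  structure(list(events = events, tr = tr, n_volumes = nv),
            class = "task_design")
}

zero_motion <- function(nv) {
  rp <- matrix(0, nv, 6)
  colnames(rp) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  rp
}
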