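#' Haemodynamic response function kernels
#'
#' Builds a sampled HRF kernel on a fine time grid. The double-gamma kernel is
#' the canonical difference of two gamma densities (response peak near 6 s,
#' undershoot peaking near 16 s, undershoot amplitude 1/6 of the peak lobe);
#' the single-gamma kernel is the positive lobe only. Both are zero at t = 0
#' and have finite support.
#'
#' @param kind `"double_gamma"` or `"single_gamma"`.
#' @param dt sampling step of the kernel, seconds.
#' @param duration kernel support, seconds.
#' @param peak,undershoot gamma-density shape parameters (rate 1) controlling
#'   the positive lobe and the undershoot.
#' @param undershoot_ratio relative amplitude of the undershoot lobe.
#' @return An object of class `hrf_kernel`: a list with `kind`, `dt`, `time`
#'   and `values`.
#' @examples
#' h <- make_hrf("double_gamma", dt = 0.1)
#' h$values[1] # 0 at t = 0
#' @export
make_hrf <- function(kind = c("double_gamma", "single_gamma"), dt = 0.1,
                     duration = 32, peak = 6, undershoot = 16,
                     undershoot_ratio = 1 / 6) {
  kind <- match.arg(kind)
  assert_that(is.numeric(dt) && dt > 0, "`dt` must be a positive number")
  t <- seq(0, duration, by = dt)
  pos <- dgamma(t, shape = peak, rate = 1)
  v <- if (kind == "double_gamma") {
    pos - undershoot_ratio * dgamma(t, shape = undershoot, rate = 1)
  } else {
    pos
  }
  v <- v / max(v) # peak-normalized so responses are in amplitude units
  structure(list(kind = kind, dt = dt, time = t, values = v),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %s, dt = %gs, support [0, %g]s, peak at %.2fs\n",
              x$kind, x$dt, max(x$time), x$time[which.max(x$values)]))
  invisible(x)
}

# Convolve an event train (onsets/durations/amplitudes in seconds) with an HRF
# on the kernel's fine grid, then bin-average down to the volume grid.
# Returns a length-n_volumes numeric regressor. Bin-averaging (rather than
# point sampling) keeps sub-TR events (350 ms) visible on a 2 s grid.
convolve_events <- function(onsets, durations, hrf, tr, n_volumes,
                            amplitudes = NULL) {
  stopifnot(length(onsets) == length(durations))
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  dt <- hrf$dt
  run_len <- tr * n_volumes
  n_fine <- ceiling(run_len / dt)
  stim <- numeric(n_fine + length(hrf$values))
  tgrid <- (seq_len(n_fine) - 1) * dt
  for (i in seq_along(onsets)) {
    idx <- which(tgrid >= onsets[i] & tgrid < onsets[i] + durations[i])
    if (length(idx) == 0) { # event shorter than dt: nearest bin
      idx <- max(1L, min(n_fine, 1L + round(onsets[i] / dt)))
    }
    stim[idx] <- stim[idx] + amplitudes[i]
  }
  conv <- stats::convolve(stim, rev(hrf$values), type = "open")[seq_len(n_fine)] * dt
  downsample_to_volumes(conv, dt, tr, n_volumes)
}

# Average a fine-grid series within each TR bin (volume i covers
# [(i-1)*tr, i*tr)). Used for both convolved regressors and task indicators.
downsample_to_volumes <- function(x_fine, dt, tr, n_volumes) {
  per_bin <- round(tr / dt)
  stopifnot(abs(per_bin * dt - tr) < 1e-8)
  need <- per_bin * n_volumes
  x_fine <- c(x_fine, numeric(max(0, need - length(x_fine))))[seq_len(need)]
  colMeans(matrix(x_fine, nrow = per_bin))
}
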