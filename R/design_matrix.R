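#' Expand realignment parameters into a nuisance regressor set
#'
#' * `"6"` — the six realignment parameters.
#' * `"24"` — the six parameters, their backward-difference temporal
#'   derivatives, and the squares of those twelve.
#' * `"18_wm_csf"` — parameters + derivatives + squared parameters (18)
#'   plus two tissue-signal columns supplied via `wm` and `csf`.
#'
#' @param rp n_volumes x 6 matrix/data.frame of realignment parameters.
#' @param set `"6"`, `"24"` or `"18_wm_csf"`.
#' @param wm,csf tissue-signal vectors, required for `"18_wm_csf"`.
#' @return Numeric matrix with named columns.
#' @export
expand_motion_regressors <- function(rp, set = c("24", "6", "18_wm_csf"),
                                     wm = NULL, csf = NULL) {
  set <- match.arg(set)
  rp <- as.matrix(rp)
  assert_that(ncol(rp) == 6, "realignment parameters must have exactly 6 columns")
  if (is.null(colnames(rp)))
    colnames(rp) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  deriv <- rbind(0, diff(rp))
  colnames(deriv) <- paste0(colnames(rp), "_deriv")
  if (set == "6") return(rp)
  if (set == "24") {
    first12 <- cbind(rp, deriv)
    sq <- first12^2
    colnames(sq) <- paste0(colnames(first12), "_sq")
    return(cbind(first12, sq))
  }
  assert_that(!is.null(wm) && !is.null(csf),
              "set \"18_wm_csf\" needs `wm` and `csf` tissue signals")
  sq6 <- rp^2
  colnames(sq6) <- paste0(colnames(rp), "_sq")
  cbind(rp, deriv, sq6, wm = wm, csf = csf)
}

#' Censoring weights from framewise displacement
#'
#' Volumes with FD strictly above `threshold_mm` get weight 0, others 1. A
#' scan is flagged for exclusion when more than `max_bad_volumes` volumes
#' exceed the threshold.
#'
#' @param fd_series per-volume FD in mm (first volume 0).
#' @param threshold_mm censoring threshold (default 0.9 mm).
#' @param max_bad_volumes exclusion rule: flag scans with more than this many
#'   suprathreshold volumes (default 40).
#' @return List with `weights` (0/1 vector) and `scan_excluded` (logical).
#' @export
censor_weights <- function(fd_series, threshold_mm = 0.9, max_bad_volumes = 40) {
  assert_that(all(fd_series >= 0), "FD values must be non-negative")
  bad <- fd_series > threshold_mm
  list(weights = as.numeric(!bad), scan_excluded = sum(bad) > max_bad_volumes)
}

#' Low-frequency drift basis
#'
#' `"highpass"` returns a discrete-cosine basis whose slowest
#' `floor(2 * run_length * cutoff_hz)` components implement a high-pass filter
#' at `cutoff_hz` when entered as regressors (a deterministic substitute for
#' running-line filters). `"quadratic"` returns an orthogonalized
#' constant/linear/quadratic basis. Both include the constant column.
#'
#' @param kind `"highpass"` or `"quadratic"`.
#' @param n_volumes,tr run geometry.
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @return Numeric matrix of drift columns (including `intercept`).
#' @export
detrend_basis <- function(kind = c("highpass", "quadratic"), n_volumes, tr,
                          cutoff_hz = 0.01) {
  kind <- match.arg(kind)
  assert_that(n_volumes >= 3, "need at least 3 volumes")
  t_idx <- seq_len(n_volumes) - 1
  if (kind == "highpass") {
    k_max <- floor(2 * n_volumes * tr * cutoff_hz)
    basis <- vapply(seq_len(k_max), function(k)
      cos(pi * (2 * t_idx + 1) * k / (2 * n_volumes)), numeric(n_volumes))
    out <- cbind(intercept = 1, basis)
    colnames(out) <- c("intercept", paste0("dct_", seq_len(k_max)))
  } else {
    raw <- cbind(1, t_idx, t_idx^2)
    q <- qr.Q(qr(raw))
    out <- cbind(intercept = 1, q[, 2] / max(abs(q[, 2])),
                 q[, 3] / max(abs(q[, 3])))
    colnames(out) <- c("intercept", "poly_1", "poly_2")
  }
  out
}

#' Assemble a scan-level design matrix
#'
#' Task regressors per condition (events convolved with the chosen HRF),
#' optional backward-difference temporal derivatives, a drift basis, and a
#' nuisance set, with per-volume censoring weights from FD.
#'
#' @param design a [generate_task_design()] object.
#' @param rp realignment parameters (n_volumes x 6).
#' @param fd_series per-volume FD.
#' @param hrf an [make_hrf()] kernel.
#' @param nuisance_set passed to [expand_motion_regressors()].
#' @param detrend passed to [detrend_basis()].
#' @param derivatives include temporal derivatives of the task regressors.
#' @param wm,csf tissue signals for the `"18_wm_csf"` set.
#' @param fd_threshold_mm censoring threshold.
#' @return A `design_matrix`: list with `X` (named columns), `weights`,
#'   `scan_excluded`, `task_cols`.
#' @export
build_design_matrix <- function(design, rp, fd_series,
                                hrf = make_hrf("double_gamma"),
                                nuisance_set = "24",
                                detrend = "highpass",
                                derivatives = TRUE,
                                wm = NULL, csf = NULL,
                                fd_threshold_mm = 0.9) {
  e <- design$events
  conds <- sort(unique(e$trial_type))
  task <- vapply(conds, function(cc) {
    sel <- e$trial_type == cc
    convolve_events(e$onset[sel], e$duration[sel], hrf, design$tr,
                    design$n_volumes)
  }, numeric(design$n_volumes))
  colnames(task) <- conds
  assert_that(all(colSums(abs(task)) > 0), "a task regressor is all zero")
  X <- task
  if (derivatives) {
    d <- rbind(0, diff(task))
    colnames(d) <- paste0(conds, "_deriv")
    X <- cbind(X, d)
  }
  X <- cbind(X, detrend_basis(detrend, design$n_volumes, design$tr))
  X <- cbind(X, expand_motion_regressors(rp, nuisance_set, wm = wm, csf = csf))
  assert_that(!anyDuplicated(colnames(X)), "design column names must be unique")
  cw <- censor_weights(fd_series, threshold_mm = fd_threshold_mm)
  structure(list(X = X, weights = cw$weights,
                 scan_excluded = cw$scan_excluded, task_cols = conds),
            class = "design_matrix")
}
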