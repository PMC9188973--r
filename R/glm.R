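# Weighted least squares with 0/1 censoring weights implemented as row
# deletion, optional AR(1) prewhitening (single-lag Cochrane-Orcutt on the
# pooled OLS residuals, then refit). Y may have several columns (one QR is
# shared across ROIs). Adjacency for both the lag-1 autocorrelation estimate
# and the quasi-differencing is adjacency in acquisition time, so censored
# volumes break the chain exactly as row deletion would.
wls_core <- function(Y, X, weights = NULL, prewhiten = c("ar1", "none")) {
  prewhiten <- match.arg(prewhiten)
  Y <- as.matrix(Y)
  n <- nrow(X)
  keep <- if (is.null(weights)) rep(TRUE, n) else weights > 0
  assert_that(sum(keep) >= ncol(X) + 2,
              "fewer uncensored volumes than design columns + 2")
  idx <- which(keep)
  Xk <- X[idx, , drop = FALSE]
  Yk <- Y[idx, , drop = FALSE]

  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    bad <- colnames(Xk)[qrX$pivot[seq(qrX$rank + 1, ncol(Xk))]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
                 paste(bad, collapse = ", ")))
  }

  rho <- 0
  if (prewhiten == "ar1") {
    res <- qr.resid(qrX, Yk)
    adj <- which(diff(idx) == 1) # pairs adjacent in acquisition time
    if (length(adj) > 2) {
      num <- sum(res[adj, , drop = FALSE] * res[adj + 1, , drop = FALSE])
      den <- sum(res^2)
      rho <- if (den > 0) max(-0.95, min(0.95, num / den)) else 0
    }
    if (abs(rho) > 1e-8) {
      prev_kept <- c(FALSE, diff(idx) == 1)
      Xw <- Xk; Yw <- Yk
      Xw[prev_kept, ] <- Xk[prev_kept, ] - rho * Xk[which(prev_kept) - 1, ]
      Yw[prev_kept, ] <- Yk[prev_kept, ] - rho * Yk[which(prev_kept) - 1, , drop = FALSE]
      sc <- sqrt(1 - rho^2)
      Xw[!prev_kept, ] <- sc * Xk[!prev_kept, ]
      Yw[!prev_kept, ] <- sc * Yk[!prev_kept, , drop = FALSE]
      Xk <- Xw; Yk <- Yw
      qrX <- qr(Xk)
    }
  }

  beta <- qr.coef(qrX, Yk)
  res <- qr.resid(qrX, Yk)
  dof <- sum(keep) - qrX$rank
  sigma2 <- colSums(res^2) / dof
  R <- qr.R(qrX)
  XtXinv <- chol2inv(R)
  # undo any column pivoting in the qr
  piv <- qrX$pivot
  XtXinv <- XtXinv[order(piv), order(piv), drop = FALSE]
  rownames(beta) <- colnames(X)
  list(beta = beta, sigma2 = sigma2, dof = dof, XtXinv = XtXinv, rho = rho,
       n_used = sum(keep))
}

contrast_rows <- function(fit, X_names, roi_names) {
  cvecs <- list(
    "fear>baseline"  = c(fear = 1),
    "neutral>baseline" = c(neutral = 1),
    "fear>neutral"   = c(fear = 1, neutral = -1)
  )
  out <- lapply(names(cvecs), function(cn) {
    cv <- numeric(length(X_names)); names(cv) <- X_names
    cv[names(cvecs[[cn]])] <- cvecs[[cn]]
    est <- drop(crossprod(cv, fit$beta))
    cvar <- drop(crossprod(cv, fit$XtXinv %*% cv))
    se <- sqrt(pmax(0, cvar * fit$sigma2))
    tibble::tibble(
      roi = roi_names, contrast = cn, beta = as.numeric(est),
      se = as.numeric(se),
      t_stat = ifelse(se > 0, as.numeric(est) / as.numeric(se), NA_real_),
      dof = fit$dof
    )
  })
  dplyr::bind_rows(out)
}

#' Fit a scan-level GLM and return condition contrasts
#'
#' Weighted least squares with FD-censoring weights (0/1, implemented as row
#' deletion) and optional AR(1) prewhitening via single-lag Cochrane-Orcutt.
#' Returns the three standard contrasts (fear > baseline, neutral > baseline,
#' fear > neutral) per ROI; the difference contrast equals the difference of
#' the two baseline contrasts by linearity.
#'
#' @param roi_ts numeric vector, matrix, or tibble of ROI timeseries
#'   (n_volumes rows).
#' @param dm a [build_design_matrix()] object.
#' @param prewhiten `"ar1"` or `"none"`.
#' @return Tibble with one row per (roi, contrast): `beta`, `se`, `t_stat`
#'   (`NA` when the residual is exactly zero), `dof`.
#' @export
fit_glm <- function(roi_ts, dm, prewhiten = c("ar1", "none")) {
  prewhiten <- match.arg(prewhiten)
  Y <- as.matrix(roi_ts)
  if (is.null(colnames(Y)))
    colnames(Y) <- if (ncol(Y) == 1) "roi" else paste0("roi", seq_len(ncol(Y)))
  assert_that(nrow(Y) == nrow(dm$X), "timeseries length must equal n_volumes")
  fit <- wls_core(Y, dm$X, dm$weights, prewhiten)
  contrast_rows(fit, colnames(dm$X), colnames(Y))
}
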