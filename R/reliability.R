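#' Longitudinal test-retest reliability via variance decomposition
#'
#' Fits the measure's multilevel model (measure ~ covariates + participant
#' random intercept) and decomposes variance:
#'
#' * `"variance_components"` (fast path): ICC =
#'   `sigma^2_between / (sigma^2_between + sigma^2_within)` from an REML fit,
#'   with a seeded bootstrap over participants for the interval.
#' * `"posterior_predictive"`: per posterior draw, the variance of the
#'   posterior predictive distribution conditioned on the sampled random
#'   effects is compared to the variance when random effects are redrawn from
#'   their population distribution; ICC = `1 - var(cond)/var(marginal)`,
#'   summarized by the posterior median and 95% quantiles. Negative values
#'   are possible and indicate the conditional predictive variance exceeds
#'   the marginal one.
#'
#' All scans are used, including participants with a single visit.
#'
#' @param scan_table scan-level tibble (`participant_id`, covariate columns,
#'   measure column).
#' @param measure measure column name.
#' @param covariates fixed covariates (default `"mean_fd"`; use `character(0)`
#'   for a covariate-free decomposition).
#' @param method `"variance_components"` or `"posterior_predictive"`.
#' @param nboot bootstrap resamples for the fast-path interval (0 skips it).
#' @param seed integer seed.
#' @param priors [prior_spec()] for the Bayesian path.
#' @return Tibble row: `measure`, `icc`, `lower`, `upper`, `method`, `band`,
#'   `n_participants`, `n_scans`.
#' @export
icc_variance_components <- function(scan_table, measure,
                                    covariates = "mean_fd",
                                    method = c("variance_components",
                                               "posterior_predictive"),
                                    nboot = 1000, seed = 1,
                                    priors = prior_spec()) {
  method <- match.arg(method)
  d <- scan_table[!is.na(scan_table[[measure]]), , drop = FALSE]
  n_multi <- sum(tapply(d$participant_id, d$participant_id, length) >= 2)
  assert_that(n_multi >= 2, "need at least 2 participants with 2+ scans")
  d$.y <- d[[measure]]
  assert_that(sd(d$.y) > 0, "measure is degenerate (zero total variance)")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste(".y ~", rhs, "+ (1 | participant_id)"))

  if (method == "variance_components") {
    point <- icc_from_fit(f, d)
    lo <- hi <- NA_real_
    if (nboot > 0) {
      ids <- unique(d$participant_id)
      boots <- with_seed(seed, {
        vapply(seq_len(nboot), function(b) {
          take <- sample(ids, length(ids), replace = TRUE)
          db <- dplyr::bind_rows(lapply(seq_along(take), function(j) {
            rows <- d[d$participant_id == take[j], , drop = FALSE]
            rows$participant_id <- sprintf("boot_%d", j)
            rows
          }))
          tryCatch(icc_from_fit(f, db), error = function(e) NA_real_)
        }, numeric(1))
      })
      qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE)
      lo <- qs[1]; hi <- qs[2]
    }
    icc <- point
  } else {
    X <- model.matrix(stats::as.formula(paste("~", rhs)), d)
    jf <- jags_lmm(d$.y, X, d$participant_id, priors = priors, seed = seed,
                   monitor_extra = c("sigma_u", "sigma"))
    dr <- jf$draws
    g <- as.integer(factor(d$participant_id))
    nG <- length(unique(g))
    b_idx <- grep("^b($|\\[)", colnames(dr))
    iccs <- with_seed(seed, {
      vapply(seq_len(nrow(dr)), function(s) {
        mu <- drop(X %*% dr[s, b_idx])
        sig <- dr[s, "sigma"]; sig_u <- dr[s, "sigma_u"]
        u_cond <- rnorm(nG, 0, sig_u)
        y_cond <- mu + u_cond[g] + rnorm(length(mu), 0, sig)
        u_marg <- rnorm(nG, 0, sig_u)
        y_marg <- mu + u_marg[sample.int(nG, length(mu), replace = TRUE)] +
          rnorm(length(mu), 0, sig)
        # conditional: residual spread around the sampled participant means;
        # marginal: participant effects redrawn per observation
        1 - var(y_cond - u_cond[g]) / var(y_marg)
      }, numeric(1))
    })
    icc <- median(iccs)
    lo <- quantile(iccs, 0.025); hi <- quantile(iccs, 0.975)
  }
  tibble::tibble(measure = measure, icc = unname(icc), lower = unname(lo),
                 upper = unname(hi), method = method,
                 band = icc_band(icc),
                 n_participants = length(unique(d$participant_id)),
                 n_scans = nrow(d))
}

icc_from_fit <- function(f, d) {
  fit <- suppressMessages(suppressWarnings(lme4::lmer(f, data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_b <- vc$vcov[vc$grp == "participant_id"]
  s_w <- vc$vcov[vc$grp == "Residual"]
  s_b / (s_b + s_w)
}

#' Reliability band of an ICC value
#'
#' Thresholds applied half-open on the lower edge: poor below 0.4, fair
#' `[0.4, 0.6)`, good `[0.6, 0.75)`, excellent at or above 0.75. Negative
#' estimates are poor.
#'
#' @param icc finite ICC point estimate.
#' @return `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @export
icc_band <- function(icc) {
  assert_that(all(is.finite(icc)), "ICC must be finite")
  cut(icc, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"), right = FALSE) |>
    as.character()
}
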