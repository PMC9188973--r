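#' Specification of a group-level age model
#'
#' @param age_form `"linear"`, `"quadratic"` (linear + quadratic term) or
#'   `"inverse"` (1/age on raw years).
#' @param covariates subset of `c("mean_fd", "block", "scanner")`; `mean_fd`
#'   is always included.
#' @param random_slopes allow participant-varying age slopes.
#' @param outlier_rule `"exclude_3sd"` (drop outcome values more than 3 SD
#'   from the mean) or `"exclude_3sd_plus_robust"` (also use a heavy-tailed /
#'   reweighted fit).
#' @param parametrization `"pooled_age"` or `"within_between"`.
#' @param estimation `"fast_freq"` (REML via lme4 with Satterthwaite Wald
#'   intervals) or `"bayes_mcmc"` (JAGS; 4 chains, 1000 warmup + 1000
#'   sampling).
#' @return An `age_model_spec` list.
#' @export
age_model_spec <- function(age_form = c("linear", "quadratic", "inverse"),
                           covariates = "mean_fd",
                           random_slopes = TRUE,
                           outlier_rule = c("exclude_3sd",
                                            "exclude_3sd_plus_robust"),
                           parametrization = c("pooled_age", "within_between"),
                           estimation = c("fast_freq", "bayes_mcmc")) {
  age_form <- match.arg(age_form)
  outlier_rule <- match.arg(outlier_rule)
  parametrization <- match.arg(parametrization)
  estimation <- match.arg(estimation)
  covariates <- union("mean_fd", covariates)
  assert_that(all(covariates %in% c("mean_fd", "block", "scanner")),
              "covariates must be among mean_fd, block, scanner")
  structure(list(age_form = age_form, covariates = covariates,
                 random_slopes = random_slopes, outlier_rule = outlier_rule,
                 parametrization = parametrization, estimation = estimation,
                 robust = outlier_rule == "exclude_3sd_plus_robust"),
            class = "age_model_spec")
}

#' Outlier exclusion by z-score
#'
#' Drops observations more than 3 SD from the mean of all values (mean and SD
#' over the full set of scan-level estimates for the measure). A zero SD
#' excludes nothing.
#'
#' @param values numeric vector.
#' @param rule `"exclude_3sd"` or `"exclude_3sd_plus_robust"` (same exclusion;
#'   the robust part affects the subsequent fit).
#' @param n_sd threshold in SD units.
#' @return List: `keep` (logical vector), `excluded` (indices), `n_excluded`.
#' @export
exclude_outliers <- function(values, rule = "exclude_3sd", n_sd = 3) {
  assert_that(length(values) >= 3, "need at least 3 values")
  m <- mean(values, na.rm = TRUE)
  s <- sd(values, na.rm = TRUE)
  keep <- if (is.na(s) || s == 0) !is.na(values) else
    !is.na(values) & abs(values - m) <= n_sd * s
  list(keep = keep, excluded = which(!keep & !is.na(values)),
       n_excluded = sum(!keep & !is.na(values)))
}

# ---- internal fitting machinery -------------------------------------------

# random-slope models can have more random effects than scans (98 intercepts
# + 98 slopes vs 183 scans); they remain estimable through shrinkage, so the
# conservative nobs-vs-nRE guard is relaxed and singular fits are flagged via
# the convergence flag instead
lmer_ctrl <- function() {
  lme4::lmerControl(check.nobs.vs.nRE = "ignore", calc.derivs = FALSE)
}

# Huber-weighted iterative refitting of an lmer model (frequentist robust path)
fit_lmer_robust <- function(formula, data, k = 1.345, iters = 4) {
  data$.w <- rep(1, nrow(data))
  fit <- NULL
  for (it in seq_len(iters + 1)) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data, weights = .w, REML = TRUE,
                     control = lmer_ctrl())))
    r <- stats::residuals(fit)
    s <- stats::mad(r)
    if (s <= 0) break
    data$.w <- pmin(1, k / abs(r / s))
  }
  fit
}

# fit by lme4/lmerTest and return tidy rows with Satterthwaite-Wald intervals
fit_freq <- function(formula, data, robust = FALSE) {
  fit <- if (robust) fit_lmer_robust(formula, data) else
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = data, REML = TRUE,
                     control = lmer_ctrl())))
  sm <- summary(fit)$coefficients
  df <- if ("df" %in% colnames(sm)) sm[, "df"] else
    rep(nrow(data) - nrow(sm), nrow(sm))
  df[!is.finite(df) | df <= 0] <- nrow(data) - nrow(sm)
  crit <- qt(0.975, df)
  out <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, "Estimate"]),
    lower = unname(sm[, "Estimate"] - crit * sm[, "Std. Error"]),
    upper = unname(sm[, "Estimate"] + crit * sm[, "Std. Error"])
  )
  attr(out, "converged") <- !lme4::isSingular(fit) &&
    length(fit@optinfo$conv$lme4$messages) == 0
  attr(out, "fit") <- fit
  out
}

fit_bayes <- function(y, X, group1, group2 = NULL, slope_x = NULL,
                      robust = FALSE, priors = prior_spec(), seed = 1) {
  jf <- jags_lmm(y, X, group1, group2 = group2, slope_x = slope_x,
                 robust = robust, priors = priors, seed = seed)
  out <- summarize_draws(jf$b_draws)
  attr(out, "converged") <- jf$converged
  attr(out, "b_draws") <- jf$b_draws
  out
}

finalize_estimates <- function(tidy, data, fork_id = NA_character_) {
  tidy$excludes_zero <- tidy$lower > 0 | tidy$upper < 0
  tidy$n_scans <- nrow(data)
  tidy$n_participants <- length(unique(data$participant_id))
  tidy$converged <- attr(tidy, "converged") %||% TRUE
  tidy$fork_id <- fork_id
  tidy
}

# build age columns and fixed-formula pieces for a spec
age_terms <- function(data, spec) {
  data$age_c <- data$age_at_scan - 12 # centered at 12 years
  fixed <- switch(spec$age_form,
    linear = "age_c",
    quadratic = c("age_c", "age_c_sq"),
    inverse = "inv_age")
  if (spec$age_form == "quadratic") data$age_c_sq <- data$age_c^2
  if (spec$age_form == "inverse") {
    assert_that(all(data$age_at_scan > 0), "inverse age needs positive ages")
    data$inv_age <- 1 / data$age_at_scan
  }
  covs <- setdiff(spec$covariates, "mean_fd")
  covs <- c("mean_fd", intersect(c("block", "scanner"), covs))
  if ("block" %in% covs) data$block <- data$block_order
  fixed <- c(fixed, covs)
  slope_var <- switch(spec$age_form, inverse = "inv_age", "age_c")
  list(data = data, fixed = fixed, slope_var = slope_var)
}

pretty_terms <- function(terms) {
  map <- c(age_c = "age", age_c_sq = "age_quadratic", inv_age = "inverse_age",
           `(Intercept)` = "intercept", age_between = "age_between",
           age_within = "age_within")
  unname(ifelse(terms %in% names(map), map[terms], terms))
}

# shared fitting path for any scan-level outcome model with participant
# random intercepts (+ optional random age slopes)
fit_scan_outcome <- function(data, outcome, spec, priors, seed, fixed,
                             slope_var = NULL, fork_id = NA_character_) {
  data$.y <- data[[outcome]]
  data <- data[!is.na(data$.y), , drop = FALSE]
  excl <- exclude_outliers(data$.y, spec$outlier_rule)
  data <- data[excl$keep, , drop = FALSE]
  assert_that(length(unique(data$participant_id)) >= 2,
              "need at least 2 participants")
  assert_that(sd(data$.y) > 0, "outcome is degenerate (zero variance)")

  if (spec$estimation == "fast_freq") {
    rnd <- if (spec$random_slopes && !is.null(slope_var))
      sprintf("(1 + %s | participant_id)", slope_var) else
      "(1 | participant_id)"
    f <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "), "+", rnd))
    tidy <- fit_freq(f, data, robust = spec$robust)
  } else {
    X <- model.matrix(stats::as.formula(
      paste("~", paste(fixed, collapse = " + "))), data)
    sx <- if (spec$random_slopes && !is.null(slope_var)) data[[slope_var]] else NULL
    tidy <- fit_bayes(data$.y, X, data$participant_id, slope_x = sx,
                      robust = spec$robust, priors = priors, seed = seed)
  }
  tidy$term <- pretty_terms(tidy$term)
  out <- finalize_estimates(tidy, data, fork_id)
  attr(out, "n_outliers_excluded") <- excl$n_excluded
  out
}

# ---- user-facing model fits ------------------------------------------------

#' Multilevel age-trajectory model for a scan-level measure
#'
#' `outcome ~ age form + mean FD (+ block + scanner)` with participant random
#' intercepts and optionally participant-varying age slopes. Age is centered
#' at 12 years (the inverse form uses 1/age on raw years). The `estimation`
#' field of the spec selects restricted maximum likelihood (lme4, Wald
#' intervals with Satterthwaite degrees of freedom) or MCMC (JAGS, student-t
#' priors, posterior median and equal-tailed 95% interval). The outlier rule
#' is applied to the outcome before fitting.
#'
#' @param scan_table scan-level tibble with `participant_id`, `age_at_scan`,
#'   `mean_fd` (+ `block_order`, `scanner` if used) and the outcome column.
#' @param outcome name of the outcome column.
#' @param spec an [age_model_spec()].
#' @param priors a [prior_spec()] (Bayesian path).
#' @param seed integer seed (MCMC path).
#' @param fork_id label carried into the output.
#' @return Tidy tibble, one row per fixed-effect term: `estimate`, `lower`,
#'   `upper`, `excludes_zero`, `n_scans`, `n_participants`, `converged`.
#' @export
fit_age_model <- function(scan_table, outcome, spec = age_model_spec(),
                          priors = prior_spec(), seed = 1,
                          fork_id = NA_character_) {
  if (spec$parametrization == "within_between") {
    return(fit_within_between(scan_table, outcome, spec, priors = priors,
                              seed = seed, fork_id = fork_id))
  }
  at <- age_terms(scan_table, spec)
  fit_scan_outcome(at$data, outcome, spec, priors, seed, at$fixed,
                   slope_var = at$slope_var, fork_id = fork_id)
}

#' Within/between-participant age decomposition
#'
#' Splits age into each participant's mean age across scans (between) and the
#' scan-level deviation from that mean (within); both slopes are estimated in
#' one model and their difference is reported. With a purely cross-sectional
#' table the within term is structurally inestimable and flagged.
#'
#' @inheritParams fit_age_model
#' @return Tidy tibble with `age_between`, `age_within` and
#'   `within_minus_between` rows (plus covariates); or, for cross-sectional
#'   data, a row flagged `inestimable`.
#' @export
fit_within_between <- function(scan_table, outcome, spec = age_model_spec(),
                               priors = prior_spec(), seed = 1,
                               fork_id = NA_character_) {
  d <- scan_table
  d$.mean_age <- stats::ave(d$age_at_scan, d$participant_id)
  n_multi <- sum(tapply(d$age_at_scan, d$participant_id, length) >= 2)
  d$age_between <- d$.mean_age - 12
  d$age_within <- d$age_at_scan - d$.mean_age
  if (n_multi == 0 || sd(d$age_within) == 0) {
    out <- tibble::tibble(term = "age_within", estimate = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          excludes_zero = NA, n_scans = nrow(d),
                          n_participants = length(unique(d$participant_id)),
                          converged = FALSE, fork_id = fork_id)
    attr(out, "inestimable") <- "no participant has 2 or more scans"
    return(out)
  }
  covs <- c("mean_fd", intersect(c("block", "scanner"),
                                 setdiff(spec$covariates, "mean_fd")))
  if ("block" %in% covs) d$block <- d$block_order
  fixed <- c("age_between", "age_within", covs)

  d$.y <- d[[outcome]]
  d <- d[!is.na(d$.y), , drop = FALSE]
  excl <- exclude_outliers(d$.y, spec$outlier_rule)
  d <- d[excl$keep, , drop = FALSE]

  if (spec$estimation == "fast_freq") {
    rnd <- if (spec$random_slopes) "(1 + age_within | participant_id)" else
      "(1 | participant_id)"
    f <- stats::as.formula(paste(".y ~", paste(fixed, collapse = " + "), "+", rnd))
    tidy <- fit_freq(f, d, robust = spec$robust)
    fit <- attr(tidy, "fit")
    cv <- numeric(nrow(tidy)); names(cv) <- tidy$term
    cv["age_within"] <- 1; cv["age_between"] <- -1
    V <- as.matrix(vcov(fit))
    dd <- cv[rownames(V)]
    diff_est <- sum(dd * lme4::fixef(fit)[rownames(V)])
    diff_se <- sqrt(drop(t(dd) %*% V %*% dd))
    diff_row <- tibble::tibble(term = "within_minus_between",
                               estimate = diff_est,
                               lower = diff_est - 1.96 * diff_se,
                               upper = diff_est + 1.96 * diff_se)
    conv <- attr(tidy, "converged")
    tidy <- dplyr::bind_rows(tidy, diff_row)
    attr(tidy, "converged") <- conv
  } else {
    X <- model.matrix(stats::as.formula(
      paste("~", paste(fixed, collapse = " + "))), d)
    sx <- if (spec$random_slopes) d$age_within else NULL
    tidy <- fit_bayes(d$.y, X, d$participant_id, slope_x = sx,
                      robust = spec$robust, priors = priors, seed = seed)
    bd <- attr(tidy, "b_draws")
    diff_d <- bd[, "age_within"] - bd[, "age_between"]
    conv <- attr(tidy, "converged")
    tidy <- dplyr::bind_rows(tidy, tibble::tibble(
      term = "within_minus_between", estimate = median(diff_d),
      lower = quantile(diff_d, 0.025), upper = quantile(diff_d, 0.975)))
    attr(tidy, "converged") <- conv
  }
  tidy$term <- pretty_terms(tidy$term)
  finalize_estimates(tidy, d, fork_id)
}

#' Group-level models of within-scan trial dynamics
#'
#' Three variants for estimating how within-scan change in reactivity varies
#' with age:
#' * `"slopes_on_age"` — scan-level Spearman slopes regressed on age (same
#'   machinery as [fit_age_model()]); the interest term is `age`.
#' * `"halves_interaction"` — half-mean outcome with an age x half
#'   interaction and within-scan pairing (`age:half` term).
#' * `"single_trial"` — trial-level outcome with a trial-number x age
#'   interaction and random intercepts for participants and scans
#'   (`age:trial` term).
#'
#' @param data variant-specific table. `slopes_on_age`: scan-level with a
#'   `slope` column. `halves_interaction`: one row per (scan, half) with
#'   columns `half` (1 or 2) and `half_mean`. `single_trial`: one row per
#'   trial with `trial_index` and `beta`.
#' @param variant one of the three method labels.
#' @inheritParams fit_age_model
#' @export
fit_trial_dynamics_models <- function(data,
                                      variant = c("slopes_on_age",
                                                  "halves_interaction",
                                                  "single_trial"),
                                      spec = age_model_spec(),
                                      priors = prior_spec(), seed = 1,
                                      fork_id = NA_character_) {
  variant <- match.arg(variant)
  if (variant == "slopes_on_age") {
    return(fit_age_model(data, "slope", spec, priors, seed, fork_id))
  }
  data$age_c <- data$age_at_scan - 12
  covs <- c("mean_fd", intersect(c("block", "scanner"),
                                 setdiff(spec$covariates, "mean_fd")))
  if ("block" %in% covs) data$block <- data$block_order
  if (variant == "halves_interaction") {
    data$half2 <- as.numeric(data$half == 2)
    fixed <- c("age_c", "half2", "age_c:half2", covs)
    outcome <- "half_mean"
    interact <- "age_c:half2"
    pretty <- "age:half"
  } else {
    data$trial_c <- data$trial_index - mean(data$trial_index)
    fixed <- c("age_c", "trial_c", "age_c:trial_c", covs)
    outcome <- "beta"
    interact <- "age_c:trial_c"
    pretty <- "age:trial"
  }
  data$.y <- data[[outcome]]
  data <- data[!is.na(data$.y), , drop = FALSE]
  if (spec$estimation == "fast_freq") {
    f <- stats::as.formula(paste(
      ".y ~", paste(fixed, collapse = " + "),
      "+ (1 | participant_id) + (1 | scan_id)"))
    tidy <- fit_freq(f, data, robust = spec$robust)
  } else {
    X <- model.matrix(stats::as.formula(
      paste("~", paste(fixed, collapse = " + "))), data)
    tidy <- fit_bayes(data$.y, X, data$participant_id, group2 = data$scan_id,
                      robust = spec$robust, priors = priors, seed = seed)
  }
  tidy$term[tidy$term == interact] <- pretty
  tidy$term <- pretty_terms(tidy$term)
  finalize_estimates(tidy, data, fork_id)
}

#' k-nearest-neighbour imputation of questionnaire items
#'
#' A missing item is replaced by the mean of that item among the `k` rows
#' nearest in Euclidean distance over the mutually observed items (items are
#' standardized before computing distances; distances are averaged per item
#' to compare rows with different overlap). Ties are broken by row order.
#' When fewer than `k` candidate rows exist, all available are used and the
#' result is flagged.
#'
#' @param item_table data frame / tibble of numeric item columns (id columns
#'   are preserved and ignored in distances).
#' @param k number of neighbours (default 5).
#' @param item_cols columns treated as items (default: numeric columns).
#' @return The completed table, with attribute `imputation_log` (tibble of
#'   row, item, value, n_neighbours, flagged).
#' @export
impute_scared_items <- function(item_table, k = 5, item_cols = NULL) {
  out <- item_table
  if (is.null(item_cols))
    item_cols <- names(item_table)[vapply(item_table, is.numeric, TRUE)]
  M <- as.matrix(item_table[, item_cols])
  if (!anyNA(M)) {
    attr(out, "imputation_log") <- tibble::tibble()
    return(out)
  }
  mu <- colMeans(M, na.rm = TRUE)
  s <- apply(M, 2, sd, na.rm = TRUE)
  s[is.na(s) | s == 0] <- 1
  Z <- sweep(sweep(M, 2, mu), 2, s, "/")
  log <- list()
  incomplete <- which(apply(M, 1, anyNA))
  for (i in incomplete) {
    assert_that(any(!is.na(M[i, ])),
                "each incomplete row must have at least one observed item")
    for (j in which(is.na(M[i, ]))) {
      cand <- which(!is.na(M[, j]) & seq_len(nrow(M)) != i)
      obs_i <- !is.na(Z[i, ])
      d <- vapply(cand, function(r) {
        shared <- obs_i & !is.na(Z[r, ])
        if (!any(shared)) return(Inf)
        sqrt(mean((Z[i, shared] - Z[r, shared])^2))
      }, numeric(1))
      cand <- cand[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(cand) == 0) next
      ord <- order(d, cand) # ties broken by row order
      use <- cand[ord][seq_len(min(k, length(cand)))]
      val <- mean(M[use, j])
      out[[item_cols[j]]][i] <- val
      log[[length(log) + 1]] <- tibble::tibble(
        row = i, item = item_cols[j], value = val,
        n_neighbours = length(use), flagged = length(use) < k)
    }
  }
  attr(out, "imputation_log") <- dplyr::bind_rows(log)
  out
}

#' Brain-measure to anxiety association model
#'
#' `standardized anxiety ~ brain + age + mean FD` with participant random
#' intercepts; scans without anxiety scores (adults) are dropped. The anxiety
#' outcome is z-scored, so the reported brain coefficient is invariant to
#' affine rescaling of the raw instrument.
#'
#' @param scan_table scan-level tibble including the brain and anxiety
#'   columns.
#' @param brain,anxiety column names.
#' @inheritParams fit_age_model
#' @return Tidy tibble; the interest row has `term == "brain"`.
#' @export
fit_brain_anxiety_model <- function(scan_table, brain, anxiety,
                                    spec = age_model_spec(),
                                    priors = prior_spec(), seed = 1,
                                    fork_id = NA_character_) {
  d <- scan_table[!is.na(scan_table[[anxiety]]) & !is.na(scan_table[[brain]]), ]
  d$.anx <- as.numeric(scale(d[[anxiety]]))
  d$brain <- d[[brain]]
  d$age_c <- d$age_at_scan - 12
  fixed <- c("brain", "age_c", "mean_fd")
  if (spec$estimation == "fast_freq") {
    f <- stats::as.formula(paste(".anx ~", paste(fixed, collapse = " + "),
                                 "+ (1 | participant_id)"))
    tidy <- fit_freq(f, d, robust = spec$robust)
  } else {
    X <- model.matrix(~ brain + age_c + mean_fd, d)
    tidy <- fit_bayes(d$.anx, X, d$participant_id, robust = spec$robust,
                      priors = priors, seed = seed)
  }
  tidy$term <- pretty_terms(tidy$term)
  finalize_estimates(tidy, d, fork_id)
}
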