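# ---- study bundle ----------------------------------------------------------

#' Simulate a complete synthetic study
#'
#' Cohort, shared task design, one synthetic scan per cohort row, and anxiety
#' scores, all from one seed.
#'
#' @param config [cohort_config()].
#' @param design [generate_task_design()] (shared across scans, as in the
#'   study, which fixed stimulus order across participants).
#' @param params [generative_params()].
#' @param seed integer seed.
#' @return List: `cohort`, `design`, `scans`, `anxiety`, `params`.
#' @export
simulate_study <- function(config = cohort_config(),
                           design = generate_task_design(),
                           params = generative_params(), seed = 1) {
  cohort <- generate_cohort(config, seed = seed)
  scans <- simulate_cohort_scans(cohort, design, params,
                                 seed = child_seed(seed, 1000))
  anx <- generate_anxiety_scores(cohort, params, seed = child_seed(seed, 2000))
  list(cohort = cohort, design = design, scans = scans,
       anxiety = anx$scores, scared_items = anx$scared_items, params = params)
}

#' Scan metadata table for a list of scan records
#'
#' One row per scan: cohort fields, `mean_fd`, and the `excluded` flag from
#' the >40-suprathreshold-volume rule.
#' @param scans list of `scan_record`s.
#' @export
meta_table <- function(scans) {
  dplyr::bind_rows(lapply(scans, function(s) {
    cw <- censor_weights(s$fd_series)
    dplyr::mutate(tibble::as_tibble(s$meta), scan_id = s$scan_id,
                  mean_fd = s$mean_fd, excluded = cw$scan_excluded)
  }))
}

# ---- scan-level estimate tables --------------------------------------------

amygdala_rois <- function() {
  c("amyg_bilateral", "amyg_left", "amyg_right", "amyg_high", "amyg_low",
    "amyg_ho_bilateral", "amyg_ho_left", "amyg_ho_right")
}

# prewhitening emulation of the GLM-software fork
prewhiten_for_software <- function(software) {
  if (identical(software, "cpac_afni")) "none" else "ar1"
}

#' Scan-level reactivity contrasts under participant-level design forks
#'
#' For each unique (software, hrf, nuisance, lowfreq) fork, fits the scan GLM
#' once per scan across the whole amygdala ROI panel (one QR per scan-fork).
#'
#' @param scans list of `scan_record`s.
#' @param design_forks tibble with columns `software`, `hrf`, `nuisance`,
#'   `lowfreq` (duplicates are collapsed).
#' @param rois ROI columns to estimate (default: the amygdala panel).
#' @return Long tibble: scan_id, fork columns, roi, contrast, beta, se,
#'   t_stat, dof.
#' @export
compute_reactivity_estimates <- function(scans, design_forks,
                                         rois = amygdala_rois()) {
  forks <- dplyr::distinct(design_forks[, c("software", "hrf", "nuisance",
                                            "lowfreq")])
  out <- vector("list", nrow(forks) * length(scans))
  k <- 0
  for (fi in seq_len(nrow(forks))) {
    fk <- forks[fi, ]
    hrf <- make_hrf(fk$hrf)
    for (s in scans) {
      dm <- build_design_matrix(
        s$design, s$realignment_params, s$fd_series, hrf = hrf,
        nuisance_set = fk$nuisance, detrend = fk$lowfreq,
        wm = s$roi_timeseries$wm, csf = s$roi_timeseries$csf)
      est <- fit_glm(as.matrix(s$roi_timeseries[, rois]), dm,
                     prewhiten = prewhiten_for_software(fk$software))
      est$scan_id <- s$scan_id
      k <- k + 1
      out[[k]] <- dplyr::bind_cols(est, fk[rep(1, nrow(est)), ])
    }
  }
  dplyr::bind_rows(out)
}

#' Single-trial LSS betas for all scans
#'
#' Runs [fit_lss()] per scan over the requested ROI set and returns both the
#' raw and the global-signal-centered (over `center_panel`) versions.
#'
#' @param scans list of `scan_record`s.
#' @param rois ROI columns needing betas.
#' @param center_panel ROI panel over which the per-trial mean is computed
#'   for the centered variant (default: amygdala + mPFC panel).
#' @return Tibble of trial betas with a logical `gss` column (both variants
#'   stacked).
#' @export
compute_lss_betas <- function(scans,
                              rois = c("amyg_bilateral", "amyg_left",
                                       "amyg_right", "mpfc1", "mpfc2",
                                       "mpfc3", "vmpfc"),
                              center_panel = NULL) {
  center_panel <- center_panel %||% rois
  raw <- dplyr::bind_rows(lapply(scans, function(s)
    fit_lss(as.matrix(s$roi_timeseries[, unique(c(rois, center_panel))]),
            s$design, s$realignment_params, s$fd_series,
            scan_id = s$scan_id)))
  centered <- apply_global_signal_centering(raw, rois = center_panel)
  raw$gss <- FALSE
  centered$gss <- TRUE
  dplyr::bind_rows(raw[raw$roi %in% rois, ], centered[centered$roi %in% rois, ])
}

#' Scan-level gPPI estimates
#'
#' Builds the gPPI design per scan (amygdala seed) for each deconvolution
#' option and fits all mPFC targets.
#'
#' @param scans list of `scan_record`s.
#' @param deconv_options logical vector of deconvolution forks to compute.
#' @param targets target ROI columns.
#' @param seed_roi seed ROI column.
#' @param center_task centering fork (default FALSE; the main deconvolution
#'   pipeline does not center the task regressor).
#' @return Long tibble: scan_id, deconvolution, target, term, estimate, se.
#' @export
compute_gppi_estimates <- function(scans, deconv_options = c(TRUE, FALSE),
                                   targets = c("mpfc1", "mpfc2", "mpfc3",
                                               "vmpfc"),
                                   seed_roi = "amyg_bilateral",
                                   center_task = FALSE) {
  out <- list()
  for (dc in deconv_options) {
    for (s in scans) {
      gd <- build_gppi_design(
        s$roi_timeseries[[seed_roi]], s$design, deconvolve = dc,
        center_task = center_task, rp = s$realignment_params,
        fd_series = s$fd_series)
      for (tg in targets) {
        est <- fit_gppi(s$roi_timeseries[[tg]], gd)
        est$scan_id <- s$scan_id
        est$deconvolution <- dc
        est$target <- tg
        out[[length(out) + 1]] <- est
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Scan-level beta-series correlations
#'
#' @param lss_table stacked trial-beta table from [compute_lss_betas()].
#' @param seed_rois,target_rois ROI pairs to correlate.
#' @param condition trial condition.
#' @return Tibble: scan_id, roi (seed), mpfc (target), gss, condition, r, z.
#' @export
compute_bsc_estimates <- function(lss_table,
                                  seed_rois = c("amyg_bilateral", "amyg_left",
                                                "amyg_right"),
                                  target_rois = c("mpfc1", "mpfc2", "mpfc3",
                                                  "vmpfc"),
                                  condition = "fear") {
  combos <- expand.grid(scan_id = unique(lss_table$scan_id),
                        roi = seed_rois, mpfc = target_rois,
                        gss = unique(lss_table$gss),
                        stringsAsFactors = FALSE)
  sub <- lss_table[lss_table$condition == condition, ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    a <- sub[sub$scan_id == cm$scan_id & sub$roi == cm$roi &
               sub$gss == cm$gss, ]
    b <- sub[sub$scan_id == cm$scan_id & sub$roi == cm$mpfc &
               sub$gss == cm$gss, ]
    m <- dplyr::inner_join(a[, c("trial_index", "beta")],
                           b[, c("trial_index", "beta")],
                           by = "trial_index", suffix = c("_a", "_b"))
    r <- bsc(m$beta_a, m$beta_b)
    dplyr::bind_cols(tibble::as_tibble(cm), r[, c("r", "z", "n_pairs")],
                     condition = condition)
  })
  dplyr::bind_rows(rows)
}

# ---- aim runner ------------------------------------------------------------

# append the derived "age_trend" row: the implied per-year age slope at the
# centering age (12 y), comparable across age forms. Linear and quadratic
# forms contribute their linear coefficient; the inverse form contributes
# d(b/age)/d age at 12 y = -b/144, which also flips the sign (1/age
# decreases in age).
add_age_trend <- function(tidy, age_center = 12) {
  if ("age" %in% tidy$term) {
    r <- tidy[tidy$term == "age", ]
    r$term <- "age_trend"
    return(dplyr::bind_rows(tidy, r))
  }
  if ("inverse_age" %in% tidy$term) {
    r <- tidy[tidy$term == "inverse_age", ]
    r$term <- "age_trend"
    sc <- -1 / age_center^2
    lo <- sc * r$upper; hi <- sc * r$lower
    r$estimate <- sc * r$estimate; r$lower <- lo; r$upper <- hi
    return(dplyr::bind_rows(tidy, r))
  }
  tidy
}

#' Run a full analysis aim end to end
#'
#' Scan-level estimation under participant-level forks, group-level
#' multilevel models under group-level forks, specification curve and
#' decision-point meta-regression. Grids default to the packaged ones but
#' reduced grids can be supplied for quick runs.
#'
#' @param aim `"reactivity"`, `"trial_dynamics"`, `"gppi"`, `"bsc"` or one of
#'   the `"anxiety_*"` curves.
#' @param bundle a [simulate_study()] bundle (or an equivalent list).
#' @param grid grid for [enumerate_specs()]; defaults to [default_grid()].
#' @param estimation `"fast_freq"` or `"bayes_mcmc"` for the group stage.
#' @param seed integer seed (used by the MCMC path; derived per spec).
#' @param contrast scan-level contrast of interest (reactivity/gPPI).
#' @param condition trial condition (trial dynamics / BSC).
#' @param method trial-dynamics method.
#' @param curve_term term the specification curve is built on (default
#'   `"age_trend"`, or `"brain"` for anxiety aims).
#' @return List: `specs`, `estimates`, `failures`, `curve`,
#'   `decision_effects`.
#' @export
run_aim <- function(aim, bundle, grid = default_grid(aim),
                    estimation = "fast_freq", seed = 1,
                    contrast = "fear>baseline", condition = "fear",
                    method = "slopes_on_age", curve_term = NULL) {
  specs <- enumerate_specs(grid)
  meta <- meta_table(bundle$scans)
  scans_ok <- bundle$scans[!meta$excluded[match(names(bundle$scans),
                                                meta$scan_id)]]
  curve_term <- curve_term %||%
    if (startsWith(aim, "anxiety")) "brain" else "age_trend"

  fit_one <- NULL
  if (aim == "reactivity") {
    scan_est <- compute_reactivity_estimates(scans_ok, specs)
    fit_one <- function(row) {
      sub <- scan_est[scan_est$software == row$software &
                        scan_est$hrf == row$hrf &
                        scan_est$nuisance == row$nuisance &
                        scan_est$lowfreq == row$lowfreq &
                        scan_est$roi == row$roi &
                        scan_est$contrast == contrast, ]
      d <- dplyr::inner_join(meta, sub, by = "scan_id")
      d$outcome <- if (row$estimate == "t") d$t_stat else d$beta
      gs <- group_spec_from_row(row, estimation)
      tidy <- fit_age_model(d, "outcome", gs, seed = child_seed(seed, 1))
      add_age_trend(tidy)
    }
  } else if (aim == "trial_dynamics") {
    rois <- unique(specs$roi)
    lss <- compute_lss_betas(scans_ok, rois = unique(c(rois, "mpfc1", "mpfc2",
                                                       "mpfc3", "vmpfc")))
    dyn <- dplyr::bind_rows(
      dplyr::mutate(trial_dynamics_table(lss[lss$condition == condition &
                                               !lss$gss, ]), gss = FALSE),
      dplyr::mutate(trial_dynamics_table(lss[lss$condition == condition &
                                               lss$gss, ]), gss = TRUE))
    fit_one <- function(row) {
      d <- dyn[dyn$roi == row$roi & dyn$gss == row$gss, ]
      d <- dplyr::inner_join(meta, d, by = "scan_id")
      gs <- group_spec_from_row(row, estimation)
      tidy <- fit_trial_dynamics_models(d, method, gs,
                                        seed = child_seed(seed, 2))
      add_age_trend(tidy)
    }
  } else if (aim == "gppi") {
    gp <- compute_gppi_estimates(scans_ok,
                                 deconv_options = unique(specs$deconvolution),
                                 targets = unique(specs$mpfc))
    term_lab <- paste("ppi", contrast)
    fit_one <- function(row) {
      sub <- gp[gp$deconvolution == row$deconvolution &
                  gp$target == row$mpfc & gp$term == term_lab, ]
      d <- dplyr::inner_join(meta, sub, by = "scan_id")
      if (row$include_prev == "exclude") d <- d[!d$prev_analyzed, ]
      d$outcome <- d$estimate
      gs <- group_spec_from_row(row, estimation)
      tidy <- fit_age_model(d, "outcome", gs, seed = child_seed(seed, 3))
      add_age_trend(tidy)
    }
  } else if (aim == "bsc") {
    lss <- compute_lss_betas(scans_ok,
                             rois = unique(c(specs$roi, specs$mpfc)))
    bz <- compute_bsc_estimates(lss, seed_rois = unique(specs$roi),
                                target_rois = unique(specs$mpfc),
                                condition = condition)
    fit_one <- function(row) {
      sub <- bz[bz$roi == row$roi & bz$mpfc == row$mpfc &
                  bz$gss == row$gss, ]
      d <- dplyr::inner_join(meta, sub, by = "scan_id")
      d$outcome <- d$z
      gs <- group_spec_from_row(row, estimation)
      tidy <- fit_age_model(d, "outcome", gs, seed = child_seed(seed, 4))
      add_age_trend(tidy)
    }
  } else if (startsWith(aim, "anxiety")) {
    fit_one <- build_anxiety_fit_one(aim, bundle, specs, meta, scans_ok,
                                     estimation, seed)
  } else {
    abort(paste("unknown aim:", aim))
  }

  mv <- run_multiverse(specs, fit_one)
  curve <- build_spec_curve(mv$estimates, curve_term, specs = specs)
  de <- tryCatch(decision_effects(mv$estimates, specs, curve_term),
                 error = function(e) NULL)
  list(aim = aim, specs = specs, estimates = mv$estimates,
       failures = mv$failures, curve = curve, decision_effects = de)
}

# anxiety curves share structure: brain measure under forks -> association
# model with the chosen anxiety outcome
build_anxiety_fit_one <- function(aim, bundle, specs, meta, scans_ok,
                                  estimation, seed) {
  anx <- bundle$anxiety
  join_anx <- function(d, outcome) {
    d <- dplyr::inner_join(d, anx[, c("participant_id", "wave", outcome)],
                           by = c("participant_id", "wave"))
    d
  }
  if (aim == "anxiety_reactivity") {
    forks <- tibble::tibble(software = "fsl_fsl", hrf = "double_gamma",
                            nuisance = "24", lowfreq = "highpass")
    scan_est <- compute_reactivity_estimates(scans_ok, forks,
                                             rois = unique(specs$roi))
    function(row) {
      sub <- scan_est[scan_est$roi == row$roi &
                        scan_est$contrast == row$contrast, ]
      d <- join_anx(dplyr::inner_join(meta, sub, by = "scan_id"), row$outcome)
      fit_brain_anxiety_model(d, "beta", row$outcome,
                              age_model_spec(estimation = estimation),
                              seed = child_seed(seed, 5))
    }
  } else if (aim == "anxiety_gppi") {
    gp <- compute_gppi_estimates(scans_ok,
                                 deconv_options = unique(specs$deconvolution))
    function(row) {
      if (row$target == "physio_vmpfc") {
        sub <- gp[gp$deconvolution == row$deconvolution &
                    gp$target == "vmpfc" & gp$term == "physio", ]
      } else {
        sub <- gp[gp$deconvolution == row$deconvolution &
                    gp$target == row$target &
                    gp$term == paste("ppi", row$contrast), ]
      }
      d <- join_anx(dplyr::inner_join(meta, sub, by = "scan_id"), row$outcome)
      fit_brain_anxiety_model(d, "estimate", row$outcome,
                              age_model_spec(estimation = estimation),
                              seed = child_seed(seed, 6))
    }
  } else if (aim == "anxiety_bsc") {
    lss <- compute_lss_betas(
      scans_ok,
      rois = unique(c(specs$roi, "vmpfc")),
      center_panel = unique(c(specs$roi, "mpfc1", "mpfc2", "mpfc3", "vmpfc")))
    bz <- compute_bsc_estimates(lss, seed_rois = unique(specs$roi),
                                target_rois = "vmpfc")
    function(row) {
      sub <- bz[bz$roi == row$roi & bz$gss == row$gss, ]
      d <- join_anx(dplyr::inner_join(meta, sub, by = "scan_id"), row$outcome)
      fit_brain_anxiety_model(d, "z", row$outcome,
                              age_model_spec(estimation = estimation),
                              seed = child_seed(seed, 7))
    }
  } else if (aim == "anxiety_slopes") {
    lss <- compute_lss_betas(scans_ok, rois = c("amyg_bilateral", "mpfc1",
                                                "mpfc2", "mpfc3", "vmpfc"))
    function(row) {
      sub <- lss[lss$roi == "amyg_bilateral" & lss$gss == row$gss &
                   lss$condition == row$condition, ]
      dyn <- trial_dynamics_table(sub)
      d <- join_anx(dplyr::inner_join(meta, dyn, by = "scan_id"), row$outcome)
      fit_brain_anxiety_model(d, "slope", row$outcome,
                              age_model_spec(estimation = estimation),
                              seed = child_seed(seed, 8))
    }
  } else {
    abort(paste("unknown anxiety aim:", aim))
  }
}
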