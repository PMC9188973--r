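# ---- specification grids ---------------------------------------------------

#' Enumerate a specification grid
#'
#' A grid is a list of parts; each part is either a named list of level
#' vectors (crossed factorially within the part) or a data.frame of curated
#' decision combinations (rows used as-is). Parts are crossed with each
#' other. Every specification receives a stable `fork_id` (content hash of
#' its decision mapping), and enumeration order is deterministic.
#'
#' @param grid list of parts (named lists and/or data.frames).
#' @return Tibble of specifications, one row each, with `fork_id` first.
#' @examples
#' nrow(enumerate_specs(list(list(a = 1:2, b = letters[1:4])))) # 8
#' @export
enumerate_specs <- function(grid) {
  assert_that(is.list(grid) && length(grid) >= 1, "grid must be a non-empty list")
  parts <- lapply(grid, function(part) {
    if (is.data.frame(part)) return(tibble::as_tibble(part))
    assert_that(is.list(part) && !is.null(names(part)) && all(names(part) != ""),
                "factorial grid parts must be fully named lists")
    for (nm in names(part)) {
      assert_that(!anyDuplicated(part[[nm]]),
                  sprintf("duplicate level names in decision point '%s'", nm))
    }
    tibble::as_tibble(expand.grid(part, stringsAsFactors = FALSE,
                                  KEEP.OUT.ATTRS = FALSE))
  })
  specs <- Reduce(function(a, b) tidyr::crossing(a, b), parts)
  dup <- intersect(unlist(lapply(parts, names)), character(0))
  fork_id <- vapply(seq_len(nrow(specs)), function(i) {
    m <- as.list(specs[i, ])
    m <- m[order(names(m))]
    substr(digest::digest(m, algo = "sha1"), 1, 12)
  }, character(1))
  assert_that(!anyDuplicated(fork_id), "fork ids collide: duplicate specifications")
  dplyr::bind_cols(tibble::tibble(fork_id = fork_id), specs)
}

covariate_levels <- function() c("fd", "fd_block", "fd_scanner", "fd_block_scanner")

covariates_from_level <- function(level) {
  switch(level,
         fd = "mean_fd",
         fd_block = c("mean_fd", "block"),
         fd_scanner = c("mean_fd", "scanner"),
         fd_block_scanner = c("mean_fd", "block", "scanner"),
         abort(paste("unknown covariate level:", level)))
}

# 18 curated group-level model specifications (reconstruction; the printed
# count is matched, the membership is this package's documented choice)
group_grid_18 <- function() {
  g <- dplyr::bind_rows(
    expand.grid(age_form = "linear", covariates = covariate_levels(),
                random_slopes = c(TRUE, FALSE), outlier_rule = "exclude_3sd",
                stringsAsFactors = FALSE),
    expand.grid(age_form = "linear", covariates = covariate_levels(),
                random_slopes = TRUE, outlier_rule = "exclude_3sd_plus_robust",
                stringsAsFactors = FALSE),
    expand.grid(age_form = "quadratic", covariates = covariate_levels(),
                random_slopes = TRUE, outlier_rule = "exclude_3sd",
                stringsAsFactors = FALSE),
    expand.grid(age_form = "inverse", covariates = c("fd", "fd_scanner"),
                random_slopes = TRUE, outlier_rule = "exclude_3sd",
                stringsAsFactors = FALSE)
  )
  tibble::as_tibble(g)
}

# 7 curated group-level specifications (robust regression throughout)
group_grid_7 <- function() {
  tibble::tibble(
    age_form = c(rep("linear", 4), "quadratic", "linear", "inverse"),
    covariates = c(covariate_levels(), "fd", "fd", "fd"),
    random_slopes = c(rep(TRUE, 5), FALSE, TRUE),
    outlier_rule = "exclude_3sd_plus_robust"
  )
}

# 156 curated participant-level reactivity pipelines: a fully-factorial FSL
# branch (120) plus a C-PAC branch with atlas-space ROIs (36)
reactivity_participant_grid <- function() {
  fsl <- expand.grid(
    software = "fsl_fsl",
    hrf = c("double_gamma", "single_gamma"),
    nuisance = c("24", "6", "18_wm_csf"),
    lowfreq = c("highpass", "quadratic"),
    estimate = c("beta", "t"),
    roi = c("amyg_bilateral", "amyg_left", "amyg_right", "amyg_high",
            "amyg_low"),
    stringsAsFactors = FALSE)
  cpac <- expand.grid(
    software = c("cpac_fsl", "cpac_afni"),
    hrf = "double_gamma",
    nuisance = c("24", "6", "18_wm_csf"),
    lowfreq = "highpass",
    estimate = c("beta", "t"),
    roi = c("amyg_ho_bilateral", "amyg_ho_left", "amyg_ho_right"),
    stringsAsFactors = FALSE)
  tibble::as_tibble(dplyr::bind_rows(fsl, cpac))
}

#' Packaged default specification grids
#'
#' Curated grids whose sizes reproduce the study's printed specification
#' counts: reactivity 2,808 (156 participant-level x 18 group-level), gPPI
#' 288 (4 x 4 mPFC x 18), BSC 168 (3 x 4 x 2 x 7), trial dynamics 42
#' (3 x 2 x 7), and anxiety curves of 18 / 90 / 18 / 12 specifications. The
#' memberships are this package's documented reconstruction.
#'
#' @param aim one of `"reactivity"`, `"trial_dynamics"`, `"gppi"`, `"bsc"`,
#'   `"anxiety_reactivity"`, `"anxiety_gppi"`, `"anxiety_bsc"`,
#'   `"anxiety_slopes"`.
#' @return A grid (list of parts) for [enumerate_specs()].
#' @export
default_grid <- function(aim = c("reactivity", "trial_dynamics", "gppi", "bsc",
                                 "anxiety_reactivity", "anxiety_gppi",
                                 "anxiety_bsc", "anxiety_slopes")) {
  aim <- match.arg(aim)
  switch(aim,
    reactivity = list(reactivity_participant_grid(), group_grid_18()),
    trial_dynamics = list(
      list(roi = c("amyg_bilateral", "amyg_left", "amyg_right"),
           gss = c(TRUE, FALSE)),
      group_grid_7()),
    gppi = list(
      list(deconvolution = c(TRUE, FALSE),
           include_prev = c("include", "exclude")),
      list(mpfc = c("mpfc1", "mpfc2", "mpfc3", "vmpfc")),
      group_grid_18()),
    bsc = list(
      list(roi = c("amyg_bilateral", "amyg_left", "amyg_right"),
           mpfc = c("mpfc1", "mpfc2", "mpfc3", "vmpfc"),
           gss = c(TRUE, FALSE)),
      group_grid_7()),
    anxiety_reactivity = list(
      list(outcome = c("rcads_raw", "scared_raw", "scared_t"),
           contrast = c("fear>baseline", "neutral>baseline", "fear>neutral"),
           roi = c("amyg_bilateral", "amyg_right"))),
    anxiety_gppi = list(
      list(outcome = c("rcads_raw", "scared_raw", "scared_t"),
           deconvolution = c(TRUE, FALSE),
           contrast = c("fear>baseline", "neutral>baseline", "fear>neutral"),
           target = c("mpfc1", "mpfc2", "mpfc3", "vmpfc", "physio_vmpfc"))),
    anxiety_bsc = list(
      list(outcome = c("rcads_raw", "scared_raw", "scared_t"),
           gss = c(TRUE, FALSE),
           roi = c("amyg_bilateral", "amyg_left", "amyg_right"))),
    anxiety_slopes = list(
      list(outcome = c("rcads_raw", "scared_raw", "scared_t"),
           gss = c(TRUE, FALSE), condition = c("fear", "neutral"))))
}

group_spec_from_row <- function(row, estimation = "fast_freq") {
  age_model_spec(age_form = row$age_form,
                 covariates = covariates_from_level(row$covariates),
                 random_slopes = isTRUE(row$random_slopes) | row$random_slopes == "TRUE",
                 outlier_rule = row$outlier_rule,
                 estimation = estimation)
}

# ---- multiverse execution --------------------------------------------------

#' Run every specification of a grid
#'
#' Applies `fit_one(spec_row)` to each specification; failures are caught and
#' logged per fork without aborting the sweep, unless more than
#' `max_failure_frac` of the specifications fail.
#'
#' @param specs tibble from [enumerate_specs()].
#' @param fit_one function taking one spec row (a one-row tibble) and
#'   returning tidy estimate rows.
#' @param max_failure_frac sweep-level failure threshold (default 0.2).
#' @return List: `estimates` (rows carry `fork_id`), `failures` (tibble of
#'   `fork_id`, `error`).
#' @export
run_multiverse <- function(specs, fit_one, max_failure_frac = 0.2) {
  res <- vector("list", nrow(specs))
  fails <- list()
  for (i in seq_len(nrow(specs))) {
    row <- specs[i, ]
    out <- tryCatch(fit_one(row), error = function(e) e)
    if (inherits(out, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        fork_id = row$fork_id, error = conditionMessage(out))
    } else {
      out$fork_id <- row$fork_id
      res[[i]] <- out
    }
  }
  failures <- dplyr::bind_rows(fails)
  if (nrow(specs) > 0 && nrow(failures) / nrow(specs) > max_failure_frac) {
    abort(sprintf("multiverse sweep failed for %d of %d specifications",
                  nrow(failures), nrow(specs)))
  }
  list(estimates = dplyr::bind_rows(res), failures = failures)
}

#' Build a specification curve
#'
#' Ranks one term's estimates ascending, computes the median estimate
#' (midpoint rule for even counts), the proportion of estimates sharing the
#' median's sign, and the proportions of intervals excluding zero (overall
#' and in the median's direction). When `specs` is supplied, decision-level
#' rank summaries (median and IQR of curve ranks per decision level) are
#' attached.
#'
#' @param estimates tidy estimates with `fork_id`, `term`, `estimate`,
#'   `lower`, `upper`, `excludes_zero`.
#' @param term the term to curve (e.g. `"age_trend"`).
#' @param specs optional specification tibble for decision-rank summaries.
#' @return A `spec_curve`: list with `curve` (sorted tibble with `rank`),
#'   `summary`, and optionally `decision_ranks`.
#' @export
build_spec_curve <- function(estimates, term, specs = NULL) {
  est <- estimates[estimates$term == term & !is.na(estimates$estimate), ]
  assert_that(nrow(est) >= 1, "no estimates for requested term")
  est <- est[order(est$estimate), ]
  est$rank <- seq_len(nrow(est))
  med <- median(est$estimate)
  med_sign <- if (sign(med) == 0) 1 else sign(med)
  est$sign <- sign(est$estimate)
  prop_same_sign <- mean(est$sign == med_sign)
  prop_excl <- mean(est$excludes_zero)
  prop_excl_dir <- mean(est$excludes_zero & est$sign == med_sign)
  out <- list(curve = est,
              summary = list(median_estimate = med,
                             median_sign = med_sign,
                             n_specs = nrow(est),
                             prop_same_sign = prop_same_sign,
                             prop_excl_zero = prop_excl,
                             prop_excl_zero_same_dir = prop_excl_dir))
  if (!is.null(specs)) {
    # join only the rank to avoid collisions with decision points that share
    # a name with estimate columns (e.g. the beta-vs-t "estimate" decision)
    j <- dplyr::inner_join(est[, c("fork_id", "rank")], specs, by = "fork_id")
    points <- setdiff(names(specs), "fork_id")
    dr <- lapply(points, function(p) {
      lev <- as.character(j[[p]])
      tibble::tibble(decision = p, level = unique(lev),
                     median_rank = unname(vapply(unique(lev), function(l)
                       median(j$rank[lev == l]), numeric(1))),
                     iqr_rank = unname(vapply(unique(lev), function(l)
                       stats::IQR(j$rank[lev == l]), numeric(1))))
    })
    dr <- dplyr::bind_rows(dr)
    # decision points ordered by spread of their level median ranks
    spread <- tapply(dr$median_rank, dr$decision, function(v) diff(range(v)))
    dr$decision <- factor(dr$decision,
                          levels = names(sort(spread, decreasing = TRUE)))
    out$decision_ranks <- dr[order(dr$decision), ]
  }
  structure(out, class = "spec_curve")
}

#' @export
print.spec_curve <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<spec_curve> %d specifications; median estimate %.4g; ",
                     "%.1f%% same sign as median; %.1f%% of intervals exclude 0 ",
                     "in the median direction\n"),
              s$n_specs, s$median_estimate, 100 * s$prop_same_sign,
              100 * s$prop_excl_zero_same_dir))
  invisible(x)
}

#' Conditional effects of analysis decisions on the estimates
#'
#' Regresses point estimates on indicator-coded decision levels (treatment
#' coding, first level of each decision as reference). Fully aliased decision
#' points raise an error naming the alias; partial aliasing in curated grids
#' is flagged.
#'
#' @param estimates tidy estimates (one row per spec for the chosen `term`).
#' @param specs specification tibble from [enumerate_specs()].
#' @param term term to analyze.
#' @return Tibble of decision-level coefficients with `decision`, `level`,
#'   `estimate`, `se`; attribute `aliased` flags rank deficiency.
#' @export
decision_effects <- function(estimates, specs, term) {
  est <- estimates[estimates$term == term & !is.na(estimates$estimate), ]
  d <- tibble::tibble(fork_id = est$fork_id, .outcome = est$estimate)
  d <- dplyr::inner_join(d, specs, by = "fork_id")
  points <- setdiff(names(specs), "fork_id")
  varying <- points[vapply(points, function(p)
    length(unique(d[[p]])) > 1, TRUE)]
  assert_that(length(varying) >= 1, "no decision point varies across specs")
  for (p in varying) d[[p]] <- factor(as.character(d[[p]]))
  f <- stats::as.formula(paste(".outcome ~",
                               paste(sprintf("`%s`", varying), collapse = " + ")))
  fit <- lm(f, data = d)
  al <- stats::alias(fit)
  aliased_terms <- character(0)
  if (!is.null(al$Complete) && nrow(al$Complete) > 0) {
    # curated (non-factorial) grids can tie some levels to combinations of
    # others; those coefficients are inestimable and reported as an aliasing
    # flag. A decision point whose every level is tied this way is fully
    # aliased and cannot be analyzed.
    aliased_terms <- gsub("`", "", rownames(al$Complete))
    for (p in varying) {
      lev_terms <- paste0(p, levels(d[[p]])[-1])
      if (all(lev_terms %in% aliased_terms)) {
        abort(paste0("decision point '", p,
                     "' is fully aliased with other decisions"))
      }
    }
  }
  sm <- summary(fit)$coefficients
  cf <- tibble::tibble(term = gsub("`", "", rownames(sm)),
                       estimate = unname(sm[, "Estimate"]),
                       se = unname(sm[, "Std. Error"]))
  cf <- cf[cf$term != "(Intercept)", ]
  cf$decision <- vapply(cf$term, function(tn)
    varying[which.max(vapply(varying, function(p)
      startsWith(tn, p) * nchar(p), numeric(1)))], character(1))
  cf$level <- substr(cf$term, nchar(cf$decision) + 1, nchar(cf$term))
  ref <- vapply(varying, function(p) levels(d[[p]])[1], character(1))
  out <- cf[, c("decision", "level", "estimate", "se", "term")]
  attr(out, "reference_levels") <- setNames(ref, varying)
  attr(out, "aliased") <- any(is.na(coef(fit)))
  attr(out, "aliased_terms") <- aliased_terms
  out
}
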