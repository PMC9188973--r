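#!/usr/bin/env Rscript

# Stage 6: longitudinal test-retest reliability of every scan-level measure
# via variance-decomposition ICCs (fast variance-components point estimates
# with participant bootstrap intervals, plus the posterior-predictive method
# for the headline measures).

suppressMessages({library(specfmri); library(dplyr)})

seed <- 20260919
dir.create("results", showWarnings = FALSE)
bundle <- simulate_study(seed = seed)
meta <- meta_table(bundle$scans)
ok <- bundle$scans[!meta$excluded[match(names(bundle$scans), meta$scan_id)]]

scan_est <- compute_reactivity_estimates(
  ok, tibble::tibble(software = "fsl_fsl", hrf = "double_gamma",
                     nuisance = "24", lowfreq = "highpass"),
  rois = "amyg_bilateral")
react <- inner_join(meta, scan_est, by = "scan_id")

gp <- compute_gppi_estimates(ok, deconv_options = FALSE, targets = "vmpfc")
gppi <- inner_join(meta, gp[gp$term == "ppi fear>baseline", ], by = "scan_id")
gppi$gppi_beta <- gppi$estimate

rows <- list()
for (ctr in unique(react$contrast)) {
  d <- react[react$contrast == ctr, ]
  rows[[length(rows) + 1]] <- icc_variance_components(
    d, "beta", nboot = 500, seed = seed) |>
    mutate(measure = paste0("reactivity ", ctr))
}
rows[[length(rows) + 1]] <- icc_variance_components(
  gppi, "gppi_beta", nboot = 500, seed = seed) |>
  mutate(measure = "gppi fear>baseline (vmPFC)")
rows[[length(rows) + 1]] <- icc_variance_components(
  meta, "mean_fd", covariates = character(0), nboot = 500, seed = seed) |>
  mutate(measure = "mean FD")
anx <- inner_join(meta, bundle$anxiety,
                  by = c("participant_id", "wave", "age_at_scan"))
rows[[length(rows) + 1]] <- icc_variance_components(
  anx, "scared_raw", nboot = 500, seed = seed) |>
  mutate(measure = "SCARED raw")

# posterior-predictive variant for the headline reactivity measure
fear <- react[react$contrast == "fear>baseline", ]
rows[[length(rows) + 1]] <- icc_variance_components(
  fear, "beta", method = "posterior_predictive", seed = seed) |>
  mutate(measure = "reactivity fear>baseline (posterior predictive)")

icc_tab <- bind_rows(rows)
readr::write_csv(icc_tab, "results/icc.csv")
message("test-retest reliability (variance decomposition):")
print(as.data.frame(icc_tab[, c("measure", "icc", "lower", "upper", "band",
                                "method")]))
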