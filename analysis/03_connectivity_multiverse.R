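#!/usr/bin/env Rscript

# Stage 3: amygdala-mPFC functional connectivity multiverses — gPPI (288
# specifications; the deconvolution fork is the decision of interest) and
# beta-series correlation (168 specifications) — plus the rank-order
# concordance of scan-level FC estimates across methods.

suppressMessages({library(specfmri); library(dplyr)})

seed <- 20260919
dir.create("results", showWarnings = FALSE)
bundle <- simulate_study(seed = seed)

t0 <- Sys.time()
gp <- run_aim("gppi", bundle, seed = seed)
message(sprintf("gPPI: %d specs in %.1f min; median age slope %.4f; %.1f%% same sign",
                nrow(gp$specs), as.numeric(Sys.time() - t0, units = "mins"),
                gp$curve$summary$median_estimate,
                100 * gp$curve$summary$prop_same_sign))
readr::write_csv(gp$estimates, "results/gppi_estimates.csv")
readr::write_csv(gp$curve$curve, "results/gppi_curve.csv")
readr::write_csv(gp$decision_effects, "results/gppi_decision_effects.csv")

t0 <- Sys.time()
bs <- run_aim("bsc", bundle, seed = seed)
message(sprintf("BSC: %d specs in %.1f min; median age slope %.4f",
                nrow(bs$specs), as.numeric(Sys.time() - t0, units = "mins"),
                bs$curve$summary$median_estimate))
readr::write_csv(bs$estimates, "results/bsc_estimates.csv")
readr::write_csv(bs$curve$curve, "results/bsc_curve.csv")
readr::write_csv(bs$decision_effects, "results/bsc_decision_effects.csv")

# scan-level concordance between gPPI forks and BSC forks
meta <- meta_table(bundle$scans)
ok <- bundle$scans[!meta$excluded[match(names(bundle$scans), meta$scan_id)]]
gp_scan <- compute_gppi_estimates(ok, targets = "vmpfc")
lss <- compute_lss_betas(ok, rois = c("amyg_bilateral", "vmpfc"),
                         center_panel = c("amyg_bilateral", "mpfc1", "mpfc2",
                                          "mpfc3", "vmpfc"))
bsc_scan <- compute_bsc_estimates(lss, seed_rois = "amyg_bilateral",
                                  target_rois = "vmpfc")
fc <- bind_rows(
  gp_scan |>
    filter(term == "ppi fear>baseline") |>
    transmute(scan_id,
              fork = paste0("gppi_deconv_", deconvolution), estimate),
  bsc_scan |>
    transmute(scan_id, fork = paste0("bsc_gss_", gss), estimate = z))
conc <- fc_method_concordance(fc)
readr::write_csv(tibble::as_tibble(conc, rownames = "fork"),
                 "results/fc_method_concordance.csv")
message("FC method concordance (Spearman):")
print(round(conc, 2))
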