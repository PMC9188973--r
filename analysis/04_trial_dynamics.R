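#!/usr/bin/env Rscript

# Stage 4: within-scan change in amygdala reactivity across trials — the
# 42-specification multiverse (3 amygdala ROIs x 2 global-signal options x 7
# group-level models) using the trial-slopes method, for fear and neutral
# trials separately.

suppressMessages(library(specfmri))

seed <- 20260919
dir.create("results", showWarnings = FALSE)
bundle <- simulate_study(seed = seed)

for (cond in c("fear", "neutral")) {
  t0 <- Sys.time()
  res <- run_aim("trial_dynamics", bundle, seed = seed, condition = cond)
  s <- res$curve$summary
  message(sprintf("%s: %d specs in %.1f min; median age effect on trial slopes %.4f (%.0f%% same sign)",
                  cond, nrow(res$specs),
                  as.numeric(Sys.time() - t0, units = "mins"),
                  s$median_estimate, 100 * s$prop_same_sign))
  readr::write_csv(res$estimates,
                   sprintf("results/trial_dynamics_%s_estimates.csv", cond))
  readr::write_csv(res$curve$curve,
                   sprintf("results/trial_dynamics_%s_curve.csv", cond))
}
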