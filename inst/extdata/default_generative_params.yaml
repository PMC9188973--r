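# Default generative parameters for the synthetic cohort.
# Effect sizes are chosen so the default multiverse reproduces the qualitative
# pattern of interest: a detectable negative age slope for fear reactivity,
# within-scan habituation that is steeper at younger ages, condition-dependent
# seed-target amplitude coupling with a near-zero age slope, and head motion
# decreasing with age. BOLD units are arbitrary but consistent across stages.
baseline_amplitude:
  fear: 1.0
  neutral: 0.8
age_slope:              # units / year, age centered at 12
  fear: -0.05
  neutral: -0.02
habituation_slope: -0.015       # units per within-condition trial at age 12
habituation_age_slope: 0.0012   # per trial per year: steeper (more negative) when younger
trial_amp_sd: 0.5               # SD of trial-to-trial amplitude fluctuation
participant_amp_sd: 0.3         # SD of the stable participant amplitude shift
coupling_rho:                   # seed-target trial-amplitude correlation
  fear: 0.35
  neutral: 0.15
coupling_age_slope: 0.0         # change of coupling per year (default: none)
ar1_coef: 0.3
noise_sd: 1.0
drift_coefs: [0.0, 0.8, -0.5]   # polynomial drift amplitudes (const, linear, quad)
global_amp: 0.6                 # gain of the shared low-frequency component
motion_artifact_gain: 0.8       # BOLD units per mm of framewise displacement
motion_age_slope: -0.012        # mean-FD change per year (mm); negative = less motion when older
fd_base: 0.28                   # mean FD at age 12, mm
fd_between_sd: 0.08             # SD of the stable participant motion trait, mm
fd_within_sd: 0.08              # SD of the session-to-session motion level, mm
fd_spike_rate: 0.04             # per-volume probability of a large motion spike
roi_split_noise_sd: 0.4         # extra noise distinguishing L/R/atlas amygdala variants
target_share: 0.5               # shared fraction of mPFC target ROI noise
anxiety_age_slope: -0.35        # raw separation-anxiety points per year
anxiety_sd: 2.0
anxiety_item_missing_frac: 0.02
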