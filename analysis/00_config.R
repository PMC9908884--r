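# Shared settings for the analysis scripts (sourced by 01..07).
#
# Problem size: two synthetic cohorts of 16 calves monitored for 9 days
# (move-in day censored + two full 4-day periods), positions at one fix per
# 20 s. Counts are per 3-min window, so the reduced rate changes nothing
# structurally; it keeps each script in the seconds-to-minutes range.

library(calfnet)

SEED <- as.integer(Sys.getenv("CALFNET_SEED", "1"))
OUT <- file.path("results", "analysis")
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

CFG <- list(
  n_cohorts = 2, n_calves = 16, monitoring_days = 9,
  sample_hz = 0.05,                 # one fix per 20 s
  d_m = 1.0, window_s = 180, period_days = 4, smooth_window_s = 10,
  seen_frac = 0.5, prox_frac = 0.9, t0 = 86400,
  n_perm = 500,                     # stability + differentiation
  n_iter = 8000, burn_in = 2000, thin = 5
)
CFG$interval <- 1 / CFG$sample_hz
CFG$usable_days <- CFG$monitoring_days - CFG$t0 / 86400
CFG$cohort_ids <- sprintf("C%d", seq_len(CFG$n_cohorts))

# planted social structure: pair familiarity drives preferred partners;
# moderate step noise keeps preferred pairs within the 1 m threshold often
SOCIAL <- social_params(attraction_per_familiarity_day = 0.02,
                        step_length_sd_m = 0.3, persistence = 0.5,
                        dropout_prob = 0.05, visit_windows_per_day = 2)

cohort_dir <- function(id) file.path(OUT, id)
read_cohort <- function(id, file) utils::read.csv(file.path(OUT, id, file))
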