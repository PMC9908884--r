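#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic cohorts: pen trajectories with planted
# familiarity structure, step-down weaning, episodic respiratory illness,
# sensor dropout and daily human-visit windows.
source(file.path("analysis", "00_config.R"))

for (k in seq_len(CFG$n_cohorts)) {
  id <- CFG$cohort_ids[k]
  spec <- cohort_spec(cohort_id = id, n_calves = CFG$n_calves,
                      monitoring_days = CFG$monitoring_days,
                      sample_hz = CFG$sample_hz, seed = SEED + 100L * k)
  res <- write_synthetic_cohort(spec, SOCIAL, dir = cohort_dir(id),
                                seed = SEED + 100L * k)
  cat(sprintf(
    "%s: %d calves, %d raw fixes, %d health assessments (%d sick), %d visit events\n",
    id, CFG$n_calves, nrow(res$positions), nrow(res$health),
    sum(res$health$category == "sick"), nrow(res$events)))
}
cat("raw synthetic data written under", OUT, "\n")
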