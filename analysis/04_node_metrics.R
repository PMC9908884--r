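#!/usr/bin/env Rscript
# Stage 4 -- node-level sociality measures per animal-period: strength,
# total social time (3 min per associated window), eigenvector centrality,
# closeness (reciprocal-weight paths), and CV of association, joined with
# age, weaning stage and worst-in-period health category.
source(file.path("analysis", "00_config.R"))

all_nm <- list()
for (id in CFG$cohort_ids) {
  cnt <- read_cohort(id, "dyad_counts.csv")
  meta <- read_cohort(id, "cohort.csv")
  health <- read_cohort(id, "health.csv")
  mats <- build_matrices(cnt, animals = sort(meta$animal_id))
  nm <- node_metrics(mats, cnt, meta, health, period_days = CFG$period_days,
                     window_min = CFG$window_s / 60)
  utils::write.csv(nm, file.path(OUT, id, "node_metrics.csv"), row.names = FALSE)
  all_nm[[id]] <- nm
}
nm <- do.call(rbind, all_nm)
utils::write.csv(nm, file.path(OUT, "node_metrics.csv"), row.names = FALSE)
cat(sprintf("%d animal-period rows\n", nrow(nm)))
cat("per-metric summary (mean +/- sd):\n")
for (m in c("strength", "social_time_min", "eigenvector", "closeness",
            "cv_association"))
  cat(sprintf("  %-16s %8.3f +/- %.3f\n", m, mean(nm[[m]], na.rm = TRUE),
              sd(nm[[m]], na.rm = TRUE)))
print(table(stage = nm$weaning_stage, health = nm$health_category))
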