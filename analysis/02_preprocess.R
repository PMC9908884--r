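#!/usr/bin/env Rscript
# Stage 2 -- clean the raw fixes (drop the move-in day, censor human-visit
# intervals, remove out-of-pen coordinates) and smooth with a 10-s trailing
# moving average.
source(file.path("analysis", "00_config.R"))

for (id in CFG$cohort_ids) {
  pos <- read_cohort(id, "positions.csv")
  ev <- read_cohort(id, "events.csv")
  cl <- clean_positions(pos, pen = c(6, 10), events = ev,
                        first_day_s = c(0, CFG$t0))
  sm <- smooth_positions(cl$positions, window_s = CFG$smooth_window_s)
  utils::write.csv(cl$log, file.path(OUT, id, "censor_log.csv"), row.names = FALSE)
  utils::write.csv(sm, file.path(OUT, id, "positions_clean.csv"), row.names = FALSE)
  removed <- sum(cl$log$removed_fixes)
  cat(sprintf("%s: removed %d of %d fixes (%.2f%%):\n", id, removed, nrow(pos),
              100 * removed / nrow(pos)))
  print(cl$log, row.names = FALSE)
}
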