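#!/usr/bin/env Rscript
# Stage 7 -- node-level linear mixed models: each sociality measure on age,
# weaning stage and health category with calf and period-within-cohort
# random intercepts; BH correction across the five models per term.
source(file.path("analysis", "00_config.R"))

nm <- utils::read.csv(file.path(OUT, "node_metrics.csv"))
fit <- fit_node_lmms(nm)
print(fit)
for (m in unique(fit$coefficients$metric))
  utils::write.csv(fit$coefficients[fit$coefficients$metric == m, ],
                   file.path(OUT, sprintf("lmm_%s.csv", m)), row.names = FALSE)
utils::write.csv(fit$varcomp, file.path(OUT, "lmm_varcomp.csv"), row.names = FALSE)
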