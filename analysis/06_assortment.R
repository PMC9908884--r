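#!/usr/bin/env Rscript
# Stage 6 -- dyadic assortment: log association index regressed on age
# difference, health difference and familiarity, with cohort and
# multiple-membership node random effects (in-package Gibbs sampler).
source(file.path("analysis", "00_config.R"))

tabs <- list()
for (id in CFG$cohort_ids) {
  cnt <- read_cohort(id, "dyad_counts.csv")
  meta <- read_cohort(id, "cohort.csv")
  health <- read_cohort(id, "health.csv")
  fam_long <- read_cohort(id, "familiarity.csv")
  animals <- sort(meta$animal_id)
  fam <- matrix(0, length(animals), length(animals),
                dimnames = list(animals, animals))
  fam[cbind(fam_long$a, fam_long$b)] <- fam_long$familiarity_days
  fam[cbind(fam_long$b, fam_long$a)] <- fam_long$familiarity_days
  mats <- build_matrices(cnt, animals = animals)
  tabs[[id]] <- build_dyad_table(mats, meta, fam, health,
                                 period_days = CFG$period_days)
}
tab <- do.call(rbind, tabs)
cat(sprintf("%d dyad-period rows (zero-weight dyads dropped)\n", nrow(tab)))
fit <- fit_dyadic_assortment(tab, n_iter = CFG$n_iter, burn_in = CFG$burn_in,
                             thin = CFG$thin, seed = SEED + 7L)
print(fit)
utils::write.csv(fit$summary, file.path(OUT, "assortment_fit.csv"),
                 row.names = FALSE)
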