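# Shared fixtures: fast-mixing generator settings and hand-built tables.

# Movement parameters for permutation-null calibration: no planted structure,
# no feeder pull, and steps large enough that positions decorrelate between
# successive scan samples (the data-stream null assumes windows are
# exchangeable). Pair with one fix per 3-min window (interval 180 s).
null_social <- function(step = 3) {
  social_params(attraction_per_familiarity_day = 0,
                age_homophily_scale = 10,
                step_length_sd_m = step, persistence = 0,
                feeder_attraction = 0, dropout_prob = 0,
                visit_windows_per_day = 0)
}

# Strong planted preferences: paired calves with high familiarity sit within
# the 1 m threshold most of the time (small jitter around the partner).
planted_social <- function(attraction = 0.07, step = 0.35) {
  social_params(attraction_per_familiarity_day = attraction,
                age_homophily_scale = 1000,
                step_length_sd_m = step, persistence = 0,
                feeder_attraction = 0, dropout_prob = 0,
                visit_windows_per_day = 0)
}

# Small cohort on a coarse clock: `frac_day` days at one fix per
# `interval` seconds.
tiny_spec <- function(n = 6, frac_day = 0.1, interval = 30, seed = 1,
                      familiarity = NULL) {
  cohort_spec(cohort_id = "T", n_calves = n,
              entry_ages_days = rep(30L, n),
              familiarity_days = familiarity,
              monitoring_days = max(1, ceiling(frac_day)),
              sample_hz = 1 / interval, seed = seed)
}

# Paired familiarity matrix: consecutive animals share `days`, others 0.
paired_familiarity <- function(n, days = 51) {
  fam <- matrix(0L, n, n)
  for (p in seq_len(floor(n / 2))) {
    i <- 2 * p - 1; j <- 2 * p
    fam[i, j] <- fam[j, i] <- as.integer(days)
  }
  fam
}

# Trajectories truncated to a fraction of a day (keeps null replicates fast).
tiny_trajectories <- function(spec, social, seed, frac_day) {
  pos <- simulate_trajectories(spec, social, health = spec_no_health(), seed = seed)
  pos[pos$time_s < frac_day * 86400, ]
}

spec_no_health <- function() {
  data.frame(animal = character(0), day = integer(0), total = integer(0))
}

# Build a group_stream by hand from a list of windows, each a list of
# integer vectors.
manual_stream <- function(groups, animals) {
  structure(list(groups = groups, animals = animals,
                 n_windows = length(groups)),
            class = "group_stream")
}

# Deterministic fix table: one animal standing at (x, y) for given times.
standing <- function(id, times, x, y) {
  data.frame(time_s = times, animal_id = id, x_m = x, y_m = y,
             stringsAsFactors = FALSE)
}

# Dyadic rows simulated from the assortment model itself (for sampler
# calibration and recovery checks): log_edge = b0 + b1 age_diff +
# b2 health_diff + b3 familiarity + v_i + v_j + e, single cohort.
simulate_dyadic <- function(n_nodes = 12, n_periods = 6,
                            beta = c(-2, -0.005, 0, 0.02),
                            sd_node = 0.1, sd_e = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  ages <- sample(20:55, n_nodes, replace = TRUE)
  fam <- matrix(0L, n_nodes, n_nodes, dimnames = list(ids, ids))
  for (p in seq_len(n_nodes / 2)) {
    i <- 2 * p - 1; j <- 2 * p
    fam[i, j] <- fam[j, i] <- sample(10:51, 1)
  }
  v <- rnorm(n_nodes, 0, sd_node)
  ut <- which(upper.tri(fam), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(n_periods), function(p) {
    data.frame(cohort = "A", period = p,
               id_i = ids[ut[, 1]], id_j = ids[ut[, 2]],
               age_diff_days = abs(ages[ut[, 1]] - ages[ut[, 2]]),
               health_diff = sample(0:2, nrow(ut), replace = TRUE),
               familiarity_days = fam[ut])
  }))
  mu <- beta[1] + beta[2] * rows$age_diff_days + beta[3] * rows$health_diff +
    beta[4] * rows$familiarity_days +
    v[match(rows$id_i, ids)] + v[match(rows$id_j, ids)]
  rows$log_edge <- mu + rnorm(nrow(rows), 0, sd_e)
  rows
}

# Node-metric table with planted fixed effects on strength (coefficients at
# the per-day / per-category scale typical of calf sociality analyses) and
# calf/period random intercepts.
simulate_metrics <- function(n_cohorts = 2, n_calves = 12, n_periods = 8,
                             beta_age = -0.003, beta_sd = 0.072, beta_w = 0.071,
                             beta_mod = -0.007, beta_sick = -0.047,
                             sd_calf = 0.05, sd_period = 0.03, sd_e = 0.08,
                             seed = 1) {
  set.seed(seed)
  rows <- list()
  for (co in seq_len(n_cohorts)) {
    ids <- sprintf("c%d_%02d", co, seq_len(n_calves))
    ages0 <- sample(20:55, n_calves, replace = TRUE)
    u_calf <- rnorm(n_calves, 0, sd_calf)
    for (p in seq_len(n_periods)) {
      u_per <- rnorm(1, 0, sd_period)
      age <- ages0 + 4 * p
      stage <- as.character(weaning_stage(pmax(1, age - 14)))
      health <- sample(c("healthy", "moderate", "sick"), n_calves,
                       replace = TRUE, prob = c(0.7, 0.2, 0.1))
      mu <- 0.74 + beta_age * age + beta_sd * (stage == "step_down") +
        beta_w * (stage == "weaned") + beta_mod * (health == "moderate") +
        beta_sick * (health == "sick") + u_calf + u_per
      rows[[length(rows) + 1]] <- data.frame(
        cohort = paste0("C", co), period = p, animal = ids,
        strength = mu + rnorm(n_calves, 0, sd_e),
        social_time_min = 1377 + rnorm(n_calves, 0, 50),
        eigenvector = plogis(mu + rnorm(n_calves, 0, sd_e)),
        closeness = 0.6 + rnorm(n_calves, 0, 0.05),
        cv_association = 1.1 + rnorm(n_calves, 0, 0.1),
        age_days = age, weaning_stage = stage, health_category = health,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
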