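# Synthetic cohorts: weaning schedule, health scores, pen trajectories.

#' Daily milk allowance on the automatic feeder
#'
#' Step-down weaning schedule: 10 L/day for the first 35 feeder-days, then a
#' reduction of 400 ml/day from day 36 until the allowance reaches zero on
#' day 60.
#'
#' @param feeder_day Integer vector of feeder-days (>= 1): days since the calf
#'   first fed from the automatic feeder.
#' @return Numeric vector of daily allowances in litres.
#' @export
#' @examples
#' milk_allowance(c(35, 36, 60))
milk_allowance <- function(feeder_day) {
  if (!is.numeric(feeder_day) || any(is.na(feeder_day)) || any(feeder_day < 1))
    stop("feeder_day must be >= 1")
  ifelse(feeder_day <= 35, 10.0, pmax(0, 10.0 - 0.4 * (feeder_day - 35)))
}

#' Weaning stage implied by the milk schedule
#'
#' @param feeder_day Integer vector of feeder-days (>= 1).
#' @return Factor with levels `non_weaned < step_down < weaned`
#'   (full allowance, reduced-but-positive allowance, zero allowance).
#' @export
weaning_stage <- function(feeder_day) {
  a <- milk_allowance(feeder_day)
  stage <- ifelse(a >= 10, "non_weaned", ifelse(a > 0, "step_down", "weaned"))
  factor(stage, levels = c("non_weaned", "step_down", "weaned"), ordered = TRUE)
}

#' Cohort specification for the synthetic generator
#'
#' Describes one pen cohort: group size, pen geometry, ages at entry, the
#' symmetric pre-entry familiarity matrix (days of contact before the move
#' into the trial pen, 0-51), monitoring duration and positional sampling
#' rate. Defaults mirror a typical study cohort: 15-16 calves in a
#' 6 m x 10 m straw pen, entered at 2-8 weeks of age, tracked at 1 Hz.
#'
#' Calves are reared in pairs before entering the group pen, so the default
#' familiarity matrix pairs consecutive animals and gives each pair a shared
#' contact history of 14-51 days; all other dyads get 0.
#'
#' @param cohort_id Cohort label.
#' @param n_calves Number of calves (default 16).
#' @param pen_width_m,pen_length_m Pen rectangle in metres (default 6 x 10).
#' @param entry_ages_days Integer vector of ages (days) at pen entry; drawn
#'   from a clipped normal (mean 40, sd 8, range 14-60) when `NULL`.
#' @param familiarity_days Symmetric matrix of pre-entry contact days
#'   (zero diagonal, values 0-51); pair-structured default when `NULL`.
#' @param monitoring_days Days of monitoring (<= 76, default 76).
#' @param sample_hz Positional sampling rate in Hz; 1 for study conditions,
#'   reducible for fast experimentation (association counts are per 3-min
#'   window, not per fix, so the rate is a free parameter).
#' @param seed Integer seed used for the default covariate draws.
#' @return Object of class `cohort_spec` (a list).
#' @export
cohort_spec <- function(cohort_id = "C1", n_calves = 16,
                        pen_width_m = 6, pen_length_m = 10,
                        entry_ages_days = NULL, familiarity_days = NULL,
                        monitoring_days = 76, sample_hz = 1, seed = 1L) {
  stopifnot(n_calves >= 2, pen_width_m > 0, pen_length_m > 0,
            monitoring_days >= 1, monitoring_days <= 76, sample_hz > 0)
  animals <- sprintf("%s_%02d", cohort_id, seq_len(n_calves))
  if (is.null(entry_ages_days) || is.null(familiarity_days)) {
    rs <- local({ set.seed(seed); list(
      ages = pmin(60L, pmax(14L, as.integer(round(stats::rnorm(n_calves, 40, 8))))),
      pair_fam = sample(14:51, ceiling(n_calves / 2), replace = TRUE),
      ord = sample.int(n_calves)
    )})
    if (is.null(entry_ages_days)) entry_ages_days <- rs$ages
    if (is.null(familiarity_days)) {
      fam <- matrix(0L, n_calves, n_calves)
      for (p in seq_len(floor(n_calves / 2))) {
        i <- rs$ord[2 * p - 1]; j <- rs$ord[2 * p]
        fam[i, j] <- fam[j, i] <- rs$pair_fam[p]
      }
      familiarity_days <- fam
    }
  }
  familiarity_days <- as.matrix(familiarity_days)
  if (!isTRUE(all.equal(familiarity_days, t(familiarity_days))) ||
      any(diag(familiarity_days) != 0) ||
      any(familiarity_days < 0) || any(familiarity_days > 51))
    stop("familiarity_days must be symmetric, zero-diagonal, within [0, 51]")
  if (length(entry_ages_days) != n_calves)
    stop("entry_ages_days must have one value per calf")
  if (any(entry_ages_days < 14) || any(entry_ages_days > 60))
    stop("entry ages must lie in [14, 60] days")
  dimnames(familiarity_days) <- list(animals, animals)
  structure(list(
    cohort_id = cohort_id, n_calves = n_calves, animals = animals,
    pen_width_m = pen_width_m, pen_length_m = pen_length_m,
    entry_ages_days = as.integer(entry_ages_days),
    familiarity_days = familiarity_days,
    monitoring_days = monitoring_days, sample_hz = sample_hz,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Social/movement parameters for the trajectory generator
#'
#' Knobs of the planted social structure. Partner attraction between calves i
#' and j scales with `attraction_per_familiarity_day * familiarity_ij` damped
#' by `exp(-|age_i - age_j| / age_homophily_scale)`; sick days multiply a
#' calf's partner attraction by `sickness_sociality_multiplier` (< 1 lowers
#' sociality when ill), step-down/weaned days by
#' `weaning_sociality_multiplier` (>= 1 raises it once milk is reduced).
#' Non-weaned calves are additionally drawn toward the feeder zone in
#' proportion to their remaining milk allowance.
#'
#' @param attraction_per_familiarity_day Attraction gain per familiarity day.
#' @param age_homophily_scale e-folding scale (days) of the age-difference
#'   damping of partner attraction.
#' @param sickness_sociality_multiplier Multiplier in (0, 1] applied on days
#'   an animal is categorised sick.
#' @param weaning_sociality_multiplier Multiplier >= 1 applied on
#'   step-down/weaned days.
#' @param step_length_sd_m Per-fix random step standard deviation (m).
#' @param persistence Velocity autocorrelation of the correlated random walk,
#'   in [0, 1).
#' @param feeder_attraction Drift magnitude (m/fix) toward the feeder centre
#'   at full milk allowance.
#' @param feeder_zone Numeric `c(xmin, xmax, ymin, ymax)` of the feeder area
#'   (default 1.5 m x 3 m centred on one short wall).
#' @param dropout_prob Probability a scheduled fix is lost, in [0, 1).
#' @param visit_windows_per_day Number of daily 15-min human-visit windows
#'   during which no fixes are emitted (logged as censoring events).
#' @return Object of class `social_params` (a list).
#' @export
social_params <- function(attraction_per_familiarity_day = 0.02,
                          age_homophily_scale = 10,
                          sickness_sociality_multiplier = 0.5,
                          weaning_sociality_multiplier = 1.3,
                          step_length_sd_m = 0.3,
                          persistence = 0.5,
                          feeder_attraction = 0.05,
                          feeder_zone = c(2.25, 3.75, 0, 3),
                          dropout_prob = 0.05,
                          visit_windows_per_day = 2) {
  stopifnot(attraction_per_familiarity_day >= 0, age_homophily_scale > 0,
            sickness_sociality_multiplier > 0, sickness_sociality_multiplier <= 1,
            weaning_sociality_multiplier >= 1, step_length_sd_m > 0,
            persistence >= 0, persistence < 1, feeder_attraction >= 0,
            length(feeder_zone) == 4,
            dropout_prob >= 0, dropout_prob < 1, visit_windows_per_day >= 0)
  structure(as.list(environment()), class = "social_params")
}

score_components <- function(total) {
  # split a total 0-12 across (nasal, ear, eye, temperature), each capped at 3
  comp <- integer(4)
  for (k in seq_len(4)) {
    comp[k] <- min(3L, total)
    total <- total - comp[k]
  }
  comp
}

#' Simulate twice-weekly respiratory health scoring
#'
#' Emulates Wisconsin-style calf health scoring: each animal is assessed on
#' two fixed weekdays per week (days 1 and 4 of each 7-day block). Outside
#' illness episodes the total score is 0-2 (healthy); respiratory episodes
#' start with per-animal-day probability `episode_rate`, last
#' `episode_length_days`, and raise the total to >= 5 (sick) in their core
#' with moderate (3-4) shoulders on the first and last episode day.
#'
#' @param spec A [cohort_spec()].
#' @param episode_rate Per-animal-day probability an episode starts.
#' @param episode_length_days Episode duration in days (>= 1).
#' @param seed Integer seed.
#' @return data.frame with one row per animal-assessment: `animal`, `day`
#'   (study day, 1-based), component scores, `total` and `category`
#'   (healthy: total <= 2, moderate: 3-4, sick: >= 5).
#' @export
simulate_health <- function(spec, episode_rate = 0.02,
                            episode_length_days = 5, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"),
            episode_rate >= 0, episode_rate <= 1, episode_length_days >= 1)
  set.seed(seed)
  days <- seq_len(spec$monitoring_days)
  assess_days <- days[days %% 7 %in% c(1, 4)]
  out <- vector("list", spec$n_calves)
  for (a in seq_len(spec$n_calves)) {
    severity <- integer(spec$monitoring_days)       # latent daily total
    starts <- which(stats::runif(spec$monitoring_days) < episode_rate)
    for (s in starts) {
      span <- s:min(spec$monitoring_days, s + episode_length_days - 1)
      prof <- rep(6L, length(span))
      prof[1] <- 3L
      if (length(span) > 1) prof[length(span)] <- 4L
      if (length(span) > 2) prof[2:(length(span) - 1)] <-
        5L + (stats::runif(length(span) - 2) < 0.5)
      severity[span] <- pmax(severity[span], prof)
    }
    base <- sample(0:2, length(assess_days), replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
    total <- pmax(severity[assess_days], base)
    comp <- t(vapply(total, score_components, integer(4)))
    out[[a]] <- data.frame(
      animal = spec$animals[a], day = assess_days,
      nasal = comp[, 1], ear = comp[, 2], eye = comp[, 3],
      temperature = comp[, 4], total = total,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$category <- health_category(res$total)
  rownames(res) <- NULL
  res
}

#' Health category from a total Wisconsin-style score
#'
#' @param total Integer total score 0-12.
#' @return Factor `healthy < moderate < sick` (0-2 / 3-4 / >= 5).
#' @export
health_category <- function(total) {
  stopifnot(all(total >= 0), all(total <= 12))
  factor(ifelse(total <= 2, "healthy", ifelse(total <= 4, "moderate", "sick")),
         levels = c("healthy", "moderate", "sick"), ordered = TRUE)
}

#' Daily human-visit censoring windows
#'
#' @param spec A [cohort_spec()].
#' @param social A [social_params()].
#' @return data.frame of half-open intervals `start_s`, `end_s`, `reason`.
#' @export
visit_events <- function(spec, social = social_params()) {
  k <- social$visit_windows_per_day
  if (k == 0) return(data.frame(start_s = integer(0), end_s = integer(0),
                                reason = character(0)))
  # evenly spaced clock times within 08:00-17:00, 15 minutes each
  clock <- 8 * 3600 + (seq_len(k) - 1) * (9 * 3600 / k)
  starts <- as.vector(outer(clock, (seq_len(spec$monitoring_days) - 1) * 86400, "+"))
  data.frame(start_s = as.integer(sort(starts)),
             end_s = as.integer(sort(starts)) + 900L,
             reason = "human_visit", stringsAsFactors = FALSE)
}

daily_health_category <- function(spec, health) {
  # carry the most recent assessment forward; healthy before the first one
  cat_num <- matrix(0L, spec$monitoring_days, spec$n_calves,
                    dimnames = list(NULL, spec$animals))
  if (nrow(health) == 0) return(cat_num)
  for (a in seq_len(spec$n_calves)) {
    h <- health[health$animal == spec$animals[a], ]
    if (nrow(h) == 0) next
    h <- h[order(h$day), ]
    code_a <- as.integer(health_category(h$total)) - 1L
    idx <- findInterval(seq_len(spec$monitoring_days), h$day)
    cat_num[, a] <- ifelse(idx == 0, 0L, code_a[pmax(idx, 1L)])
  }
  cat_num
}

#' Simulate 1 Hz pen trajectories with planted social structure
#'
#' Bounded correlated random walk inside the pen rectangle. At each scheduled
#' fix the velocity of calf i is a persistence-weighted mix of its previous
#' velocity, pairwise attraction toward partners (weight increasing in
#' familiarity and decreasing in age difference, modulated by daily sickness
#' and weaning multipliers), attraction toward the feeder zone scaled by the
#' remaining milk allowance, and Gaussian noise; walls reflect. Scheduled
#' fixes are then dropped i.i.d. with `dropout_prob` and wholesale during the
#' generated human-visit windows.
#'
#' @param spec A [cohort_spec()].
#' @param social A [social_params()].
#' @param health Health table from [simulate_health()] (daily sickness is the
#'   most recent assessed category, carried forward); may have zero rows.
#' @param seed Integer seed (same seed and inputs give identical output).
#' @return data.frame `time_s`, `animal_id`, `x_m`, `y_m`; one row per
#'   retained fix, coordinates inside the pen.
#' @export
simulate_trajectories <- function(spec, social = social_params(),
                                  health = simulate_health(spec),
                                  seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(social, "social_params"))
  n <- spec$n_calves
  if (n < 1) stop("cohort has no animals")
  set.seed(seed)
  dt <- 1 / spec$sample_hz
  times <- seq(0, spec$monitoring_days * 86400 - dt, by = dt)
  n_t <- length(times)
  W <- spec$pen_width_m; L <- spec$pen_length_m

  age_diff <- abs(outer(spec$entry_ages_days, spec$entry_ages_days, "-"))
  base_attr <- social$attraction_per_familiarity_day * spec$familiarity_days *
    exp(-age_diff / social$age_homophily_scale)
  diag(base_attr) <- 0

  sick_daily <- daily_health_category(spec, health) >= 2L   # sick days
  feeder_mid <- c(mean(social$feeder_zone[1:2]), mean(social$feeder_zone[3:4]))

  pos <- cbind(stats::runif(n, 0, W), stats::runif(n, 0, L))
  vel <- matrix(0, n, 2)
  xs <- matrix(NA_real_, n_t, n)
  ys <- matrix(NA_real_, n_t, n)

  day_of <- pmin(spec$monitoring_days, floor(times / 86400) + 1L)
  day_breaks <- c(which(diff(day_of) != 0), n_t)
  # per-day per-animal multipliers and feeder pull, updated at day boundaries
  upd_day <- function(day) {
    feeder_day <- pmax(1L, spec$entry_ages_days - 14L + day)
    allow <- milk_allowance(feeder_day)
    mult <- ifelse(allow < 10, social$weaning_sociality_multiplier, 1) *
      ifelse(sick_daily[day, ], social$sickness_sociality_multiplier, 1)
    list(attr = base_attr * outer(mult, mult), feeder_pull = allow / 10)
  }
  dstate <- upd_day(1L)
  cur_day <- 1L
  sdm <- social$step_length_sd_m
  for (t in seq_len(n_t)) {
    if (day_of[t] != cur_day) { cur_day <- day_of[t]; dstate <- upd_day(cur_day) }
    dx <- outer(pos[, 1], pos[, 1], function(a, b) b - a)
    dy <- outer(pos[, 2], pos[, 2], function(a, b) b - a)
    d <- sqrt(dx^2 + dy^2)
    # saturating attraction, vanishing at contact and capped at half the
    # current separation so two mutually pulled calves meet rather than
    # overshoot or swap positions
    mag <- pmin(dstate$attr * (1 - exp(-d / 0.5)), d / 2)
    coef <- mag / pmax(d, 1e-9)
    drift <- cbind(rowSums(coef * dx), rowSums(coef * dy))
    fvec <- cbind(feeder_mid[1] - pos[, 1], feeder_mid[2] - pos[, 2])
    fnorm <- sqrt(rowSums(fvec^2))
    drift <- drift + social$feeder_attraction * dstate$feeder_pull *
      fvec / pmax(fnorm, 1e-9)
    vel <- social$persistence * vel + drift +
      matrix(stats::rnorm(2 * n, 0, sdm), n, 2)
    pos <- pos + vel
    # reflect off the walls
    for (k in 1:2) {
      hi <- if (k == 1) W else L
      below <- pos[, k] < 0; above <- pos[, k] > hi
      pos[below, k] <- -pos[below, k]
      pos[above, k] <- 2 * hi - pos[above, k]
      pos[, k] <- pmin(hi, pmax(0, pos[, k]))   # guard huge excursions
      vel[below | above, k] <- -vel[below | above, k]
    }
    xs[t, ] <- pos[, 1]; ys[t, ] <- pos[, 2]
  }

  keep <- matrix(stats::runif(n_t * n) >= social$dropout_prob, n_t, n)
  ev <- visit_events(spec, social)
  if (nrow(ev) > 0) {
    in_visit <- rep(FALSE, n_t)
    for (r in seq_len(nrow(ev)))
      in_visit <- in_visit | (times >= ev$start_s[r] & times < ev$end_s[r])
    keep[in_visit, ] <- FALSE
  }
  idx <- which(keep)
  ti <- ((idx - 1) %% n_t) + 1
  ai <- ((idx - 1) %/% n_t) + 1
  out <- data.frame(time_s = times[ti], animal_id = spec$animals[ai],
                    x_m = xs[idx], y_m = ys[idx], stringsAsFactors = FALSE)
  out <- out[order(out$animal_id, out$time_s), ]
  rownames(out) <- NULL
  out
}

#' Write one synthetic cohort to disk
#'
#' Emits the raw-data file set a real deployment would produce:
#' `positions.csv`, `cohort.csv`, `familiarity.csv` (long dyad format),
#' `health.csv` and `events.csv`.
#'
#' @param spec,social,seed As in [simulate_trajectories()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated tables.
#' @export
write_synthetic_cohort <- function(spec, social = social_params(),
                                   dir, seed = spec$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  health <- simulate_health(spec, seed = seed + 1L)
  pos <- simulate_trajectories(spec, social, health, seed = seed)
  ev <- visit_events(spec, social)
  meta <- data.frame(animal_id = spec$animals, cohort = spec$cohort_id,
                     entry_age_days = spec$entry_ages_days,
                     stringsAsFactors = FALSE)
  fam <- spec$familiarity_days
  ut <- which(upper.tri(fam), arr.ind = TRUE)
  fam_long <- data.frame(a = rownames(fam)[ut[, 1]], b = colnames(fam)[ut[, 2]],
                         familiarity_days = fam[ut], stringsAsFactors = FALSE)
  utils::write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(fam_long, file.path(dir, "familiarity.csv"), row.names = FALSE)
  utils::write.csv(health, file.path(dir, "health.csv"), row.names = FALSE)
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(list(positions = pos, cohort = meta, familiarity = fam_long,
                 health = health, events = ev))
}
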