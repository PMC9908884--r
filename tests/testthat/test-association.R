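test_that("window_state applies the seen and proximity rules", {
  tt <- 0:179
  expect_equal(window_state(tt, rep(1, 180), rep(1, 180),
                            tt, rep(1.5, 180), rep(1, 180), 180), "both_close")
  expect_equal(window_state(tt, rep(1, 180), rep(1, 180),
                            tt, rep(3, 180), rep(1, 180), 180), "both_far")
  expect_equal(window_state(tt, rep(1, 180), rep(1, 180),
                            integer(0), numeric(0), numeric(0), 180), "only_A")
  expect_equal(window_state(integer(0), numeric(0), numeric(0),
                            tt, rep(1, 180), rep(1, 180), 180), "only_B")
  expect_equal(window_state(integer(0), numeric(0), numeric(0),
                            integer(0), numeric(0), numeric(0), 180), "neither")
  # 85% of co-fixes close is below the 90% default
  xb <- c(rep(1.5, 85), rep(5, 15))
  expect_equal(window_state(0:99, rep(1, 100), rep(1, 100),
                            0:99, xb, rep(1, 100), 100), "both_far")
})

test_that("accumulate_counts matches a planted state schedule", {
  # 10 windows of 180 s at 60-s sampling (3 fixes/window, seen needs >= 2):
  # 3 close, 2 far, 2 only_A, 1 only_B, 2 neither
  states <- c("c", "c", "c", "f", "f", "a", "a", "b", "n", "n")
  rows <- list()
  for (w in seq_along(states)) {
    tt <- (w - 1) * 180 + c(0, 60, 120)
    st <- states[w]
    if (st %in% c("c", "f", "a"))
      rows[[length(rows) + 1]] <- standing("A", tt, 1, 1)
    if (st %in% c("c", "f", "b"))
      rows[[length(rows) + 1]] <- standing("B", tt, if (st == "c") 1.5 else 4, 1)
  }
  pos <- do.call(rbind, rows)
  cnt <- accumulate_counts(pos, animals = c("A", "B"),
                           monitoring_days = 1800 / 86400,
                           sample_interval_s = 60, period_days = 1800 / 86400)
  expect_equal(cnt$X, 3)
  expect_equal(cnt$Y_AB, 2)
  expect_equal(cnt$Y_A, 2)
  expect_equal(cnt$Y_B, 1)
  expect_equal(cnt$N_windows, 10)
})

test_that("association index and SE match their closed forms", {
  expect_equal(as.numeric(association_index(10, 5, 3, 2)), 0.5)
  expect_equal(as.numeric(association_index(0, 7, 1, 2)), 0)
  expect_equal(as.numeric(association_index(1440, 0, 0, 0)), 1)
  z <- association_index(0, 0, 0, 0)
  expect_equal(as.numeric(z), 0)
  expect_false(attr(z, "defined"))
  expect_error(association_index(-1, 0, 0, 0))

  expect_equal(index_standard_error(0.5, 25), 0.5 * sqrt(0.02))
  expect_equal(index_standard_error(0.5, 25), 0.070711, tolerance = 1e-5)
  expect_equal(index_standard_error(1, 10), 0)
  expect_equal(index_standard_error(0, 10), 0)
  expect_true(is.na(index_standard_error(0.5, 0)))
})

test_that("association index is monotone in X at fixed denominator", {
  w <- vapply(0:90, function(x)
    as.numeric(association_index(x, 90 - x, 5, 5)), numeric(1))
  expect_true(all(diff(w) > 0))
  expect_true(all(w >= 0 & w <= 1))
})

test_that("build_matrix is symmetric, zero-diagonal and complete", {
  cnt <- data.frame(period = 1,
                    a = c("a1", "a1", "a2"), b = c("a2", "a3", "a3"),
                    X = 1, Y_AB = 1, Y_A = 0, Y_B = 0, N_windows = 10)
  E <- build_matrix(cnt)
  expect_equal(dim(E), c(3, 3))
  expect_true(all(E[upper.tri(E)] == 0.5))
  expect_equal(E, t(E))
  expect_equal(diag(E), c(a1 = 0, a2 = 0, a3 = 0))
  expect_error(build_matrix(cnt[-1, ]), "every dyad")

  n <- 16
  ids <- sprintf("x%02d", 1:n)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  expect_equal(nrow(ut), n * (n - 1) / 2)   # 120 dyads for 16 animals
  cnt16 <- data.frame(period = 1, a = ids[ut[, 1]], b = ids[ut[, 2]],
                      X = seq_len(120), Y_AB = 3, Y_A = 1, Y_B = 2,
                      N_windows = 200)
  E16 <- build_matrix(cnt16)
  expect_equal(dim(E16), c(16, 16))
  expect_equal(E16, t(E16))
  expect_equal(E16["x01", "x02"], 1 / (1 + 3 + 1 + 2))
})

test_that("window tallies conserve totals against a brute-force oracle", {
  sp <- tiny_spec(n = 5, interval = 30, seed = 21,
                  familiarity = paired_familiarity(5, 40))
  pos <- tiny_trajectories(sp, planted_social(0.03), seed = 22, frac_day = 0.1)
  interval <- 30; win_s <- 180; pdays <- 0.1
  cnt <- accumulate_counts(pos, animals = sp$animals,
                           monitoring_days = pdays, sample_interval_s = interval,
                           period_days = pdays, window_s = win_s)
  # oracle: classify every dyad-window independently with window_state
  n_win <- floor(pdays * 86400 / win_s)
  tally <- 0
  oracle <- cnt; oracle[c("X", "Y_AB", "Y_A", "Y_B")] <- 0
  for (r in seq_len(nrow(cnt))) {
    pa <- pos[pos$animal_id == cnt$a[r], ]
    pb <- pos[pos$animal_id == cnt$b[r], ]
    for (w in seq_len(n_win)) {
      lo <- (w - 1) * win_s; hi <- w * win_s
      ia <- pa$time_s >= lo & pa$time_s < hi
      ib <- pb$time_s >= lo & pb$time_s < hi
      st <- window_state(pa$time_s[ia], pa$x_m[ia], pa$y_m[ia],
                         pb$time_s[ib], pb$x_m[ib], pb$y_m[ib],
                         expected_fixes = win_s / interval)
      col <- switch(st, both_close = "X", both_far = "Y_AB",
                    only_A = "Y_A", only_B = "Y_B", NULL)
      if (!is.null(col)) oracle[r, col] <- oracle[r, col] + 1
      if (st == "both_close") tally <- tally + 1
    }
  }
  expect_equal(cnt$X, oracle$X)
  expect_equal(cnt$Y_AB, oracle$Y_AB)
  expect_equal(cnt$Y_A, oracle$Y_A)
  expect_equal(cnt$Y_B, oracle$Y_B)
  expect_equal(sum(cnt$X), tally)
  # cross-module conservation: social time = 3 * sum of X per animal
  st_min <- social_time(cnt)
  for (an in sp$animals)
    expect_equal(st_min[[an]], 3 * sum(cnt$X[cnt$a == an | cnt$b == an]))
})

test_that("edge weights are rank-stable across the threshold grid", {
  # graded familiarity so dyads have genuinely different association levels
  fam <- matrix(0L, 8, 8)
  for (p in 1:4) {
    i <- 2 * p - 1; j <- 2 * p
    fam[i, j] <- fam[j, i] <- c(15L, 27L, 39L, 51L)[p]
  }
  sp <- tiny_spec(n = 8, interval = 60, seed = 31, familiarity = fam)
  pos <- tiny_trajectories(sp, planted_social(0.012, step = 0.35),
                           seed = 32, frac_day = 0.2)
  grid_weights <- function(d_m, win_s) {
    cnt <- accumulate_counts(pos, animals = sp$animals,
                             monitoring_days = 0.2, sample_interval_s = 60,
                             period_days = 0.2, window_s = win_s, d_m = d_m)
    as.numeric(association_index(cnt$X, cnt$Y_AB, cnt$Y_A, cnt$Y_B))
  }
  ref <- grid_weights(1.0, 180)
  for (d in c(0.8, 1.2))
    expect_gt(cor(ref, grid_weights(d, 180), method = "spearman"), 0.8)
  for (w in c(120, 240))
    expect_gt(cor(ref, grid_weights(1.0, w), method = "spearman"), 0.8)
})
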