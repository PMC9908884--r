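rand_assoc <- function(n, seed) {
  set.seed(seed)
  R <- matrix(runif(n * n), n, n)
  R <- (R + t(R)) / 2
  diag(R) <- 0
  dimnames(R) <- list(paste0("n", 1:n), paste0("n", 1:n))
  R
}

test_that("mantel_qap recovers perfect and affine correlation", {
  E1 <- rand_assoc(8, 1)
  mt <- mantel_qap(E1, E1, n_perm = 200, seed = 3)
  expect_equal(mt$statistic_observed, 1)
  expect_lt(mt$p_value, 0.05)
  mt2 <- mantel_qap(E1, 0.2 + 0.5 * E1, n_perm = 50, seed = 3)
  expect_equal(mt2$statistic_observed, 1)
  expect_error(mantel_qap(E1, rand_assoc(7, 2)), "node set")
  expect_identical(mantel_qap(E1, rand_assoc(8, 5), 100, seed = 9)$null_values,
                   mantel_qap(E1, rand_assoc(8, 5), 100, seed = 9)$null_values)
})

test_that("QAP p agrees with exhaustive enumeration on 4 nodes", {
  E1 <- rand_assoc(4, 11)
  E2 <- rand_assoc(4, 12)
  ut <- upper.tri(E1)
  r_obs <- cor(E1[ut], E2[ut])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  r_null <- apply(perms, 1, function(p) cor(E1[ut], E2[p, p][ut]))
  p_exact <- mean(r_null >= r_obs)
  n_perm <- 4000
  mt <- mantel_qap(E1, E2, n_perm = n_perm, seed = 13)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(mt$p_value - p_exact), 2 * se + 2 / n_perm)
})

test_that("mantel r matches vegan's implementation", {
  skip_if_not_installed("vegan")
  E1 <- rand_assoc(9, 21); E2 <- rand_assoc(9, 22)
  mt <- mantel_qap(E1, E2, n_perm = 50, seed = 1)
  vg <- vegan::mantel(as.dist(E1), as.dist(E2), permutations = 50)
  expect_equal(mt$statistic_observed, unname(vg$statistic), tolerance = 1e-12)
})

test_that("QAP null is calibrated on exchangeable matrices", {
  set.seed(77)
  n_rep <- 120
  rej <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    E1 <- rand_assoc(8, 1000 + k)
    E2 <- rand_assoc(8, 2000 + k)
    rej[k] <- mantel_qap(E1, E2, n_perm = 200, seed = 3000 + k)$p_value <= 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(mean(rej), 0.05 + 3 * se)
})

test_that("stability summary covers all period pairs", {
  mats <- list("1" = rand_assoc(6, 1), "2" = rand_assoc(6, 2),
               "3" = rand_assoc(6, 3))
  st <- stability_summary(mats, n_perm = 100, seed = 5)
  expect_equal(nrow(st$table), 3)          # C(3,2)
  expect_equal(sort(st$table$lag), c(1, 1, 2))
  ident <- list("1" = rand_assoc(6, 9), "2" = rand_assoc(6, 9),
                "3" = rand_assoc(6, 9))
  st2 <- stability_summary(ident, n_perm = 200, seed = 6)
  expect_equal(st2$share_significant_pct, 100)
  expect_equal(st2$mean_r_significant, 1)
  expect_equal(nrow(stability_summary(mats["1"], 10)$table), 0)
})

test_that("data-stream swaps preserve all marginals exactly", {
  sp <- tiny_spec(n = 6, interval = 180, seed = 51,
                  familiarity = paired_familiarity(6, 40))
  pos <- tiny_trajectories(sp, planted_social(), seed = 52, frac_day = 0.2)
  gs <- window_group_stream(pos, animals = sp$animals, monitoring_days = 0.2,
                            sample_interval_s = 180, period_days = 0.2)
  before <- calfnet:::stream_marginals(gs)
  perm <- datastream_permute(gs, n_swaps = 500, seed = 53)
  after <- calfnet:::stream_marginals(perm)
  expect_equal(after$seen_count, before$seen_count)
  expect_equal(after$group_sizes, before$group_sizes)
  expect_false(identical(gs$groups, perm$groups))
  # nothing to swap with a single animal per window
  solo <- manual_stream(rep(list(list(1L)), 4), "A")
  expect_warning(out <- datastream_permute(solo, 10, 1), "no window")
  expect_identical(out$groups, solo$groups)
})

test_that("swap chain is uniform over assignments on a toy stream", {
  # 3 animals, 4 windows, each window split {2,1}: 3 partitions per window
  groups0 <- rep(list(list(c(1L, 2L), 3L)), 4)
  gs <- manual_stream(groups0, c("A", "B", "C"))
  # exhaustive null: X_AB ~ Binomial(4, 1/3) under uniform partitions
  set.seed(61)
  n_samp <- 4000
  x_ab <- integer(n_samp)
  g <- gs
  for (k in seq_len(n_samp)) {
    g <- datastream_permute(g, n_swaps = 12, seed = 600 + k)
    x_ab[k] <- calfnet:::stream_counts(g)$X["A", "B"]
  }
  emp <- tabulate(x_ab + 1, 5) / n_samp
  exact <- dbinom(0:4, 4, 1 / 3)
  se <- sqrt(exact * (1 - exact) / n_samp)
  expect_true(all(abs(emp - exact) < 4 * se + 0.01))
})

test_that("social differentiation test is degenerate-safe and reproducible", {
  sp <- tiny_spec(n = 6, interval = 180, seed = 71,
                  familiarity = paired_familiarity(6, 45))
  pos <- tiny_trajectories(sp, planted_social(), seed = 72, frac_day = 0.2)
  gs <- window_group_stream(pos, animals = sp$animals, monitoring_days = 0.2,
                            sample_interval_s = 180, period_days = 0.2)
  d1 <- social_differentiation_test(gs, n_perm = 100, seed = 5)
  d2 <- social_differentiation_test(gs, n_perm = 100, seed = 5)
  expect_identical(d1$null_values, d2$null_values)
  expect_true(d1$p_value > 0 && d1$p_value <= 1)
  expect_equal(d1$p_value,
               (1 + sum(d1$null_values >= d1$statistic_observed)) / 101)
  # strongly planted preferences should be detected even in a short stream
  expect_lte(d1$p_value, 0.05)
  # binomial null agrees qualitatively
  db <- social_differentiation_test(gs, n_perm = 200, seed = 6, null = "binomial")
  expect_lte(db$p_value, 0.05)
})
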