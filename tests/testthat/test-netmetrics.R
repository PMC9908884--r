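mat3 <- function(w = 0.5) {
  E <- matrix(w, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(E) <- 0
  E
}

test_that("strength is the row sum of association indices", {
  E <- mat3(0.5)
  expect_equal(unname(node_strength(E)), rep(1, 3))
  E["a", "b"] <- E["b", "a"] <- 0; E["a", "c"] <- E["c", "a"] <- 0
  expect_equal(node_strength(E, "a"), 0)
  set.seed(1)
  R <- matrix(runif(25), 5, 5); R <- (R + t(R)) / 2; diag(R) <- 0
  dimnames(R) <- list(paste0("n", 1:5), paste0("n", 1:5))
  brute <- vapply(1:5, function(i) sum(R[i, ]), numeric(1))
  expect_equal(unname(node_strength(R)), brute)
  expect_error(node_strength(R, "zz"), "unknown node")
  # adding a positive edge never decreases strength
  R2 <- R; R2[1, 2] <- R2[2, 1] <- R[1, 2] + 0.3
  expect_true(all(node_strength(R2) >= node_strength(R)))
})

test_that("social time is 3 minutes per associated window", {
  cnt <- data.frame(period = 1, a = c("a", "a", "b"), b = c("b", "c", "c"),
                    X = c(60, 40, 0), Y_AB = 1, Y_A = 1, Y_B = 1,
                    N_windows = 100)
  st <- social_time(cnt)
  expect_equal(st[["a"]], 3 * 100)
  expect_equal(st[["b"]], 3 * 60)
  expect_equal(st[["c"]], 3 * 40)
  cnt$X <- 0
  expect_equal(unname(social_time(cnt)), c(0, 0, 0))
})

test_that("eigenvector centrality matches closed forms and the definition", {
  expect_equal(unname(eigenvector_centrality(mat3(0.7))), rep(1, 3))
  # path a-b-c with equal weights: centre/leaf ratio is sqrt(2)
  P <- mat3(0); P["a", "b"] <- P["b", "a"] <- 0.4; P["b", "c"] <- P["c", "b"] <- 0.4
  v <- eigenvector_centrality(P)
  expect_equal(v[["b"]] / v[["a"]], sqrt(2), tolerance = 1e-10)
  expect_equal(v[["a"]], v[["c"]], tolerance = 1e-10)
  # definitional residual: E v = lambda v
  set.seed(2)
  R <- matrix(runif(36), 6, 6); R <- (R + t(R)) / 2; diag(R) <- 0
  dimnames(R) <- list(paste0("n", 1:6), paste0("n", 1:6))
  v <- eigenvector_centrality(R)
  lam <- max(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(R %*% v - lam * v)), 1e-10)
  # scale invariance and agreement with igraph's implementation
  expect_equal(eigenvector_centrality(3.7 * R), v)
  g <- igraph::graph_from_adjacency_matrix(R, "undirected", weighted = TRUE)
  vi <- igraph::eigen_centrality(g)$vector
  expect_equal(unname(v), unname(vi[rownames(R)]), tolerance = 1e-8)
  z <- eigenvector_centrality(mat3(0))
  expect_equal(as.numeric(z), rep(0, 3))
  expect_equal(attr(z, "flag"), "empty_network")
  expect_error(eigenvector_centrality(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("closeness uses reciprocal-weight paths with component scaling", {
  E2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(closeness_centrality(E2)), c(0.5, 0.5))  # 1 / (1/0.5)
  K <- mat3(1)
  expect_equal(unname(closeness_centrality(K)), rep(1, 3))     # all distances 1
  # 4 nodes, one isolate
  E4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  E4["a", "b"] <- E4["b", "a"] <- 0.5
  E4["b", "c"] <- E4["c", "b"] <- 0.5
  cl <- closeness_centrality(E4)
  expect_equal(cl[["d"]], 0)
  # a reaches b (d=2) and c (d=4): (2/3) * (2/6)
  expect_equal(cl[["a"]], (2 / 3) * (2 / 6))
})

test_that("node CV measures bond heterogeneity", {
  E <- mat3(0.5)
  expect_equal(unname(node_cv(E)), rep(0, 3))
  E2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  E2["a", "b"] <- E2["b", "a"] <- 0.2
  E2["a", "c"] <- E2["c", "a"] <- 0.4
  expect_equal(node_cv(E2, "a"), sd(c(0.2, 0.4)) / 0.3)
  expect_equal(node_cv(E2, "a"), 0.471405, tolerance = 1e-5)
  expect_equal(node_cv(5 * E2, "a"), node_cv(E2, "a"))   # scale invariant
  # fewer than 2 usable edges -> NA
  D <- attr(E2, "defined")
  E3 <- E2
  attr(E3, "defined") <- matrix(c(FALSE, TRUE, FALSE,
                                  TRUE, FALSE, FALSE,
                                  FALSE, FALSE, FALSE), 3, 3)
  expect_true(is.na(node_cv(E3, 1)))
})

test_that("node_metrics assembles measures with covariates", {
  sp <- tiny_spec(n = 4, interval = 30, seed = 41,
                  familiarity = paired_familiarity(4, 30))
  pos <- tiny_trajectories(sp, planted_social(0.03), seed = 42, frac_day = 0.2)
  cnt <- accumulate_counts(pos, animals = sp$animals, monitoring_days = 0.2,
                           sample_interval_s = 30, period_days = 0.1)
  mats <- build_matrices(cnt)
  meta <- data.frame(animal_id = sp$animals, cohort = "T",
                     entry_age_days = sp$entry_ages_days)
  health <- data.frame(animal = sp$animals[1], day = 1, total = 6)
  nm <- node_metrics(mats, cnt, meta, health, period_days = 0.1)
  expect_equal(nrow(nm), 4 * 2)
  expect_equal(nm$strength[nm$period == 1 & nm$animal == sp$animals[1]],
               unname(node_strength(mats[["1"]])[1]))
  expect_equal(nm$social_time_min,
               3 * vapply(seq_len(nrow(nm)), function(r) {
                 cc <- cnt[cnt$period == nm$period[r], ]
                 sum(cc$X[cc$a == nm$animal[r] | cc$b == nm$animal[r]])
               }, numeric(1)))
  expect_equal(unique(nm$health_category[nm$animal == sp$animals[1]]), "sick")
  expect_true(all(nm$health_category[nm$animal != sp$animals[1]] == "healthy"))
  expect_true(all(nm$weaning_stage == "non_weaned"))  # age 30 => feeder day ~16
})
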