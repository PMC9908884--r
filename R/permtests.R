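# Permutation inference: network stability (Mantel/QAP) and social
# differentiation (data-stream permutation of within-window groups).

perm_result <- function(statistic_observed, null_values, n_perm, seed,
                        alternative = "greater") {
  b <- if (alternative == "two.sided")
    sum(abs(null_values) >= abs(statistic_observed))
  else sum(null_values >= statistic_observed)
  structure(list(statistic_observed = statistic_observed,
                 null_values = null_values,
                 p_value = (1 + b) / (1 + length(null_values)),
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "perm_result")
}

#' @method print perm_result
#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4f, p = %.4g (%s, n_perm = %d)\n",
              x$statistic_observed, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Mantel correlation between two association matrices with a QAP null
#'
#' Pearson correlation of the upper-triangle entries of two matrices on the
#' same node set. The null applies a random node-label permutation jointly
#' to the rows and columns of the second matrix and recomputes the
#' correlation (quadratic assignment procedure).
#'
#' @param E1,E2 Symmetric matrices with identical node sets and ordering.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (default, p = proportion of null r >=
#'   observed, add-one corrected) or `"two.sided"`.
#' @return A `perm_result` with elements `statistic_observed` (r),
#'   `p_value`, `null_values`, `n_perm`, `seed`.
#' @export
mantel_qap <- function(E1, E2, n_perm = 10000, seed = 1L,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- nrow(E1)
  if (!all(dim(E1) == dim(E2)) ||
      !identical(rownames(E1), rownames(E2)))
    stop("matrices must share the same node set and ordering")
  if (n < 3) stop("need at least 3 nodes")
  ut <- upper.tri(E1)
  v1 <- E1[ut]
  if (stats::sd(v1) == 0 || stats::sd(E2[ut]) == 0)
    stop("degenerate matrix: zero variance in the upper triangle")
  r_obs <- stats::cor(v1, E2[ut])
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    stats::cor(v1, E2[p, p][ut])
  }, numeric(1))
  perm_result(r_obs, null, n_perm, seed, alternative)
}

#' Pairwise network stability across periods
#'
#' Mantel/QAP tests for every unordered pair of period matrices of one
#' cohort, plus the summary the stability analysis reports: the share of
#' significant correlations, the mean and sd of the significant r values,
#' and the same grouped by period lag.
#'
#' @param matrices Named list of per-period association matrices.
#' @param n_perm,seed Passed to [mantel_qap()]; pair `(i, j)` uses
#'   `seed + 7919 * i + j` so tests are independent and reproducible.
#' @param alpha Significance level (default 0.05).
#' @return List: `table` (period_i, period_j, lag, r, p, significant),
#'   `share_significant_pct`, `mean_r_significant`, `sd_r_significant`,
#'   `by_lag` (per-lag mean/sd of significant r).
#' @export
stability_summary <- function(matrices, n_perm = 10000, alpha = 0.05, seed = 1L) {
  periods <- as.integer(names(matrices))
  np <- length(periods)
  if (np < 2)
    return(list(table = data.frame(), share_significant_pct = NA_real_,
                mean_r_significant = NA_real_, sd_r_significant = NA_real_,
                by_lag = data.frame()))
  rows <- list()
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    mt <- mantel_qap(matrices[[i]], matrices[[j]], n_perm = n_perm,
                     seed = seed + 7919L * i + j)
    rows[[length(rows) + 1]] <- data.frame(
      period_i = periods[i], period_j = periods[j],
      lag = abs(periods[j] - periods[i]),
      r = mt$statistic_observed, p = mt$p_value,
      significant = mt$p_value <= alpha)
  }
  tab <- do.call(rbind, rows)
  sig <- tab$r[tab$significant]
  by_lag <- do.call(rbind, lapply(split(tab, tab$lag), function(d) data.frame(
    lag = d$lag[1], n_pairs = nrow(d), n_significant = sum(d$significant),
    mean_r_significant = if (any(d$significant)) mean(d$r[d$significant]) else NA_real_)))
  rownames(by_lag) <- NULL
  list(table = tab,
       share_significant_pct = 100 * mean(tab$significant),
       mean_r_significant = if (length(sig)) mean(sig) else NA_real_,
       sd_r_significant = if (length(sig) > 1) stats::sd(sig) else NA_real_,
       by_lag = by_lag)
}

# ---- within-window proximity groups and the data-stream null ----

#' Within-window proximity-group stream for one period
#'
#' For every 3-min window of one period: the set of animals seen, partitioned
#' into proximity groups (connected components of the graph joining pairs in
#' proximity, per [window_state()] rules; seen singletons are their own
#' group). This is the sampling-unit representation the data-stream
#' permutation operates on.
#'
#' @inheritParams accumulate_counts
#' @param period Which period of the grid to extract (default 1).
#' @return Object of class `group_stream`: list with `groups` (per window, a
#'   list of integer vectors of animal indices), `animals`, `n_windows`.
#' @export
window_group_stream <- function(positions, animals = sort(unique(positions$animal_id)),
                                period = 1, monitoring_days = NULL,
                                sample_interval_s = 1, period_days = 4,
                                window_s = 180, d_m = 1.0, seen_frac = 0.5,
                                prox_frac = 0.9, t0 = 0) {
  positions <- positions[positions$time_s >= t0, , drop = FALSE]
  positions$time_s <- positions$time_s - t0
  if (is.null(monitoring_days))
    monitoring_days <- ceiling((max(positions$time_s) + sample_interval_s) / 86400)
  grid <- window_grid(monitoring_days, period_days, window_s)
  if (period > grid$n_periods) stop("period beyond the monitoring span")
  fix_per_win <- window_s / sample_interval_s
  lo_s <- (period - 1) * grid$period_s
  sel <- positions$time_s >= lo_s & positions$time_s < period * grid$period_s
  positions <- positions[sel, , drop = FALSE]
  positions$time_s <- positions$time_s - lo_s
  n_t <- as.integer(grid$windows_per_period * fix_per_win)
  pa <- pos_array(positions, animals, sample_interval_s, n_t)
  win <- rep(seq_len(grid$windows_per_period), each = fix_per_win)
  seen <- rowsum((!is.na(pa$X)) + 0, win) / fix_per_win >= seen_frac
  n <- length(animals)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  close_pair <- matrix(FALSE, grid$windows_per_period, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    both <- !is.na(pa$X[, i]) & !is.na(pa$X[, j])
    dclose <- both & (pa$X[, i] - pa$X[, j])^2 + (pa$Y[, i] - pa$Y[, j])^2 <= d_m^2
    n_co <- rowsum(both + 0, win)[, 1]
    n_close <- rowsum(dclose + 0, win)[, 1]
    close_pair[, k] <- seen[, i] & seen[, j] & n_co > 0 &
      n_close / pmax(n_co, 1) >= prox_frac
  }
  groups <- vector("list", grid$windows_per_period)
  parent <- integer(n)
  for (w in seq_len(grid$windows_per_period)) {
    parent[] <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in which(close_pair[w, ])) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
    seen_w <- which(seen[w, ])
    if (length(seen_w) == 0) { groups[[w]] <- list(); next }
    roots <- vapply(seen_w, find, integer(1))
    groups[[w]] <- unname(split(seen_w, roots))
  }
  structure(list(groups = groups, animals = animals,
                 n_windows = grid$windows_per_period),
            class = "group_stream")
}

stream_marginals <- function(stream) {
  n <- length(stream$animals)
  seen_count <- integer(n)
  for (g in stream$groups) for (v in g) seen_count[v] <- seen_count[v] + 1L
  sizes <- lapply(stream$groups, function(g) sort(lengths(g)))
  list(seen_count = stats::setNames(seen_count, stream$animals),
       group_sizes = sizes)
}

stream_counts <- function(stream) {
  # X: windows in same group; denom: windows with at least one member seen
  n <- length(stream$animals)
  X <- matrix(0L, n, n, dimnames = list(stream$animals, stream$animals))
  either <- matrix(0L, n, n)
  for (g in stream$groups) {
    seen_w <- unlist(g)
    if (length(seen_w) == 0) next
    either[seen_w, ] <- either[seen_w, ] + 1L
    either[, seen_w] <- either[, seen_w] + 1L
    either[seen_w, seen_w] <- either[seen_w, seen_w] - 1L
    for (v in g) if (length(v) > 1)
      X[v, v] <- X[v, v] + 1L
  }
  diag(X) <- 0L; diag(either) <- 0L
  list(X = X, denom = either)
}

swap_once <- function(groups, eligible) {
  # one random pairwise swap of individuals between two groups of one window
  w <- eligible[sample.int(length(eligible), 1)]
  g <- groups[[w]]
  ij <- sample.int(length(g), 2)
  ga <- g[[ij[1]]]; gb <- g[[ij[2]]]
  a <- ga[sample.int(length(ga), 1)]
  b <- gb[sample.int(length(gb), 1)]
  g[[ij[1]]] <- c(setdiff(ga, a), b)
  g[[ij[2]]] <- c(setdiff(gb, b), a)
  groups[[w]] <- g
  list(groups = groups, w = w, a = a, b = b,
       ga_rest = setdiff(ga, a), gb_rest = setdiff(gb, b))
}

#' Data-stream permutation of a group stream
#'
#' Performs `n_swaps` random pairwise swaps of individuals between proximity
#' groups within the same window. Each swap preserves every window's group
#' sizes and every animal's windows-seen count exactly; the chain's
#' stationary distribution is uniform over group assignments with those
#' marginals (the uniform-association null).
#'
#' @param stream A `group_stream` from [window_group_stream()].
#' @param n_swaps Number of swaps (default `20 * n_windows`).
#' @param seed Integer seed.
#' @return A permuted `group_stream`.
#' @export
datastream_permute <- function(stream, n_swaps = 20 * stream$n_windows,
                               seed = 1L) {
  set.seed(seed)
  eligible <- which(vapply(stream$groups, function(g) length(g) >= 2, logical(1)))
  if (length(eligible) == 0) {
    warning("no window has two or more groups; returning the stream unchanged")
    return(stream)
  }
  groups <- stream$groups
  for (s in seq_len(n_swaps)) groups <- swap_once(groups, eligible)$groups
  stream$groups <- groups
  stream
}

#' Social differentiation test for one cohort-period
#'
#' Tests whether dyadic associations are more heterogeneous than expected if
#' calves associated uniformly. The statistic is the coefficient of
#' variation, across dyads, of the simple-ratio association indices computed
#' from the within-window group stream. The default null resamples the
#' stream by data-stream permutation (swaps within windows, preserving all
#' marginals); `null = "binomial"` instead redraws each dyad's associated
#' windows as Binomial(denominator, pooled association rate). One-sided
#' add-one p-value: proportion of null statistics >= observed.
#'
#' @param stream A `group_stream` from [window_group_stream()].
#' @param n_perm Number of null statistics (default 10,000).
#' @param seed Integer seed.
#' @param swaps_per_sample Swaps between successive null samples (default:
#'   the number of swappable windows).
#' @param burn_in_swaps Swaps before the first sample (default
#'   `10 * swaps_per_sample`).
#' @param null `"datastream"` (default) or `"binomial"`.
#' @return A `perm_result` with extra fields `cv_observed`, `cv_corrected`
#'   (sampling-error-corrected differentiation, using
#'   [index_standard_error()]), `n_dyads`.
#' @export
social_differentiation_test <- function(stream, n_perm = 10000, seed = 1L,
                                        swaps_per_sample = NULL,
                                        burn_in_swaps = NULL,
                                        null = c("datastream", "binomial")) {
  null <- match.arg(null)
  sc <- stream_counts(stream)
  ut <- upper.tri(sc$X)
  denom <- sc$denom[ut]
  usable <- denom > 0
  if (sum(usable) < 3) stop("need at least 3 dyads with defined indices")
  cv_of <- function(x) {
    w <- x[usable] / denom[usable]
    m <- mean(w)
    if (m == 0) return(0)
    stats::sd(w) / m
  }
  x_obs <- sc$X[ut]
  obs <- cv_of(x_obs)
  w_obs <- x_obs[usable] / denom[usable]
  se <- index_standard_error(w_obs, x_obs[usable])
  cv_corr <- if (mean(w_obs) > 0 && any(!is.na(se)))
    sqrt(max(0, stats::var(w_obs) - mean(se^2, na.rm = TRUE))) / mean(w_obs)
  else NA_real_

  set.seed(seed)
  if (null == "binomial") {
    p_hat <- sum(x_obs) / sum(denom)
    null_vals <- vapply(seq_len(n_perm), function(k)
      cv_of(stats::rbinom(length(denom), denom, p_hat)), numeric(1))
  } else {
    eligible <- which(vapply(stream$groups, function(g) length(g) >= 2, logical(1)))
    if (length(eligible) == 0) {
      warning("no swappable window; p = 1 by construction")
      return(perm_result(obs, rep(obs, n_perm), n_perm, seed))
    }
    if (is.null(swaps_per_sample)) swaps_per_sample <- length(eligible)
    if (is.null(burn_in_swaps)) burn_in_swaps <- 10 * swaps_per_sample
    groups <- stream$groups
    X <- sc$X
    null_vals <- numeric(n_perm)
    total_swaps <- burn_in_swaps + n_perm * swaps_per_sample
    rec <- 0L
    for (s in seq_len(total_swaps)) {
      sw <- swap_once(groups, eligible)
      groups <- sw$groups
      a <- sw$a; b <- sw$b
      if (length(sw$ga_rest)) {
        X[a, sw$ga_rest] <- X[a, sw$ga_rest] - 1L; X[sw$ga_rest, a] <- X[a, sw$ga_rest]
        X[b, sw$ga_rest] <- X[b, sw$ga_rest] + 1L; X[sw$ga_rest, b] <- X[b, sw$ga_rest]
      }
      if (length(sw$gb_rest)) {
        X[b, sw$gb_rest] <- X[b, sw$gb_rest] - 1L; X[sw$gb_rest, b] <- X[b, sw$gb_rest]
        X[a, sw$gb_rest] <- X[a, sw$gb_rest] + 1L; X[sw$gb_rest, a] <- X[a, sw$gb_rest]
      }
      if (s > burn_in_swaps && (s - burn_in_swaps) %% swaps_per_sample == 0) {
        rec <- rec + 1L
        null_vals[rec] <- cv_of(X[ut])
      }
    }
  }
  res <- perm_result(obs, null_vals, n_perm, seed)
  res$cv_observed <- obs
  res$cv_corrected <- cv_corr
  res$n_dyads <- sum(usable)
  res
}
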