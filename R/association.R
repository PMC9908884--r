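# Dyadic window states, counts, and the simple-ratio association index.

#' Window grid for a monitoring stretch
#'
#' Tiles each aggregation period (4 days by default) into consecutive,
#' non-overlapping windows of `window_s` seconds (3 minutes by default). One
#' associated window is one proximity interaction. Trailing periods shorter
#' than `period_days` are dropped.
#'
#' @param monitoring_days Total days covered by the positions.
#' @param period_days Aggregation period length in days (default 4; may be
#'   fractional for small experiments).
#' @param window_s Window length in seconds (default 180).
#' @return List with `period_s`, `window_s`, `n_periods`,
#'   `windows_per_period`.
#' @export
window_grid <- function(monitoring_days, period_days = 4, window_s = 180) {
  stopifnot(period_days > 0, window_s >= 1)
  period_s <- period_days * 86400
  list(period_s = period_s, window_s = window_s,
       n_periods = floor(monitoring_days * 86400 / period_s),
       windows_per_period = floor(period_s / window_s))
}

#' Classify one dyad-window
#'
#' An animal is "seen" in a window when its valid-fix fraction is at least
#' `seen_frac` of the scheduled fixes. When both are seen, the window is
#' `both_close` when the fraction of co-timestamped fix pairs at Euclidean
#' distance <= `d_m` is at least `prox_frac`, else `both_far`.
#'
#' @param t_a,x_a,y_a Times and coordinates of animal A's fixes in the window.
#' @param t_b,x_b,y_b Same for animal B.
#' @param expected_fixes Number of scheduled fixes per animal in the window.
#' @param d_m Spatial threshold in metres (default 1).
#' @param seen_frac Minimum fraction of scheduled fixes to count as seen.
#' @param prox_frac Minimum fraction of co-timestamped pairs within `d_m`.
#' @return One of `"both_close"`, `"both_far"`, `"only_A"`, `"only_B"`,
#'   `"neither"`.
#' @export
window_state <- function(t_a, x_a, y_a, t_b, x_b, y_b, expected_fixes,
                         d_m = 1.0, seen_frac = 0.5, prox_frac = 0.9) {
  seen_a <- length(t_a) / expected_fixes >= seen_frac
  seen_b <- length(t_b) / expected_fixes >= seen_frac
  if (!seen_a && !seen_b) return("neither")
  if (seen_a && !seen_b) return("only_A")
  if (!seen_a && seen_b) return("only_B")
  shared <- intersect(t_a, t_b)
  if (length(shared) == 0) return("both_far")
  ia <- match(shared, t_a); ib <- match(shared, t_b)
  close <- sqrt((x_a[ia] - x_b[ib])^2 + (y_a[ia] - y_b[ib])^2) <= d_m
  if (mean(close) >= prox_frac) "both_close" else "both_far"
}

pos_array <- function(positions, animals, sample_interval_s, n_t) {
  # wide (time x animal) coordinate matrices; NA where no fix
  ti <- positions$time_s / sample_interval_s + 1
  if (any(abs(ti - round(ti)) > 1e-8))
    stop("fix times are not aligned to the sampling interval")
  ti <- as.integer(round(ti))
  ai <- match(positions$animal_id, animals)
  if (anyNA(ai)) stop("positions contain unknown animal ids")
  if (anyDuplicated(cbind(ti, ai)))
    stop("duplicate fixes for the same animal and second")
  X <- matrix(NA_real_, n_t, length(animals), dimnames = list(NULL, animals))
  Y <- X
  X[cbind(ti, ai)] <- positions$x_m
  Y[cbind(ti, ai)] <- positions$y_m
  list(X = X, Y = Y)
}

#' Tally dyadic window states over all periods
#'
#' Converts cleaned, smoothed positions into per-period, per-dyad counts:
#' `X` windows with both animals seen and in proximity, `Y_AB` both seen but
#' apart, `Y_A`/`Y_B` only one seen, out of `N_windows` windows per period.
#'
#' @param positions Cleaned and smoothed fix table.
#' @param animals Character vector fixing the node set and order (sorted ids
#'   of the cohort by default).
#' @param monitoring_days Monitoring span; inferred from the last fix when
#'   `NULL`.
#' @param sample_interval_s Seconds between scheduled fixes (1 / sampling
#'   rate).
#' @param period_days,window_s Aggregation grid, see [window_grid()].
#' @param d_m,seen_frac,prox_frac Thresholds, see [window_state()].
#' @param t0 Start of the period grid in seconds (e.g. 86400 when the first
#'   monitored day has been censored); fixes before `t0` are ignored.
#' @return data.frame with one row per period and unordered dyad `(a, b)`
#'   (a < b in `animals` order): `period`, `a`, `b`, `X`, `Y_AB`, `Y_A`,
#'   `Y_B`, `N_windows`.
#' @export
accumulate_counts <- function(positions, animals = sort(unique(positions$animal_id)),
                              monitoring_days = NULL, sample_interval_s = 1,
                              period_days = 4, window_s = 180,
                              d_m = 1.0, seen_frac = 0.5, prox_frac = 0.9,
                              t0 = 0) {
  positions <- positions[positions$time_s >= t0, , drop = FALSE]
  positions$time_s <- positions$time_s - t0
  if (is.null(monitoring_days))
    monitoring_days <- ceiling((max(positions$time_s) + sample_interval_s) / 86400)
  grid <- window_grid(monitoring_days, period_days, window_s)
  if (grid$n_periods < 1) stop("monitoring span shorter than one period")
  fix_per_win <- window_s / sample_interval_s
  n_t <- as.integer(grid$n_periods * grid$windows_per_period * fix_per_win)
  positions <- positions[positions$time_s < n_t * sample_interval_s, , drop = FALSE]
  pa <- pos_array(positions, animals, sample_interval_s, n_t)
  win <- rep(seq_len(grid$n_periods * grid$windows_per_period), each = fix_per_win)
  n_win_tot <- max(win)
  seen_n <- rowsum((!is.na(pa$X)) + 0, win)        # fixes per animal-window
  seen <- seen_n / fix_per_win >= seen_frac
  n <- length(animals)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0
  period_of_win <- rep(seq_len(grid$n_periods), each = grid$windows_per_period)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !is.na(pa$X[, i]) & !is.na(pa$X[, j])
    dclose <- both & (pa$X[, i] - pa$X[, j])^2 + (pa$Y[, i] - pa$Y[, j])^2 <= d_m^2
    n_co <- rowsum(both + 0, win)[, 1]
    n_close <- rowsum(dclose + 0, win)[, 1]
    si <- seen[, i]; sj <- seen[, j]
    close_win <- si & sj & n_co > 0 & n_close / pmax(n_co, 1) >= prox_frac
    state <- ifelse(si & sj, ifelse(close_win, 1L, 2L),
                    ifelse(si, 3L, ifelse(sj, 4L, 5L)))
    k <- k + 1
    tab <- vapply(1:4, function(s) rowsum((state == s) + 0L, period_of_win)[, 1],
                  numeric(grid$n_periods))
    tab <- matrix(tab, nrow = grid$n_periods)
    out[[k]] <- data.frame(period = seq_len(grid$n_periods),
                           a = animals[i], b = animals[j],
                           X = as.integer(tab[, 1]), Y_AB = as.integer(tab[, 2]),
                           Y_A = as.integer(tab[, 3]), Y_B = as.integer(tab[, 4]),
                           N_windows = grid$windows_per_period,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$period, res$a, res$b), ]
  rownames(res) <- NULL
  res
}

#' Simple-ratio association index
#'
#' `E_AB = X / (X + Y_AB + Y_A + Y_B)`: the fraction of windows in which the
#' dyad was together out of the windows in which at least one member was
#' observed. Dyads never observed (zero denominator) get weight 0 and are
#' flagged via the `defined` attribute so they can be excluded from
#' dispersion statistics.
#'
#' @param X,Y_AB,Y_A,Y_B Non-negative counts (vectorised).
#' @return Numeric weights in \[0, 1\] with logical attribute `defined`.
#' @export
association_index <- function(X, Y_AB, Y_A, Y_B) {
  if (any(c(X, Y_AB, Y_A, Y_B) < 0)) stop("counts must be non-negative")
  den <- X + Y_AB + Y_A + Y_B
  w <- ifelse(den > 0, X / pmax(den, 1), 0)
  attr(w, "defined") <- den > 0
  w
}

#' Standard error of an association index
#'
#' `SE = alpha * sqrt((1 - alpha) / x)` where `alpha` is the index and `x`
#' the number of windows in which the dyad interacted. Dyads with `x = 0`
#' get `NA` (excluded from differentiation statistics).
#'
#' @param alpha Association index in \[0, 1\].
#' @param x Count of associated windows.
#' @return Numeric standard errors (NA where `x = 0`).
#' @export
index_standard_error <- function(alpha, x) {
  stopifnot(all(alpha >= 0), all(alpha <= 1), all(x >= 0))
  ifelse(x >= 1, alpha * sqrt((1 - alpha) / x), NA_real_)
}

#' Assemble the association matrix for one cohort-period
#'
#' @param counts Rows of [accumulate_counts()] for a single period.
#' @param animals Node set and order; inferred (sorted) when `NULL`.
#' @return Symmetric weight matrix with zero diagonal, dimnames = animal ids,
#'   and attributes `X` (matrix of associated-window counts) and `defined`
#'   (logical matrix, FALSE for zero-denominator dyads).
#' @export
build_matrix <- function(counts, animals = NULL) {
  if (is.null(animals)) animals <- sort(unique(c(counts$a, counts$b)))
  n <- length(animals)
  if (length(unique(counts$period)) > 1)
    stop("counts span more than one period")
  if (nrow(counts) != n * (n - 1) / 2)
    stop("counts must cover every dyad exactly once")
  E <- matrix(0, n, n, dimnames = list(animals, animals))
  Xm <- matrix(0L, n, n, dimnames = list(animals, animals))
  Dm <- matrix(TRUE, n, n, dimnames = list(animals, animals))
  w <- association_index(counts$X, counts$Y_AB, counts$Y_A, counts$Y_B)
  ia <- match(counts$a, animals); ib <- match(counts$b, animals)
  if (anyNA(ia) || anyNA(ib)) stop("counts contain animals outside the node set")
  E[cbind(ia, ib)] <- w; E[cbind(ib, ia)] <- w
  Xm[cbind(ia, ib)] <- counts$X; Xm[cbind(ib, ia)] <- counts$X
  Dm[cbind(ia, ib)] <- attr(w, "defined"); Dm[cbind(ib, ia)] <- attr(w, "defined")
  diag(Dm) <- FALSE
  attr(E, "X") <- Xm
  attr(E, "defined") <- Dm
  E
}

#' Association matrices for all periods
#'
#' @param counts Full output of [accumulate_counts()].
#' @param animals Node set; inferred when `NULL`.
#' @return Named list of matrices, one per period (names `"1"`, `"2"`, ...).
#' @export
build_matrices <- function(counts, animals = NULL) {
  lapply(split(counts, counts$period), build_matrix, animals = animals)
}
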