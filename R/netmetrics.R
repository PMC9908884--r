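# Node-level sociality measures from one 4-day association matrix.

#' Association strength (weighted degree)
#'
#' Sum of a node's edge weights (association indices).
#'
#' @param E Symmetric association matrix.
#' @param node Animal id or index; all nodes when `NULL`.
#' @return Named numeric vector (or scalar) of row sums.
#' @export
node_strength <- function(E, node = NULL) {
  s <- rowSums(E)
  if (is.null(node)) return(s)
  if (is.character(node) && !node %in% rownames(E)) stop("unknown node: ", node)
  s[[node]]
}

#' Total social time in minutes
#'
#' Sum of a calf's associated windows (proximity interactions) with the rest
#' of the group, times 3 (each interaction is one 3-minute window). Computed
#' from raw counts, without the association index.
#'
#' @param counts Rows of [accumulate_counts()] for one cohort-period.
#' @param node Animal id; all animals when `NULL`.
#' @param window_min Window length in minutes (default 3).
#' @return Named numeric vector of minutes.
#' @export
social_time <- function(counts, node = NULL, window_min = 3) {
  animals <- sort(unique(c(counts$a, counts$b)))
  x <- vapply(animals, function(an)
    sum(counts$X[counts$a == an | counts$b == an]), numeric(1))
  res <- window_min * x
  if (is.null(node)) res else res[[node]]
}

#' Eigenvector centrality of a weighted association network
#'
#' First (Perron-Frobenius) eigenvector of the adjacency matrix, which is
#' entrywise non-negative for a connected non-negative matrix, normalised so
#' the maximum is 1. An all-zero matrix returns all zeros with attribute
#' `flag = "empty_network"`.
#'
#' @param E Symmetric non-negative association matrix.
#' @return Named numeric vector in \[0, 1\].
#' @export
eigenvector_centrality <- function(E) {
  if (!isTRUE(all.equal(E, t(E)))) stop("association matrix must be symmetric")
  if (all(E == 0)) {
    v <- stats::setNames(rep(0, nrow(E)), rownames(E))
    attr(v, "flag") <- "empty_network"
    return(v)
  }
  es <- eigen(E, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                      # clip FP noise on a Perron vector
  stats::setNames(v / max(v), rownames(E))
}

#' Closeness centrality with reciprocal-weight distances
#'
#' Edge length is `1 / E_ij` for positive weights (stronger association =
#' shorter distance); `d(i, j)` is the weighted shortest-path length. For
#' possibly disconnected networks the Wasserman-Faust scaling is used:
#' `closeness(i) = (r_i / (n - 1)) * (r_i / sum_j d(i, j))` over the `r_i`
#' nodes reachable from `i`. Isolated nodes get 0.
#'
#' @param E Symmetric non-negative association matrix.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(E) {
  if (!isTRUE(all.equal(E, t(E)))) stop("association matrix must be symmetric")
  n <- nrow(E)
  g <- igraph::graph_from_adjacency_matrix(E, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  res <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    reach <- is.finite(d) & d > 0
    r <- sum(reach)
    res[i] <- if (r == 0) 0 else (r / (n - 1)) * (r / sum(d[reach]))
  }
  stats::setNames(res, rownames(E))
}

#' Coefficient of variation of a node's associations
#'
#' Sample standard deviation (n - 1 denominator) of the node's off-diagonal
#' association indices divided by their mean: the heterogeneity of the
#' calf's social bonds. Dyads flagged as undefined (never-observed) are
#' excluded; fewer than 2 usable edges or a zero mean gives `NA`.
#'
#' @param E Association matrix (with optional `defined` attribute from
#'   [build_matrix()]).
#' @param node Animal id or index; all nodes when `NULL`.
#' @return Numeric CV (or named vector).
#' @export
node_cv <- function(E, node = NULL) {
  def <- attr(E, "defined")
  if (is.null(def)) { def <- matrix(TRUE, nrow(E), ncol(E)); diag(def) <- FALSE }
  one <- function(i) {
    w <- E[i, -i][def[i, -i]]
    if (length(w) < 2) return(NA_real_)
    m <- mean(w)
    if (m == 0) return(NA_real_)
    stats::sd(w) / m
  }
  if (!is.null(node)) {
    if (is.character(node)) node <- match(node, rownames(E))
    return(one(node))
  }
  stats::setNames(vapply(seq_len(nrow(E)), one, numeric(1)), rownames(E))
}

#' Node-metric table for one cohort across periods
#'
#' Combines the five sociality measures with the covariates the node-level
#' models use: age at the end of each 4-day period, weaning stage at the end
#' of the period (from feeder-days = age - 14), and the worst health
#' category assessed within the period.
#'
#' @param matrices Named list of per-period association matrices
#'   ([build_matrices()]).
#' @param counts Output of [accumulate_counts()] for the same cohort.
#' @param meta data.frame `animal_id`, `cohort`, `entry_age_days`.
#' @param health Health table (`animal`, `day`, `total`); may be empty.
#' @param period_days Period length in days (default 4).
#' @param window_min Minutes per window for social time (default 3).
#' @return data.frame with one row per animal-period: cohort, period, animal,
#'   strength, social_time_min, eigenvector, closeness, cv_association,
#'   age_days, weaning_stage, health_category.
#' @export
node_metrics <- function(matrices, counts, meta, health = NULL,
                         period_days = 4, window_min = 3) {
  rows <- list()
  for (p in names(matrices)) {
    E <- matrices[[p]]
    pnum <- as.integer(p)
    cp <- counts[counts$period == pnum, ]
    stm <- social_time(cp, window_min = window_min)
    ev <- eigenvector_centrality(E)
    cl <- closeness_centrality(E)
    cv <- node_cv(E)
    str <- node_strength(E)
    animals <- rownames(E)
    m <- meta[match(animals, meta$animal_id), ]
    age_end <- m$entry_age_days + pnum * period_days
    stage <- weaning_stage(pmax(1, age_end - 14))
    hc <- rep("healthy", length(animals))
    if (!is.null(health) && nrow(health) > 0) {
      lo <- (pnum - 1) * period_days + 1; hi <- pnum * period_days
      for (k in seq_along(animals)) {
        h <- health[health$animal == animals[k], ]
        inper <- h[h$day >= lo & h$day <= hi, ]
        tot <- if (nrow(inper) > 0) max(inper$total) else {
          # no assessment inside the period: use the nearest one
          if (nrow(h) > 0) h$total[which.min(abs(h$day - hi))] else 0
        }
        hc[k] <- as.character(health_category(tot))
      }
    }
    rows[[p]] <- data.frame(
      cohort = m$cohort, period = pnum, animal = animals,
      strength = as.numeric(str), social_time_min = as.numeric(stm[animals]),
      eigenvector = as.numeric(ev), closeness = as.numeric(cl),
      cv_association = as.numeric(cv), age_days = age_end,
      weaning_stage = as.character(stage), health_category = hc,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
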