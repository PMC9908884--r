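# Dyadic assortment regression (multiple-membership Gibbs sampler) and
# node-level linear mixed models with Benjamini-Hochberg correction.

#' Dyadic observation table for assortment testing
#'
#' One row per dyad per period: the (log) edge weight as response and the
#' dyadic covariates age difference (days between birth dates), health
#' difference (categories coded healthy = 0, moderate = 1, sick = 2, absolute
#' difference at the assessment nearest the period end) and pre-entry
#' familiarity days.
#'
#' @param matrices Named list of per-period association matrices for one
#'   cohort ([build_matrices()]).
#' @param meta data.frame `animal_id`, `cohort`, `entry_age_days`.
#' @param familiarity Symmetric familiarity matrix (days), dimnames =
#'   animal ids.
#' @param health Health table (`animal`, `day`, `total`); `NULL` for all
#'   healthy.
#' @param period_days Period length in days (default 4).
#' @param zero_rule `"drop"` (default: dyad-periods with zero weight are
#'   excluded, since log 0 is undefined) or `"offset"` (log(E + c) with c =
#'   half the smallest positive weight).
#' @return data.frame: cohort, period, id_i, id_j, edge_weight, log_edge,
#'   age_diff_days, health_diff, familiarity_days.
#' @export
build_dyad_table <- function(matrices, meta, familiarity, health = NULL,
                             period_days = 4, zero_rule = c("drop", "offset")) {
  zero_rule <- match.arg(zero_rule)
  rows <- list()
  for (p in names(matrices)) {
    E <- matrices[[p]]
    pnum <- as.integer(p)
    def <- attr(E, "defined")
    if (is.null(def)) { def <- matrix(TRUE, nrow(E), ncol(E)); diag(def) <- FALSE }
    animals <- rownames(E)
    m <- meta[match(animals, meta$animal_id), ]
    if (anyNA(m$animal_id)) stop("metadata missing for some animals")
    hcode <- rep(0L, length(animals))
    if (!is.null(health) && nrow(health) > 0) {
      hi <- pnum * period_days
      for (k in seq_along(animals)) {
        h <- health[health$animal == animals[k], ]
        if (nrow(h) > 0)
          hcode[k] <- as.integer(health_category(
            h$total[which.min(abs(h$day - hi))])) - 1L
      }
    }
    ut <- which(upper.tri(E), arr.ind = TRUE)
    rows[[p]] <- data.frame(
      cohort = m$cohort[1], period = pnum,
      id_i = animals[ut[, 1]], id_j = animals[ut[, 2]],
      edge_weight = E[ut],
      age_diff_days = abs(m$entry_age_days[ut[, 1]] - m$entry_age_days[ut[, 2]]),
      health_diff = abs(hcode[ut[, 1]] - hcode[ut[, 2]]),
      familiarity_days = familiarity[cbind(animals[ut[, 1]], animals[ut[, 2]])],
      defined = def[ut],
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  tab <- tab[tab$defined, setdiff(names(tab), "defined")]
  if (zero_rule == "drop") {
    tab <- tab[tab$edge_weight > 0, ]
    tab$log_edge <- log(tab$edge_weight)
  } else {
    pos <- tab$edge_weight[tab$edge_weight > 0]
    c0 <- if (length(pos)) min(pos) / 2 else 1e-6
    tab$log_edge <- log(tab$edge_weight + c0)
  }
  rownames(tab) <- NULL
  tab
}

rinvgamma <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

ess_ar1 <- function(x) {
  # effective sample size from the lag-1 autocorrelation (AR(1) approximation)
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  r1 <- stats::cor(x[-1], x[-n])
  r1 <- min(max(r1, -0.999), 0.999)
  n * (1 - r1) / (1 + r1)
}

#' Dyadic assortment model with multiple-membership node effects
#'
#' Gaussian Gibbs sampler for
#' `log_edge = b0 + b1 age_diff + b2 health_diff + b3 familiarity +
#' u_cohort + v_i + v_j + e`, where `v` is a single node-effect vector that
#' enters each dyadic row once per member (multiple membership, design
#' weight 1). Diffuse normal prior on the coefficients, inverse-gamma
#' (shape = rate = 0.001) priors on the variance components. With a single
#' cohort the cohort variance is not identifiable and is fixed at zero with
#' a message.
#'
#' @param table Output of [build_dyad_table()] (any data.frame with columns
#'   `log_edge`, `age_diff_days`, `health_diff`, `familiarity_days`, `id_i`,
#'   `id_j`, `cohort`).
#' @param n_iter,burn_in,thin MCMC controls (defaults 60,000 / 10,000 / 25).
#' @param seed Integer seed.
#' @param prior_shape,prior_rate Inverse-gamma hyperparameters.
#' @return List of class `dyadic_fit`: `summary` (posterior mean, 95%
#'   credible interval, pMCMC and effective size per coefficient),
#'   `vc` (posterior means of the cohort, node and residual variances),
#'   `samples` (thinned coefficient draws), `converged` (all coefficient
#'   effective sizes >= 100), and the MCMC settings.
#' @export
fit_dyadic_assortment <- function(table, n_iter = 60000, burn_in = 10000,
                                  thin = 25, seed = 1L,
                                  prior_shape = 0.001, prior_rate = 0.001) {
  stopifnot(nrow(table) > 10, burn_in < n_iter)
  set.seed(seed)
  y <- table$log_edge
  Xmat <- cbind(intercept = 1, age_diff = table$age_diff_days,
                health_diff = table$health_diff,
                familiarity = table$familiarity_days)
  nodes <- sort(unique(c(table$id_i, table$id_j)))
  K <- length(nodes)
  ii <- match(table$id_i, nodes); jj <- match(table$id_j, nodes)
  cohorts <- sort(unique(table$cohort))
  C <- length(cohorts)
  cc <- match(table$cohort, cohorts)
  single_cohort <- C < 2
  if (single_cohort)
    message("single cohort: cohort variance fixed at 0")
  n <- length(y); P <- ncol(Xmat)
  XtX <- crossprod(Xmat)
  prior_prec_beta <- diag(1e-8, P)
  rows_of_node <- lapply(seq_len(K), function(k) which(ii == k | jj == k))
  partner_of <- lapply(seq_len(K), function(k) {
    r <- rows_of_node[[k]]
    ifelse(ii[r] == k, jj[r], ii[r])
  })
  rows_of_coh <- lapply(seq_len(C), function(k) which(cc == k))

  beta <- stats::coef(stats::lm.fit(Xmat, y))
  v <- rep(0, K); u <- rep(0, C)
  s2e <- max(stats::var(y), 1e-6); s2v <- s2e / 4; s2c <- s2e / 4
  n_keep <- floor((n_iter - burn_in) / thin)
  bsamp <- matrix(NA_real_, n_keep, P,
                  dimnames = list(NULL, colnames(Xmat)))
  vcsamp <- matrix(NA_real_, n_keep, 3,
                   dimnames = list(NULL, c("cohort", "node", "residual")))
  keep <- 0L
  for (it in seq_len(n_iter)) {
    re <- v[ii] + v[jj] + u[cc]
    prec <- XtX / s2e + prior_prec_beta
    ch <- chol(prec)
    mu <- backsolve(ch, forwardsolve(t(ch), crossprod(Xmat, y - re) / s2e))
    beta <- drop(mu + backsolve(ch, stats::rnorm(P)))
    xb <- drop(Xmat %*% beta)
    for (k in seq_len(K)) {
      r <- rows_of_node[[k]]
      resid_k <- y[r] - xb[r] - u[cc[r]] - v[partner_of[[k]]]
      pk <- length(r) / s2e + 1 / s2v
      v[k] <- stats::rnorm(1, sum(resid_k) / s2e / pk, sqrt(1 / pk))
    }
    if (!single_cohort) {
      for (k in seq_len(C)) {
        r <- rows_of_coh[[k]]
        resid_k <- y[r] - xb[r] - v[ii[r]] - v[jj[r]]
        pk <- length(r) / s2e + 1 / s2c
        u[k] <- stats::rnorm(1, sum(resid_k) / s2e / pk, sqrt(1 / pk))
      }
      s2c <- rinvgamma(prior_shape + C / 2, prior_rate + sum(u^2) / 2)
    }
    resid <- y - xb - v[ii] - v[jj] - u[cc]
    s2e <- rinvgamma(prior_shape + n / 2, prior_rate + sum(resid^2) / 2)
    s2v <- rinvgamma(prior_shape + K / 2, prior_rate + sum(v^2) / 2)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      keep <- keep + 1L
      bsamp[keep, ] <- beta
      vcsamp[keep, ] <- c(if (single_cohort) 0 else s2c, s2v, s2e)
    }
  }
  summ <- data.frame(
    term = colnames(bsamp),
    mean = colMeans(bsamp),
    lower95 = apply(bsamp, 2, stats::quantile, 0.025),
    upper95 = apply(bsamp, 2, stats::quantile, 0.975),
    pMCMC = apply(bsamp, 2, function(b)
      max(2 * min(mean(b > 0), mean(b < 0)), 1 / length(b))),
    ess = apply(bsamp, 2, ess_ar1),
    row.names = NULL
  )
  structure(list(summary = summ, vc = colMeans(vcsamp), samples = bsamp,
                 vc_samples = vcsamp,
                 converged = all(summ$ess >= 100),
                 n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
            class = "dyadic_fit")
}

#' @method print dyadic_fit
#' @export
print.dyadic_fit <- function(x, ...) {
  cat(sprintf("dyadic assortment fit (%d kept draws%s)\n", nrow(x$samples),
              if (x$converged) "" else "; LOW EFFECTIVE SIZE"))
  print(x$summary, digits = 4)
  cat("variance components:\n"); print(round(x$vc, 5))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Node-level linear mixed models for the five sociality measures
#'
#' For each metric (strength, social time, eigenvector centrality,
#' closeness, CV of association) fits
#' `metric ~ age_days + weaning_stage + health_category + (1 | animal) +
#' (1 | cohort:period)` (plus `(1 | cohort)` with two or more cohorts) by
#' REML via \pkg{lme4}. Wald t statistics use residual degrees of freedom;
#' BH adjustment is applied per coefficient across the five models.
#' Categorical terms with a single observed level are dropped with a
#' warning.
#'
#' @param metrics Node-metric table from [node_metrics()] (rows with `NA`
#'   metric values are dropped per model).
#' @param metric_names Metrics to model.
#' @return List of class `node_lmm_fit`: `coefficients` (metric, term, beta,
#'   se, t, df, p_raw, p_BH), `varcomp` (per metric), `fits` (the lme4
#'   objects).
#' @export
fit_node_lmms <- function(metrics,
                          metric_names = c("strength", "social_time_min",
                                           "eigenvector", "closeness",
                                           "cv_association")) {
  metrics$weaning_stage <- factor(metrics$weaning_stage,
                                  levels = c("non_weaned", "step_down", "weaned"))
  metrics$health_category <- factor(metrics$health_category,
                                    levels = c("healthy", "moderate", "sick"))
  metrics$cohort_period <- interaction(metrics$cohort, metrics$period, drop = TRUE)
  multi_cohort <- length(unique(metrics$cohort)) > 1
  out <- list(); fits <- list(); vcs <- list()
  for (mn in metric_names) {
    d <- metrics[is.finite(metrics[[mn]]), , drop = FALSE]
    d <- droplevels(d)
    fixed <- "age_days"
    for (f in c("weaning_stage", "health_category")) {
      if (nlevels(d[[f]]) >= 2) fixed <- c(fixed, f)
      else warning(sprintf("%s: dropping '%s' (single level observed)", mn, f))
    }
    rand <- c("(1 | animal)", "(1 | cohort_period)")
    if (multi_cohort) rand <- c(rand, "(1 | cohort)")
    fml <- stats::as.formula(paste(mn, "~", paste(c(fixed, rand), collapse = " + ")))
    fit <- lme4::lmer(fml, data = d, REML = TRUE)
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    tval <- fe / se
    df_resid <- nrow(d) - length(fe)
    ct <- data.frame(metric = mn, term = names(fe), beta = as.numeric(fe),
                     se = as.numeric(se), t = as.numeric(tval), df = df_resid,
                     p_raw = 2 * stats::pt(-abs(tval), df_resid),
                     row.names = NULL)
    out[[mn]] <- ct
    fits[[mn]] <- fit
    vc <- as.data.frame(lme4::VarCorr(fit))
    vcs[[mn]] <- data.frame(metric = mn, group = vc$grp, variance = vc$vcov)
  }
  coefs <- do.call(rbind, out)
  # BH family: the same coefficient tested across the five metric models
  coefs$p_BH <- NA_real_
  for (tm in unique(coefs$term)) {
    sel <- coefs$term == tm
    coefs$p_BH[sel] <- bh_adjust(coefs$p_raw[sel])
  }
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, varcomp = do.call(rbind, vcs),
                 fits = fits), class = "node_lmm_fit")
}

#' @method print node_lmm_fit
#' @export
print.node_lmm_fit <- function(x, ...) {
  print(x$coefficients, digits = 4)
  invisible(x)
}
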