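#' Permutation-tested ordinary least squares with bootstrap CI
#'
#' Fits y ~ x by OLS and assesses the slope two ways: (i) a permutation test
#' that permutes the response and compares absolute slopes, with the add-one
#' rule p = (1 + #(|slope*| >= |slope|)) / (n_perm + 1); (ii) a percentile
#' bootstrap confidence interval on the slope by case resampling. A
#' correlation is flagged `significant` under the dual criterion used
#' throughout the analysis: permutation p < 0.05 AND the 95% bootstrap CI
#' excludes zero.
#'
#' The AIC reported is the Gaussian-likelihood form n*log(RSS/n) + 2k with
#' k = 3 (intercept, slope, residual variance).
#'
#' @param x,y Numeric vectors of equal length >= 3, finite.
#' @param n_perm Number of permutations (default 9999).
#' @param n_boot Number of bootstrap resamples (default 1999).
#' @param conf_level Confidence level of the bootstrap interval (default .95).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `arclakes_regression`: a list with `slope`,
#'   `intercept`, `r_squared`, `permutation_p`, `boot_ci`, `aic`, `k`,
#'   `significant`, `n`, `n_perm`, `n_boot`.
#' @export
ols_permutation_fit <- function(x, y, n_perm = 9999, n_boot = 1999,
                                conf_level = 0.95, seed = NULL) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("predictor is constant")
  if (!is.null(seed)) set.seed(seed)

  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  rss <- sum((y - fitted)^2)
  tss <- sum((y - my)^2)

  if (tss == 0) {
    # constant response: no association by construction
    res <- list(slope = 0, intercept = my, r_squared = 0,
                permutation_p = 1, boot_ci = c(0, 0),
                aic = NA_real_, k = 3L, significant = FALSE,
                n = n, n_perm = n_perm, n_boot = n_boot)
    class(res) <- "arclakes_regression"
    return(res)
  }
  r_squared <- 1 - rss / tss
  aic <- n * log(rss / n) + 2 * 3

  xc <- x - mx
  perm_slopes <- vapply(seq_len(n_perm), function(i) {
    sum(xc * sample(y)) / sxx
  }, numeric(1))
  permutation_p <- (1 + sum(abs(perm_slopes) >= abs(slope))) / (n_perm + 1)

  boot_slopes <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    sb <- sum((xb - mean(xb))^2)
    if (sb == 0) return(NA_real_)
    sum((xb - mean(xb)) * (yb - mean(yb))) / sb
  }, numeric(1))
  boot_slopes <- boot_slopes[is.finite(boot_slopes)]
  alpha <- 1 - conf_level
  boot_ci <- unname(stats::quantile(boot_slopes,
                                    c(alpha / 2, 1 - alpha / 2)))

  res <- list(slope = slope, intercept = intercept, r_squared = r_squared,
              permutation_p = permutation_p, boot_ci = boot_ci,
              aic = aic, k = 3L,
              significant = permutation_p < 0.05 &&
                (boot_ci[1] > 0 || boot_ci[2] < 0),
              n = n, n_perm = n_perm, n_boot = n_boot)
  class(res) <- "arclakes_regression"
  res
}

#' @export
print.arclakes_regression <- function(x, ...) {
  cat(sprintf(
    "OLS fit (n = %d): slope = %.4g, R2 = %.3f, perm p = %.4g (%d perms)\n",
    x$n, x$slope, x$r_squared, x$permutation_p, x$n_perm))
  cat(sprintf("  95%% bootstrap CI on slope: [%.4g, %.4g] (%d resamples)\n",
              x$boot_ci[1], x$boot_ci[2], x$n_boot))
  cat(sprintf("  AIC = %.2f; significant (dual criterion): %s\n",
              x$aic, x$significant))
  invisible(x)
}

#' Select the best candidate fit by AIC
#'
#' Smallest AIC wins; ties are broken towards the model with fewest
#' parameters, then by position in the candidate list.
#'
#' @param fits Named list of fits, each carrying `aic` and `k` elements
#'   (e.g. [ols_permutation_fit()] results).
#' @return List with `best_index`, `best_name` (or `NA`), and `best` (the
#'   winning fit).
#' @export
aic_select <- function(fits) {
  if (length(fits) == 0) stop("no candidate fits supplied")
  aics <- vapply(fits, function(f) as.numeric(f$aic), numeric(1))
  ks <- vapply(fits, function(f) as.numeric(f$k %||% NA_real_), numeric(1))
  ord <- order(aics, ks, seq_along(fits))
  best <- ord[1]
  list(best_index = best,
       best_name = if (!is.null(names(fits))) names(fits)[best] else NA,
       best = fits[[best]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way PERMANOVA on 2-D isotope coordinates
#'
#' Permutational multivariate analysis of variance on the Euclidean
#' distances between (d13C, d15N) points. The pseudo-F statistic is
#' (SS_between / (a - 1)) / (SS_within / (N - a)), with sums of squares
#' obtained from squared inter-point distances (Gower identity). The p-value
#' permutes group labels, one-sided on F with the add-one rule.
#'
#' @param points_2d Numeric matrix or data frame, one row per sample, two
#'   columns (d13C, d15N). More than two columns are accepted.
#' @param groups Group labels, one per row; every group needs >= 2 points.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return List with `pseudo_f`, `p_value`, `ss_between`, `ss_within`,
#'   `df_between`, `df_within`, `n_perm`.
#' @export
permanova_one_way <- function(points_2d, groups, n_perm = 9999, seed = NULL) {
  pts <- as.matrix(points_2d)
  storage.mode(pts) <- "double"
  groups <- as.factor(groups)
  n <- nrow(pts)
  if (length(groups) != n) stop("groups must match rows of points")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(droplevels(groups)) < 2)) {
    stop("every group needs at least two points")
  }
  if (!is.null(seed)) set.seed(seed)
  d2 <- as.matrix(stats::dist(pts))^2
  ss_total <- sum(d2) / (2 * n)
  if (ss_total == 0) stop("all points identical; PERMANOVA undefined")
  a <- nlevels(droplevels(groups))

  ss_within_for <- function(g) {
    sw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  pseudo_f_for <- function(g) {
    sw <- ss_within_for(g)
    sb <- ss_total - sw
    (sb / (a - 1)) / (sw / (n - a))
  }
  g0 <- droplevels(groups)
  f_obs <- pseudo_f_for(g0)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    pseudo_f_for(g0[sample.int(n)])
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  sw <- ss_within_for(g0)
  list(pseudo_f = f_obs, p_value = p,
       ss_between = ss_total - sw, ss_within = sw,
       df_between = a - 1L, df_within = n - a, n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower triangles of two distance matrices,
#' with a two-sided permutation p-value obtained by simultaneously permuting
#' the rows and columns of the second matrix (add-one rule).
#'
#' @param d1,d2 Symmetric non-negative distance matrices with zero diagonals
#'   and matching dimensions (`dist` objects are accepted).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return List with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("distance matrices differ in dimension")
  check_dist <- function(m, name) {
    if (any(m < 0) || any(abs(diag(m)) > 1e-12) ||
        max(abs(m - t(m))) > 1e-8) {
      stop(name, " is not a valid distance matrix")
    }
  }
  check_dist(m1, "d1"); check_dist(m2, "d2")
  if (!is.null(seed)) set.seed(seed)
  tri <- lower.tri(m1)
  v1 <- m1[tri]
  if (stats::sd(v1) == 0 || stats::sd(m2[tri]) == 0) {
    stop("zero variance in a distance matrix; Mantel r undefined")
  }
  r_obs <- stats::cor(v1, m2[tri])
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(v1, m2[p, p][tri])
  }, numeric(1))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1)
  list(r = r_obs, p_value = p, n_perm = n_perm)
}

#' Two-way ANOVA with Type-II sums of squares
#'
#' Tests the effects of two crossed factors (e.g. lake category and
#' aquatic/terrestrial compartment) and their interaction on a response.
#' The study design is unbalanced, so Type-II sums of squares are used by
#' default: each main effect is adjusted for the other, the interaction
#' last. If some factor-level combinations are empty the interaction is
#' inestimable and is dropped with a warning.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible), same length as `values`.
#' @param ss_type Sums-of-squares type passed to [car::Anova()]; "II"
#'   (default) or "III".
#' @return Data frame of class `arclakes_anova` with columns `term`, `df`,
#'   `ss`, `f`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, ss_type = "II") {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("both factors need at least two levels")
  }
  dat <- data.frame(y = values, a = a, b = b)
  dat <- dat[stats::complete.cases(dat), ]
  with_interaction <- all(table(dat$a, dat$b) > 0)
  if (!with_interaction) {
    warning("empty factor cells: interaction inestimable, dropped")
    fit <- stats::lm(y ~ a + b, data = dat)
  } else {
    fit <- stats::lm(y ~ a * b, data = dat)
  }
  an <- car::Anova(fit, type = ss_type)
  terms <- rownames(an)
  keep <- terms != "Residuals"
  out <- data.frame(
    term = c("factor_a", "factor_b", if (with_interaction) "interaction"),
    df = an$Df[keep],
    ss = an$`Sum Sq`[keep],
    f = an$`F value`[keep],
    p = an$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("arclakes_anova", "data.frame")
  attr(out, "residual_df") <- an$Df[!keep]
  attr(out, "residual_ss") <- an$`Sum Sq`[!keep]
  out
}

#' Two-sample or paired t test
#'
#' Welch's t test for independent samples, or a paired t test. Degenerate
#' zero-variance inputs are resolved by convention rather than error: equal
#' constant samples give t = 0, p = 1; a constant non-zero paired difference
#' gives p ~ 0; both cases carry `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Logical; paired test?
#' @return List with `t`, `p_value`, `df`, `paired`, `degenerate`.
#' @export
t_test <- function(a, b, paired = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (paired && length(a) != length(b)) {
    stop("paired test requires equal lengths")
  }
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    delta <- if (paired) mean(a - b) else mean(a) - mean(b)
    if (delta == 0) {
      return(list(t = 0, p_value = 1, df = NA_real_, paired = paired,
                  degenerate = TRUE))
    }
    return(list(t = sign(delta) * Inf, p_value = 0, df = NA_real_,
                paired = paired, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), paired = paired, degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1). The
#' uncorrected statistic is used throughout the analysis.
#'
#' @param tab 2x2 matrix of non-negative integer counts; all row and column
#'   margins must be positive.
#' @return List with `chi2`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all table margins must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Screen collinear predictors and pick the best single predictor
#'
#' Reports variance-inflation factors among candidate predictors, then
#' reduces the candidates to single-predictor permutation-tested fits
#' compared by AIC. Perfectly collinear predictors get infinite VIF but both
#' remain in the single-predictor comparison.
#'
#' @param predictors Data frame (or matrix) of candidate predictors, >= 2
#'   columns.
#' @param response Numeric response vector.
#' @param ... Passed to [ols_permutation_fit()] (e.g. `n_perm`, `seed`).
#' @return List with `vif` (named vector), `fits` (named list of
#'   single-predictor fits), `best_name`, `best`.
#' @export
collinearity_screen <- function(predictors, response, ...) {
  preds <- as.data.frame(predictors)
  if (ncol(preds) < 2) stop("need at least two candidate predictors")
  vif <- vapply(seq_along(preds), function(j) {
    others <- as.matrix(preds[, -j, drop = FALSE])
    fit <- stats::lm.fit(cbind(1, others), preds[[j]])
    rss <- sum(fit$residuals^2)
    tss <- sum((preds[[j]] - mean(preds[[j]]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(preds)
  if (any(!is.finite(vif))) {
    warning("perfectly collinear predictors detected (infinite VIF)")
  }
  fits <- lapply(preds, function(p) ols_permutation_fit(p, response, ...))
  sel <- aic_select(fits)
  list(vif = vif, fits = fits, best_name = sel$best_name, best = sel$best)
}
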