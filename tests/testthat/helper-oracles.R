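# Independent oracles used across the suite. These re-derive quantities by
# brute force or closed form, without calling the implementation paths they
# check.

# walk every cell's D8 path step by step; TRUE if it reaches the lake
oracle_catchment <- function(direction, lake_mask) {
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  nr <- nrow(direction); nc <- ncol(direction)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(direction[r, c])) next
      cr <- r; cc <- c
      for (step in seq_len(nr * nc + 1)) {
        if (lake_mask[cr, cc]) { out[r, c] <- TRUE; break }
        d <- direction[cr, cc]
        if (is.na(d) || d == 0) break
        cr <- cr + dr[d]; cc <- cc + dc[d]
        if (step > nr * nc) stop("oracle: path did not terminate")
      }
    }
  }
  out
}

# PERMANOVA sums of squares from group centroids (Euclidean geometry only)
oracle_permanova_ss <- function(points, groups) {
  pts <- as.matrix(points)
  groups <- as.factor(groups)
  grand <- colMeans(pts)
  ss_within <- 0; ss_between <- 0
  for (lev in levels(groups)) {
    sub <- pts[groups == lev, , drop = FALSE]
    cen <- colMeans(sub)
    ss_within <- ss_within + sum(sweep(sub, 2, cen)^2)
    ss_between <- ss_between + nrow(sub) * sum((cen - grand)^2)
  }
  list(ss_between = ss_between, ss_within = ss_within)
}

# exhaustive permutation p-value for the OLS slope, two-sided, n! small
oracle_exhaustive_ols_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  slope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  b0 <- abs(slope(x, y))
  bs <- vapply(perms(y), function(p) abs(slope(x, p)), numeric(1))
  mean(bs >= b0 - 1e-12)
}

# deterministic grid integration of the two-source mixing posterior
oracle_two_source_posterior_mean <- function(consumers, sources, tef,
                                             alpha = c(1, 1),
                                             n_grid = 2001) {
  obs13 <- consumers$d13c; obs15 <- consumers$d15n
  mu13 <- sources$mean_d13c + tef$d13c_mean
  v13 <- sources$sd_d13c^2 + tef$d13c_sd^2
  mu15 <- sources$mean_d15n + tef$d15n_mean
  v15 <- sources$sd_d15n^2 + tef$d15n_sd^2
  p1 <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  lp <- vapply(p1, function(p) {
    pv <- c(p, 1 - p)
    m13 <- sum(pv * mu13); s13 <- sum(pv^2 * v13)
    m15 <- sum(pv * mu15); s15 <- sum(pv^2 * v15)
    sum(dnorm(obs13, m13, sqrt(s13), log = TRUE)) +
      sum(dnorm(obs15, m15, sqrt(s15), log = TRUE)) +
      (alpha[1] - 1) * log(p) + (alpha[2] - 1) * log(1 - p)
  }, numeric(1))
  w <- exp(lp - max(lp))
  sum(w * p1) / sum(w)
}

# brute-force buffer: double loop over all cell pairs
oracle_buffer <- function(lake_mask, distance_m, cell_size) {
  nr <- nrow(lake_mask); nc <- ncol(lake_mask)
  lk <- which(lake_mask, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (lake_mask[r, c]) next
      dmin <- min(sqrt((lk[, 1] - r)^2 + (lk[, 2] - c)^2)) * cell_size
      out[r, c] <- dmin <= distance_m
    }
  }
  out
}

# Type-II two-way ANOVA by nested model comparison (lm only)
oracle_type2_anova <- function(y, a, b) {
  d <- data.frame(y = y, a = as.factor(a), b = as.factor(b))
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = d))^2)
  full <- stats::lm(y ~ a * b, data = d)
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  ms_res <- rss_full / df_res
  ss_a <- rss(y ~ b) - rss(y ~ a + b)
  ss_b <- rss(y ~ a) - rss(y ~ a + b)
  ss_ab <- rss(y ~ a + b) - rss_full
  df_a <- nlevels(d$a) - 1; df_b <- nlevels(d$b) - 1
  df_ab <- df_a * df_b
  data.frame(term = c("factor_a", "factor_b", "interaction"),
             f = c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / ms_res)
}

# tiny fixture builders ------------------------------------------------------

make_sources <- function(d13c = c(-25, -15), d15n = c(5, 10),
                         sd13 = 0.5, sd15 = 0.5) {
  data.frame(name = paste0("s", seq_along(d13c)),
             mean_d13c = d13c, sd_d13c = sd13,
             mean_d15n = d15n, sd_d15n = sd15,
             stringsAsFactors = FALSE)
}

tef_zero <- function() trophic_enrichment(0, 0, 0, 0)
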