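test_that("an exact linear relation is detected as significant", {
  x <- 1:10
  fit <- ols_permutation_fit(x, 2 * x, n_perm = 999, n_boot = 499, seed = 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$permutation_p, 0.01)
  expect_true(fit$significant)
  expect_true(fit$boot_ci[1] > 0)
})

test_that("degenerate regressions are resolved by convention", {
  fit <- ols_permutation_fit(1:8, rep(3, 8), n_perm = 99, n_boot = 99)
  expect_equal(fit$slope, 0)
  expect_equal(fit$permutation_p, 1)
  expect_false(fit$significant)
  expect_error(ols_permutation_fit(rep(1, 5), 1:5), "constant")
  expect_error(ols_permutation_fit(1:2, 1:2), "at least 3")
})

test_that("sampled permutation p agrees with the exhaustive p at n = 6", {
  set.seed(8)
  x <- rnorm(6); y <- 0.8 * x + rnorm(6, 0, 1)
  p_exh <- oracle_exhaustive_ols_p(x, y)
  fit <- ols_permutation_fit(x, y, n_perm = 1999, n_boot = 99, seed = 2)
  mc_sd <- sqrt(p_exh * (1 - p_exh) / 1999)
  expect_lt(abs(fit$permutation_p - p_exh), 3 * mc_sd + 1e-3)
  # the add-one rule keeps p strictly positive
  perfect <- ols_permutation_fit(1:6, (1:6) * 3, n_perm = 999, n_boot = 99,
                                 seed = 3)
  expect_gt(perfect$permutation_p, 0)
})

test_that("AIC selection finds the true predictor", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 20
    x_true <- rnorm(n); x_noise <- rnorm(n)
    y <- 1.5 * x_true + rnorm(n, 0, 1)
    fits <- list(
      true = ols_permutation_fit(x_true, y, n_perm = 49, n_boot = 49),
      noise = ols_permutation_fit(x_noise, y, n_perm = 49, n_boot = 49))
    if (aic_select(fits)$best_name == "true") hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_error(aic_select(list()), "no candidate")
})

test_that("PERMANOVA decomposition equals the centroid oracle", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(12, 0), ncol = 2),
               matrix(rnorm(12, 2), ncol = 2),
               matrix(rnorm(12, 4), ncol = 2))
  groups <- rep(letters[1:3], each = 6)
  res <- permanova_one_way(pts, groups, n_perm = 199, seed = 1)
  want <- oracle_permanova_ss(pts, groups)
  expect_equal(res$ss_between, want$ss_between)
  expect_equal(res$ss_within, want$ss_within)
  expect_equal(res$df_between, 2L)
  expect_equal(res$df_within, 15L)

  # duplicating every point changes F only through the degrees of freedom
  pts2 <- rbind(pts, pts); groups2 <- c(groups, groups)
  res2 <- permanova_one_way(pts2, groups2, n_perm = 199, seed = 1)
  want2 <- oracle_permanova_ss(pts2, groups2)
  expect_equal(res2$ss_between, want2$ss_between)
  expect_equal(res2$ss_within, want2$ss_within)
  f_manual <- (want2$ss_between / 2) / (want2$ss_within / (36 - 3))
  expect_equal(res2$pseudo_f, f_manual)
})

test_that("PERMANOVA agrees with the reference implementation", {
  set.seed(6)
  pts <- rbind(matrix(rnorm(16, 0), ncol = 2),
               matrix(rnorm(16, 1.5), ncol = 2))
  groups <- rep(c("a", "b"), each = 8)
  res <- permanova_one_way(pts, groups, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(dist(pts) ~ g,
                        data = data.frame(g = groups), permutations = 999)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("separated groups give maximal pseudo-F and the tie-count p", {
  pts <- rbind(matrix(c(0, 0, 0, 0, 0, 0), ncol = 2),
               matrix(c(5, 5, 5, 5, 5, 5), ncol = 2))
  groups <- rep(c("a", "b"), each = 3)
  res <- permanova_one_way(pts + matrix(rnorm(12, 0, 1e-9), ncol = 2),
                           groups, n_perm = 1999, seed = 7)
  # label permutations preserving the partition: 3! * 3! * 2 of 6! = 0.1
  expect_lt(abs(res$p_value - 0.1), 3 * sqrt(0.1 * 0.9 / 1999))
  expect_error(permanova_one_way(pts, c("a", rep("b", 5)), 99), "two points")
  expect_error(permanova_one_way(matrix(0, 6, 2), groups, 99), "identical")
})

test_that("Mantel r is 1 for identical and affine matrices", {
  set.seed(9)
  d1 <- dist(matrix(rnorm(20), ncol = 2))
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(d1, 3 * d1 + 0, n_perm = 99, seed = 1)$r, 1)
  res <- mantel_test(d1, dist(matrix(rnorm(20), ncol = 2)),
                     n_perm = 999, seed = 2)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(mantel_test(d1, dist(rep(0, 10))), "zero variance")
  expect_error(mantel_test(matrix(1, 3, 3), matrix(1, 4, 4)), "dimension")
})

test_that("Mantel agrees with the reference implementation on r", {
  set.seed(10)
  d1 <- dist(matrix(rnorm(24), ncol = 2))
  d2 <- dist(matrix(rnorm(24), ncol = 2))
  mine <- mantel_test(d1, d2, n_perm = 999, seed = 3)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("two-way ANOVA reproduces hand-computed balanced F values", {
  # balanced 2x2 with 3 replicates per cell
  y <- c(10, 11, 12,  14, 15, 16,  20, 21, 22,  30, 31, 32)
  a <- rep(c("a1", "a2"), each = 6)
  b <- rep(rep(c("b1", "b2"), each = 3), 2)
  got <- two_way_anova(y, a, b)
  want <- oracle_type2_anova(y, a, b)
  expect_equal(got$f, want$f, tolerance = 1e-10)
  # equal cell means with within-cell noise: every F collapses to zero
  flat <- two_way_anova(rep(c(4, 5, 6), 4), a, b)
  expect_true(all(flat$f < 1e-20))
  expect_true(all(flat$p > 0.9))
})

test_that("unbalanced Type-II ANOVA equals the nested-RSS oracle", {
  set.seed(12)
  a <- sample(c("x", "y", "z"), 40, replace = TRUE)
  b <- sample(c("aq", "terr"), 40, replace = TRUE)
  y <- rnorm(40) + ifelse(b == "aq", 1.5, 0)
  got <- two_way_anova(y, a, b)
  want <- oracle_type2_anova(y, a, b)
  expect_equal(got$f, want$f, tolerance = 1e-10)
  # empty cell: interaction dropped with a warning
  bad_a <- c(rep("x", 20), rep("y", 20))
  bad_b <- c(rep("aq", 20), rep("terr", 20))
  expect_warning(res <- two_way_anova(rnorm(40), bad_a, bad_b), "empty")
  expect_false("interaction" %in% res$term)
})

test_that("t tests match Welch closed form and handle degeneracy", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  got <- t_test(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 5)^2 / 4)
  expect_equal(got$t, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # identical groups
  same <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # paired with constant non-zero difference
  pair <- t_test(c(1, 2, 3), c(2, 3, 4), paired = TRUE)
  expect_true(pair$degenerate)
  expect_equal(pair$p_value, 0)
  # paired with zero difference
  pair0 <- t_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(pair0$p_value, 1)
})

test_that("Pearson chi-square on 2x2 tables is uncorrected", {
  expect_equal(chi_square_2x2(matrix(c(9, 3, 0, 6), 2))$chi2, 9)
  expect_equal(chi_square_2x2(matrix(c(5, 5, 5, 5), 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$chi2, 20)
  expect_equal(chi_square_2x2(matrix(c(9, 3, 0, 6), 2))$df, 1)
  expect_error(chi_square_2x2(matrix(c(9, 3, 0, 0), 2, byrow = TRUE)),
               "margins")
  expect_error(chi_square_2x2(matrix(1, 3, 3)), "2x2")
})

test_that("collinearity screen flags VIFs and picks the real predictor", {
  set.seed(13)
  x <- rnorm(30)
  expect_warning(
    res <- collinearity_screen(data.frame(a = x, b = x),
                               2 * x + rnorm(30), n_perm = 49, n_boot = 49),
    "collinear")
  expect_true(any(!is.finite(res$vif)))
  # orthogonal predictors have VIF 1
  x2 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  x3 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  res2 <- collinearity_screen(data.frame(a = x2, b = x3),
                              rnorm(8), n_perm = 49, n_boot = 49)
  expect_equal(unname(res2$vif), c(1, 1))
  # true predictor wins in simulation
  hits <- 0
  for (s in 1:100) {
    set.seed(100 + s)
    xt <- rnorm(20); xn <- rnorm(20)
    y <- xt + rnorm(20, 0, 0.8)
    r <- collinearity_screen(data.frame(true = xt, noise = xn), y,
                             n_perm = 19, n_boot = 19)
    if (r$best_name == "true") hits <- hits + 1
  }
  expect_gte(hits, 95)
})
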