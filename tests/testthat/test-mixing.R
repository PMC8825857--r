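test_that("mixture likelihood matches the closed form for one source", {
  src <- make_sources(d13c = -24, d15n = 6, sd13 = 0.8, sd15 = 0.4)
  tef <- trophic_enrichment()
  obs <- data.frame(d13c = -24 + tef$d13c_mean, d15n = 6 + tef$d15n_mean)
  got <- mixture_likelihood(obs, 1, src, tef)
  want <- dnorm(0, 0, sqrt(0.8^2 + tef$d13c_sd^2), log = TRUE) +
    dnorm(0, 0, sqrt(0.4^2 + tef$d15n_sd^2), log = TRUE)
  expect_equal(got, want)
})

test_that("likelihood peaks at the even mixture for symmetric sources", {
  src <- make_sources(d13c = c(-25, -15), d15n = c(4, 8))
  obs <- data.frame(d13c = -20, d15n = 6)  # exact midpoint
  grid <- seq(0.01, 0.99, by = 0.01)
  ll <- vapply(grid, function(p) {
    mixture_likelihood(obs, c(p, 1 - p), src, tef_zero())
  }, numeric(1))
  expect_equal(grid[which.max(ll)], 0.5)
  # moving the observation away from the mixture mean never helps
  p <- c(0.3, 0.7)
  base <- mixture_likelihood(data.frame(d13c = -18, d15n = 6.8),
                             p, src, tef_zero())
  for (shift in c(0.5, 1, 3)) {
    worse <- mixture_likelihood(data.frame(d13c = -18 - shift,
                                           d15n = 6.8 + shift),
                                p, src, tef_zero())
    expect_lt(worse, base)
  }
  expect_error(mixture_likelihood(obs, c(0.6, 0.6), src, tef_zero()),
               "simplex")
})

test_that("degenerate zero-variance mixtures are flagged", {
  src <- make_sources(d13c = c(-25, -15), d15n = c(4, 8),
                      sd13 = 0, sd15 = 0)
  obs <- data.frame(d13c = -24, d15n = 4.2)
  expect_warning(ll <- mixture_likelihood(obs, c(1, 0), src, tef_zero()),
                 "zero mixture variance")
  expect_identical(ll, -Inf)
})

test_that("single-source posterior is a point mass", {
  src <- make_sources(d13c = -24, d15n = 6)
  post <- fit_diet_mcmc(data.frame(d13c = -23.6, d15n = 8.3), src)
  expect_equal(unname(post$draws[, 1]), 1)
  expect_equal(trophic_link_count(post), 1L)
})

test_that("two-source posterior matches deterministic grid integration", {
  cfg <- mixing_config(n_chains = 2, n_iter = 6000, n_burn = 2000,
                       thin = 2, seed = 21)
  src <- make_sources(d13c = c(-25, -15), d15n = c(5, 5))
  # consumer at the midpoint: both routes must say half and half
  cons_mid <- data.frame(d13c = -20, d15n = 5)
  post_mid <- fit_diet_mcmc(cons_mid, src, tef_zero(), cfg)
  expect_equal(post_mid$summary$mean[1], 0.5, tolerance = 0.05)
  oracle_mid <- oracle_two_source_posterior_mean(cons_mid, src, tef_zero())
  expect_equal(post_mid$summary$mean[1], oracle_mid, tolerance = 0.02)
  # asymmetric consumer
  cons_asym <- data.frame(d13c = c(-23, -22.4), d15n = c(5.2, 4.9))
  post_asym <- fit_diet_mcmc(cons_asym, src, tef_zero(), cfg)
  oracle_asym <- oracle_two_source_posterior_mean(cons_asym, src, tef_zero())
  expect_equal(post_asym$summary$mean[1], oracle_asym, tolerance = 0.02)
})

test_that("draws stay on the simplex and are reproducible from the seed", {
  src <- make_sources(d13c = c(-26, -22, -18), d15n = c(3, 6, 9))
  cons <- data.frame(d13c = c(-22.5, -23.1, -21.8), d15n = c(6.1, 5.7, 6.4))
  cfg <- mixing_config(n_chains = 2, n_iter = 2000, n_burn = 1000, seed = 9)
  p1 <- suppressWarnings(fit_diet_mcmc(cons, src, trophic_enrichment(), cfg))
  p2 <- suppressWarnings(fit_diet_mcmc(cons, src, trophic_enrichment(), cfg))
  expect_identical(p1$draws, p2$draws)
  expect_true(all(abs(rowSums(p1$draws) - 1) < 1e-9))
  expect_true(all(p1$draws >= 0))
  # summaries are consistent with the draws
  expect_equal(p1$summary$mean, unname(colMeans(p1$draws)))
})

test_that("diffuse data returns the Dirichlet prior mean", {
  src <- make_sources(d13c = c(-25, -20, -15), d15n = c(4, 6, 8),
                      sd13 = 100, sd15 = 100)
  cons <- data.frame(d13c = -21, d15n = 6)
  cfg <- mixing_config(n_chains = 3, n_iter = 8000, n_burn = 3000,
                       thin = 2, seed = 4)
  post <- fit_diet_mcmc(cons, src, tef_zero(), cfg)
  expect_equal(post$summary$mean, rep(1 / 3, 3), tolerance = 0.05)
})

test_that("link counting applies the median threshold rule", {
  fake <- structure(list(
    summary = data.frame(source = letters[1:5],
                         median = c(0.50, 0.30, 0.15, 0.04, 0.01)),
    config = list(link_threshold = 0.05)), class = "diet_posterior")
  expect_equal(trophic_link_count(fake), 3)
  expect_equal(trophic_link_count(fake, link_threshold = 0), 5)
})

test_that("food chain length is the per-lake TP and its maximum", {
  tps <- c(a = 2.0, b = 2.4, c = 2.9)
  fcl <- food_chain_length(tps)
  expect_equal(fcl$per_lake, tps)
  expect_equal(fcl$max_fcl, 2.9)
  expect_equal(food_chain_length(2.2)$max_fcl, 2.2)
  expect_equal(food_chain_length(rev(tps))$max_fcl, fcl$max_fcl)
  expect_error(food_chain_length(numeric(0)))
})
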