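small_cfg <- function(seed = 2, ...) {
  study_config(grid_shape = c(40, 40), seed = seed, ...)
}

test_that("the generator is deterministic in (config, seed)", {
  cfg <- small_cfg()
  g1 <- generate_study(cfg)
  g2 <- generate_study(cfg)
  expect_identical(g1, g2)
  g3 <- generate_study(small_cfg(seed = 3))
  expect_false(identical(g1$study$samples, g3$study$samples))
})

test_that("planted snow-cell counts realise the ground-truth FSC", {
  cfg <- small_cfg()
  truth <- arclakes:::.plant_truth(cfg)
  dem <- generate_dem(5, cfg)
  n_land <- sum(!dem$lake_mask)
  for (m in c("Apr", "May", "Jun", "Aug")) {
    sc <- generate_scene(5, m, cfg, truth = truth, dem = dem)
    expect_lte(abs(sum(sc$snow_mask) - truth$fsc[5, m] * n_land), 1)
  }
  # saturated and empty cases
  truth$fsc[5, "Jun"] <- 1
  sc1 <- generate_scene(5, "Jun", cfg, truth = truth, dem = dem)
  expect_true(all(sc1$snow_mask[!dem$lake_mask]))
  snow1 <- classify_snow(ndsi(sc1$green, sc1$swir), sc1$red)
  expect_true(all(snow1[!dem$lake_mask]))
  truth$fsc[5, "Jun"] <- 0
  sc0 <- generate_scene(5, "Jun", cfg, truth = truth, dem = dem)
  expect_equal(sum(sc0$snow_mask), 0)
  expect_error(generate_scene(5, "Sep", cfg, truth, dem), "unknown month")
})

test_that("component d15N is shifted by the droppings slope", {
  cfg <- small_cfg()
  truth <- arclakes:::.plant_truth(cfg)
  expect_equal(truth$sed_d15n - 1.5,
               cfg$d15n_droppings_slope * truth$droppings)
  expect_equal(truth$soil_d15n - 1.0,
               cfg$d15n_droppings_slope * truth$droppings)
  # a rank-4 versus rank-0 lake differs by slope * 4 = 3 per mil
  expect_equal(cfg$d15n_droppings_slope * 4, 3)
})

test_that("noise-free pure diets give exact TEF-shifted consumers", {
  diets <- matrix(rep(c(1, 0, 0), 18), ncol = 3, byrow = TRUE,
                  dimnames = list(NULL,
                                  c("sediment", "daphnia",
                                    "vegetation_aquatic")))
  cfg <- small_cfg(
    true_diets = diets,
    source_d13c_sd = c(0, 0, 0), source_d15n_sd = c(0, 0, 0),
    tef = trophic_enrichment(d13c_sd = 0, d15n_sd = 0))
  truth <- arclakes:::.plant_truth(cfg)
  i <- which(truth$template$has_lepidurus)[1]
  s <- generate_foodweb_samples(i, cfg, truth)
  cons <- s[s$component == "lepidurus", ]
  src <- truth$sources[[i]]
  expect_equal(unique(cons$d13c),
               src$mean_d13c[src$name == "sediment"] + cfg$tef$d13c_mean)
  expect_equal(unique(cons$d15n),
               src$mean_d15n[src$name == "sediment"] + cfg$tef$d15n_mean)
})

test_that("consumer sample spread reflects the planted mixture SD", {
  cfg <- small_cfg(seed = 6)
  truth <- arclakes:::.plant_truth(cfg)
  i <- which(truth$template$has_lepidurus)[1]
  s <- generate_foodweb_samples(i, cfg, truth)
  cons <- s[s$component == "lepidurus", ]
  expect_equal(nrow(cons), cfg$n_consumers)
  p <- truth$diets[i, ]
  src <- truth$sources[[i]]
  planted_sd13 <- sqrt(sum(p^2 * (src$sd_d13c^2 + cfg$tef$d13c_sd^2)))
  planted_sd15 <- sqrt(sum(p^2 * (src$sd_d15n^2 + cfg$tef$d15n_sd^2)))
  expect_lt(abs(sd(cons$d13c) - planted_sd13), 0.5 * planted_sd13)
  expect_lt(abs(sd(cons$d15n) - planted_sd15), 0.5 * planted_sd15)
})

test_that("the delineated catchment realises the published L/C ratio", {
  cfg <- small_cfg()
  for (i in c(2, 14, 18)) {  # lc 0.24, 0.27, 0.01
    d <- generate_dem(i, cfg)
    flow <- d8_flow_directions(fill_depressions(d$dem), cfg$cell_size)
    catch <- delineate_catchment(flow, d$lake_mask)
    lc <- openness_ratio(catch$lake_area_m2, catch$area_m2)
    expect_equal(round(lc, 2), arclakes:::.lake_template(cfg)$lc_ratio[i])
  }
})

test_that("study bundles cover every configured lake and month", {
  cfg <- small_cfg()
  g <- generate_study(cfg)
  expect_length(g$study$dems, 18)
  expect_length(g$study$scenes, 18)
  expect_true(all(vapply(g$study$scenes, length, integer(1)) == 4))
  expect_setequal(unique(g$study$samples$lake_id), 1:18)
  expect_equal(nrow(g$study$droppings), 18)
  # ground-truth invariants
  expect_true(all(g$truth$fsc >= 0 & g$truth$fsc <= 1))
  expect_true(all(g$truth$true_tp >= 1, na.rm = TRUE))
  expect_true(all(abs(rowSums(g$truth$diets) - 1) < 1e-9))
})

test_that("invalid configurations are rejected", {
  expect_error(study_config(n_lakes = 3), "n_lakes")
  expect_error(study_config(fsc_sd = -1), ">= 0")
  bad <- matrix(rep(c(0.5, 0.4, 0.2), 18), ncol = 3, byrow = TRUE)
  cfg <- small_cfg(true_diets = bad)
  expect_error(arclakes:::.plant_truth(cfg), "sum to 1")
})
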