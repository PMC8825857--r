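test_that("NDVI and NDSI follow the normalised-difference formulas", {
  expect_equal(ndvi(matrix(0.5), matrix(0.1))[1, 1], 2 / 3)
  expect_equal(ndvi(matrix(0.3), matrix(0.3))[1, 1], 0)
  expect_true(is.na(ndvi(matrix(0), matrix(0))[1, 1]))
  expect_equal(ndsi(matrix(0.8), matrix(0.1))[1, 1], 7 / 9)
  expect_equal(ndsi(matrix(0.4), matrix(0.4))[1, 1], 0)
  expect_equal(ndsi(matrix(0.6), matrix(0))[1, 1], 1)
  expect_error(ndvi(matrix(0, 2, 2), matrix(0, 3, 3)), "co-registered")
  # bounds wherever defined
  set.seed(1)
  a <- matrix(runif(100), 10); b <- matrix(runif(100), 10)
  v <- ndvi(a, b)
  expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
})

test_that("snow classification needs both bright NDSI and bright Red", {
  nd <- matrix(c(0.9, 0.9, 0.1, 0.5), 2)
  red <- matrix(c(0.7, 0.05, 0.7, 0.25), 2)
  snow <- classify_snow(nd, red)
  expect_true(snow[1, 1])    # snow: both tests pass
  expect_false(snow[2, 1])   # dark water: high NDSI, fails the Red test
  expect_false(snow[1, 2])   # low NDSI
  expect_true(snow[2, 2])
  expect_error(classify_snow(nd, red, thresholds = c(2, 0.2)), "range")
})

test_that("snow-cover fraction counts catchment land cells only", {
  catch <- matrix(TRUE, 10, 10)
  lake <- matrix(FALSE, 10, 10); lake[5:6, 5:6] <- TRUE
  all_snow <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(snow_cover_fraction(all_snow, catch, lake), 1)
  expect_equal(snow_cover_fraction(none, catch, lake), 0)
  part <- none; part[1:2, ] <- TRUE  # 20 land cells of 96
  expect_equal(snow_cover_fraction(part, catch, lake), 20 / 96)
  # monotone: adding snow never decreases FSC
  more <- part; more[3, 1:5] <- TRUE
  expect_gte(snow_cover_fraction(more, catch, lake),
             snow_cover_fraction(part, catch, lake))
  expect_error(snow_cover_fraction(none, matrix(FALSE, 10, 10)), "land")
})

test_that("lake buffer matches the brute-force distance oracle", {
  # isolated single lake cell, 100 m on 10 m cells: all cells within radius 10
  lake <- matrix(FALSE, 25, 25); lake[13, 13] <- TRUE
  buf <- lake_buffer(lake, 100, 10)
  expect_equal(buf, oracle_buffer(lake, 100, 10))
  expect_false(any(buf & lake))  # exclusion contract
  # distance below half a cell reaches no neighbouring centre
  expect_true(all(!lake_buffer(lake, 4, 10)))
  # irregular lake shape
  set.seed(3)
  lake2 <- matrix(runif(625) < 0.05, 25, 25)
  lake2[1, 1] <- TRUE
  expect_equal(lake_buffer(lake2, 35, 10), oracle_buffer(lake2, 35, 10))
  expect_error(lake_buffer(matrix(FALSE, 5, 5), 100, 10), "empty")
})

test_that("NDVI summaries combine months, buffer and catchment correctly", {
  n <- 12
  catch <- matrix(TRUE, n, n)
  lake <- matrix(FALSE, n, n); lake[6:7, 6:7] <- TRUE
  buf <- lake_buffer(lake, 2.5, 1)
  uni <- function(v) matrix(v, n, n)
  # spatially uniform NDVI in all months: every summary collapses to it
  s <- ndvi_summaries(list(Jun = uni(0.4), Aug = uni(0.4)), catch, lake, buf)
  expect_equal(s$mean_ndvi, 0.4)
  expect_equal(s$near_lake_ndvi, 0.4)
  expect_equal(s$catchment_ndvi, 0.4)
  expect_equal(s$delta_ndvi, 0)
  expect_equal(s$seasonal_change, 0)
  # planted contrast: buffer at 0.2, outer catchment at 0.5 in August
  aug <- uni(0.5); aug[buf] <- 0.2
  s2 <- ndvi_summaries(list(Jun = uni(0.5), Aug = aug), catch, lake, buf)
  expect_equal(s2$delta_ndvi, -0.3)
  expect_equal(s2$seasonal_change, -0.3)
  # partition identity: buffer + outer + lake = catchment
  expect_equal(sum(buf & catch & !lake) + sum(catch & !lake & !buf) +
                 sum(lake), sum(catch))
  # lake cells never contribute: poisoning them changes nothing
  aug_poison <- aug; aug_poison[lake] <- 99
  s3 <- ndvi_summaries(list(Jun = uni(0.5), Aug = aug_poison),
                       catch, lake, buf)
  expect_equal(s3$near_lake_ndvi, s2$near_lake_ndvi)
  expect_equal(s3$catchment_ndvi, s2$catchment_ndvi)
  expect_error(ndvi_summaries(list(Aug = aug), catch, lake, buf), "Jun")
})

test_that("classifier recovers the planted snow mask on synthetic scenes", {
  cfg <- study_config(grid_shape = c(40, 40), seed = 5)
  for (i in c(1, 9, 16)) {
    dem <- generate_dem(i, cfg)
    for (m in c("Apr", "Jun", "Aug")) {
      sc <- generate_scene(i, m, cfg, dem = dem)
      snow <- classify_snow(ndsi(sc$green, sc$swir), sc$red)
      expect_equal(snow, sc$snow_mask)
    }
  }
})
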