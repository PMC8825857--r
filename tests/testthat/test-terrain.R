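test_that("depression filling raises pits to their pour points only", {
  # monotone tilted plane: no pits, returned unchanged
  plane <- outer(1:6, 1:6, function(r, c) r + 2 * c)
  expect_equal(fill_depressions(plane), plane)

  # hand case: centre pit of depth 2 m below its lowest pour point (3 m)
  pit <- matrix(c(5, 5, 5,
                  5, 1, 3,
                  5, 5, 5), 3, 3, byrow = TRUE)
  filled <- fill_depressions(pit)
  expect_equal(filled[2, 2], 3)
  expect_equal(filled[-5], pit[-5])  # all other cells untouched

  # filled >= original, idempotent
  set.seed(7)
  rough <- matrix(rnorm(400), 20, 20) + outer(1:20, 1:20, `+`) / 5
  f1 <- fill_depressions(rough)
  expect_true(all(f1 >= rough - 1e-12))
  expect_equal(fill_depressions(f1), f1)
  expect_error(fill_depressions(matrix(NA_real_, 3, 3)), "nodata")
})

test_that("a plane tilted due south drains south", {
  nr <- 7; nc <- 5
  dem <- matrix(rep(rev(seq_len(nr)), nc), nr, nc)
  flow <- d8_flow_directions(fill_depressions(dem), cell_size = 1)
  interior <- flow$direction[2:(nr - 1), 2:(nc - 1)]
  expect_true(all(interior == 3))  # code 3 = S
  expect_true(all(flow$direction[nr, ] == 0))  # south edge is the outlet
})

test_that("V-shaped valley accumulates monotonically downstream", {
  dem <- outer(1:9, 1:9, function(r, c) 2 * abs(r - 5) + 0.1 * (10 - c))
  flow <- d8_flow_directions(fill_depressions(dem), cell_size = 1)
  axis_acc <- flow$accumulation[5, ]
  # hand-traced: each column funnels 9 cells into the axis, then east
  expect_equal(axis_acc, 9 * (1:9))
  expect_true(all(diff(axis_acc) > 0))
  expect_equal(max(flow$accumulation), 81)
})

test_that("accumulation satisfies the conservation identities", {
  set.seed(11)
  dem <- fill_depressions(matrix(rnorm(625), 25, 25) +
                            outer(1:25, 1:25, `+`) / 4)
  flow <- d8_flow_directions(dem, cell_size = 1)
  dirs <- flow$direction
  acc <- flow$accumulation
  # sum over outlets equals the number of defined cells
  expect_equal(sum(acc[dirs == 0]), sum(!is.na(dirs)))
  # acc = 1 + sum of inflowing neighbours, recomputed independently
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  for (r in 2:24) {
    for (c in 2:24) {
      inflow <- 0
      for (k in 1:8) {
        rn <- r - dr[k]; cn <- c - dc[k]  # neighbour that points via k to us
        if (dirs[rn, cn] == k) inflow <- inflow + acc[rn, cn]
      }
      expect_equal(acc[r, c], 1 + inflow)
    }
  }
})

test_that("catchment of a corner-low plane is the whole grid", {
  dem <- outer(1:8, 1:8, `+`)
  lake <- matrix(FALSE, 8, 8); lake[1, 1] <- TRUE
  flow <- d8_flow_directions(fill_depressions(dem), cell_size = 10)
  catch <- delineate_catchment(flow, lake)
  expect_true(all(catch$mask))
  expect_equal(catch$area_m2, 64 * 100)
  expect_equal(catch$lake_area_m2, 100)
  expect_error(delineate_catchment(flow, matrix(FALSE, 8, 8)), "empty")
})

test_that("a ridge partitions the grid into disjoint catchments", {
  dem <- outer(1:9, 1:9, function(r, c) 5 - abs(c - 5) - 0.01 * r)
  dem <- fill_depressions(dem)
  flow <- d8_flow_directions(dem, cell_size = 1)
  west <- matrix(FALSE, 9, 9); west[9, 1] <- TRUE
  east <- matrix(FALSE, 9, 9); east[9, 9] <- TRUE
  cw <- delineate_catchment(flow, west)
  ce <- delineate_catchment(flow, east)
  expect_false(any(cw$mask & ce$mask))        # disjoint
  expect_true(all(cw$mask | ce$mask))         # and exhaustive
  expect_false(ce$mask[2, 2])                 # far side of the divide
  expect_true(cw$mask[2, 2])
})

test_that("delineation equals the brute-force flow-path oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(20, 24, 30)[seed]
    base <- outer(seq_len(n), seq_len(n), function(r, c) {
      0.5 * sqrt((r - n)^2 + (c - n / 2)^2)
    })
    dem <- fill_depressions(base + matrix(rnorm(n * n, 0, 0.2), n, n))
    flow <- d8_flow_directions(dem, cell_size = 1)
    lake <- matrix(FALSE, n, n)
    lake[(n - 2):n, floor(n / 2) + (-1:1)] <- TRUE
    got <- delineate_catchment(flow, lake)$mask
    want <- oracle_catchment(flow$direction, lake)
    expect_equal(got, want | lake)
  }
})

test_that("lake-to-catchment ratio matches the published extremes", {
  # smallest and largest study lakes (areas in km^2, printed in the text)
  expect_equal(openness_ratio(0.002, 0.010), 0.20)
  expect_equal(openness_ratio(0.160, 5.350), 0.0299, tolerance = 1e-3)
  expect_equal(openness_ratio(1500, 1500), 1)
  expect_error(openness_ratio(2, 1), "exceed")
  expect_error(openness_ratio(0, 1), "positive")
})
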