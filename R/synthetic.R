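# Seeded synthetic-study generator.
#
# The generator emulates the 18-lake Svalbard study at desk scale: each lake
# keeps its published distance from the coast, lake-to-catchment ratio,
# category and substrate, while snow cover, vegetation, goose pressure,
# substrate chemistry and the consumer food web are drawn from planted
# causal relationships with known effect sizes (the ground truth). Every
# stochastic draw descends from one root seed via documented per-lake /
# per-month substreams, so any part of the study can be regenerated
# independently.

.substream_seed <- function(seed, lake = 0L, stream = 0L) {
  as.integer((as.numeric(seed) + 1009 * lake + 99991 * stream) %%
               .Machine$integer.max)
}

#' Configuration of the synthetic study
#'
#' Defaults are the study conditions: 18 lakes in four categories with the
#' published distances and lake-to-catchment ratios, 120 x 120 catchment
#' grids of 10 m cells, scenes in April, May, June and August (July skipped,
#' as in the study, where no usable July image existed), up to 20 consumer
#' specimens and six sampling sites per lake.
#'
#' Effect sizes (the planted ground truth; directions follow the study's
#' causal diagram):
#' * `snow_distance_slope` - June snow-cover fraction per km from the coast;
#' * `ndvi_snow_slope` - vegetation NDVI per unit June FSC;
#' * `droppings_ndvi_slope` - goose-dropping latent rank per NDVI unit;
#' * `grazing_delta_slope` - August near-lake NDVI change per dropping rank
#'   (drives the negative droppings / delta-NDVI association);
#' * `d15n_droppings_slope` - per-mil d15N shift of every component per
#'   dropping rank (goose-derived N);
#' * `d13c_openness_slope` - per-mil sediment d13C per unit L/C ratio
#'   (low ratio = large terrestrial drainage = depleted d13C);
#' * `afdm_ndvi_slope`, `n_ndvi_slope` - substrate AFDM% / N% per unit
#'   near-lake August NDVI;
#' * `diet_cpct_slope` - change in the true sediment diet proportion per
#'   sediment C% unit (negative: carbon excess = poorer quality).
#'
#' @param n_lakes Number of lakes (>= 4; default 18). Fewer than 18 takes
#'   the first rows of the lake template.
#' @param grid_shape Integer c(rows, cols) per catchment grid.
#' @param cell_size Cell edge (m).
#' @param months Acquisition labels, subset of Apr/May/Jun/Aug.
#' @param seed Root seed.
#' @param n_consumers Consumer specimens per occupied lake (default 20).
#' @param n_sites Sampling sites (aliquots per substrate component) per lake.
#' @param snow_distance_slope,ndvi_snow_slope,droppings_ndvi_slope,grazing_delta_slope,d15n_droppings_slope,d13c_openness_slope,afdm_ndvi_slope,n_ndvi_slope,diet_cpct_slope
#'   Planted effect sizes (see above).
#' @param fsc_sd,ndvi_sd,droppings_sd,d15n_sd,d13c_sd,afdm_sd,n_sd Noise SDs
#'   of the corresponding responses.
#' @param tef Trophic enrichment factors ([trophic_enrichment()]).
#' @param true_diets Optional matrix of per-lake diet proportions (rows =
#'   lakes with the consumer, columns = sources); default derived from the
#'   sediment C% rule.
#' @param source_d13c_sd,source_d15n_sd Within-lake sampling SDs of the
#'   three diet sources (sediment, zooplankton, aquatic vegetation).
#' @param delta_ndvi_exclude Lake ids excluded from delta-NDVI analyses
#'   (default 3 and 8: human infrastructure near those catchments).
#' @return List of class `study_config`.
#' @export
study_config <- function(n_lakes = 18,
                         grid_shape = c(120, 120),
                         cell_size = 10,
                         months = c("Apr", "May", "Jun", "Aug"),
                         seed = 1,
                         n_consumers = 20,
                         n_sites = 6,
                         snow_distance_slope = 0.45,
                         ndvi_snow_slope = -0.45,
                         droppings_ndvi_slope = 7,
                         grazing_delta_slope = -0.025,
                         d15n_droppings_slope = 0.75,
                         d13c_openness_slope = 12,
                         afdm_ndvi_slope = 25,
                         n_ndvi_slope = 2,
                         diet_cpct_slope = -0.08,
                         fsc_sd = 0.08,
                         ndvi_sd = 0.05,
                         droppings_sd = 0.5,
                         d15n_sd = 0.5,
                         d13c_sd = 1.2,
                         afdm_sd = 1.5,
                         n_sd = 0.08,
                         tef = trophic_enrichment(),
                         true_diets = NULL,
                         source_d13c_sd = c(0.6, 0.5, 1.0),
                         source_d15n_sd = c(0.6, 0.5, 0.5),
                         delta_ndvi_exclude = c(3, 8)) {
  stopifnot(n_lakes >= 4)
  sds <- c(fsc_sd, ndvi_sd, droppings_sd, d15n_sd, d13c_sd, afdm_sd, n_sd)
  if (any(sds < 0)) stop("noise SDs must be >= 0")
  if (!all(months %in% c("Apr", "May", "Jun", "Aug"))) {
    stop("months must be a subset of Apr, May, Jun, Aug")
  }
  cfg <- list(n_lakes = n_lakes, grid_shape = grid_shape,
              cell_size = cell_size, months = months, seed = seed,
              n_consumers = n_consumers, n_sites = n_sites,
              snow_distance_slope = snow_distance_slope,
              ndvi_snow_slope = ndvi_snow_slope,
              droppings_ndvi_slope = droppings_ndvi_slope,
              grazing_delta_slope = grazing_delta_slope,
              d15n_droppings_slope = d15n_droppings_slope,
              d13c_openness_slope = d13c_openness_slope,
              afdm_ndvi_slope = afdm_ndvi_slope,
              n_ndvi_slope = n_ndvi_slope,
              diet_cpct_slope = diet_cpct_slope,
              fsc_sd = fsc_sd, ndvi_sd = ndvi_sd,
              droppings_sd = droppings_sd, d15n_sd = d15n_sd,
              d13c_sd = d13c_sd, afdm_sd = afdm_sd, n_sd = n_sd,
              tef = tef, true_diets = true_diets,
              source_d13c_sd = source_d13c_sd,
              source_d15n_sd = source_d15n_sd,
              delta_ndvi_exclude = delta_ndvi_exclude)
  class(cfg) <- "study_config"
  cfg
}

# per-lake template: published distances/ratios/categories plus the
# synthetic occurrence reconstruction
.lake_template <- function(config) {
  tab <- load_table1_fixture()
  occ <- load_occurrence_fixture()
  tmpl <- merge(tab[, c("lake_id", "category", "substrate", "has_glacier",
                        "dist_coast_m", "lc_ratio")],
                occ, by = "lake_id")
  tmpl <- tmpl[order(tmpl$lake_id), ]
  if (config$n_lakes > nrow(tmpl)) {
    stop("n_lakes beyond the 18-lake template is not supported")
  }
  tmpl[seq_len(config$n_lakes), ]
}

# planted mean state of every lake: FSC by month, vegetation NDVI,
# droppings ranks, substrate chemistry, diets, TP
.plant_truth <- function(config) {
  tmpl <- .lake_template(config)
  n <- nrow(tmpl)
  set.seed(.substream_seed(config$seed, 0L, 1L))
  dist_km <- tmpl$dist_coast_m / 1000

  fsc_june <- pmin(1, pmax(0, config$snow_distance_slope * dist_km +
                             stats::rnorm(n, 0, config$fsc_sd)))
  # the study reports FSC > 0.90 in every catchment until May
  fsc <- cbind(Apr = pmin(1, pmax(0.92, 0.96 + stats::rnorm(n, 0, 0.02))),
               May = pmin(1, pmax(0.91, 0.93 + stats::rnorm(n, 0, 0.02))),
               Jun = fsc_june,
               Aug = rep(0, n))
  rownames(fsc) <- tmpl$lake_id

  veg_ndvi <- 0.32 + config$ndvi_snow_slope * fsc_june +
    stats::rnorm(n, 0, config$ndvi_sd)
  veg_ndvi <- pmin(0.9, pmax(-0.2, veg_ndvi))

  latent <- 0.8 + config$droppings_ndvi_slope * veg_ndvi
  transects <- matrix(pmin(4, pmax(0, round(
    latent + stats::rnorm(3 * n, 0, config$droppings_sd)))), nrow = n)
  droppings <- rowMeans(transects)

  near_lake_ndvi_aug <- veg_ndvi + config$grazing_delta_slope * droppings
  sed_afdm <- pmax(0.2, 2 + config$afdm_ndvi_slope * near_lake_ndvi_aug +
                     stats::rnorm(n, 0, config$afdm_sd))
  soil_afdm <- pmax(0.2, 1 + 0.6 * config$afdm_ndvi_slope *
                      near_lake_ndvi_aug + stats::rnorm(n, 0, config$afdm_sd))
  sed_n <- pmax(0.01, 0.05 + config$n_ndvi_slope * near_lake_ndvi_aug +
                  stats::rnorm(n, 0, config$n_sd))
  soil_n <- pmax(0.01, 0.03 + 0.6 * config$n_ndvi_slope *
                   near_lake_ndvi_aug + stats::rnorm(n, 0, config$n_sd))
  # C% varies through the sediment C:N ratio; like the distances and L/C
  # ratios, the quality gradient is a fixed per-lake template (evenly spaced
  # around the study mean of 14.7, deterministically interleaved so it is
  # not collinear with the coast-distance gradient); responses stay noisy
  cn_levels <- seq(10, 20, length.out = 18)
  cn_order <- c(5, 14, 1, 10, 17, 3, 12, 7, 16, 2, 11, 6, 15, 9, 4, 13, 8, 18)
  sed_cn <- cn_levels[cn_order][seq_len(n)]
  sed_c <- sed_cn * sed_n

  sed_d13c <- -26.5 + config$d13c_openness_slope * tmpl$lc_ratio +
    stats::rnorm(n, 0, config$d13c_sd / 2)
  sed_d15n <- 1.5 + config$d15n_droppings_slope * droppings
  soil_d13c <- -25.3 + stats::rnorm(n, 0, 0.4)
  soil_d15n <- 1.0 + config$d15n_droppings_slope * droppings
  veg_aq_d15n <- 2.0 + config$d15n_droppings_slope * droppings
  veg_terr_d15n <- 1.0 + config$d15n_droppings_slope * droppings

  # true diets for lakes holding the consumer: sediment share set by C%
  # (quality), remainder split 75/25 between zooplankton and vegetation
  # (specialised populations drop vegetation below the link threshold)
  has_lep <- tmpl$has_lepidurus
  if (is.null(config$true_diets)) {
    p_sed <- pmin(0.9, pmax(0.05, 0.9 + config$diet_cpct_slope * (sed_c - 2)))
    diets <- cbind(sediment = p_sed,
                   daphnia = 0.75 * (1 - p_sed),
                   vegetation_aquatic = 0.25 * (1 - p_sed))
  } else {
    diets <- config$true_diets
    if (any(abs(rowSums(diets) - 1) > 1e-9)) {
      stop("true diet vectors must sum to 1")
    }
    diets <- diets[rep_len(seq_len(nrow(diets)), n), , drop = FALSE]
  }
  rownames(diets) <- tmpl$lake_id

  # planted source distributions per lake (d15N shifts with droppings)
  source_means <- function(i) {
    data.frame(
      name = c("sediment", "daphnia", "vegetation_aquatic"),
      mean_d13c = c(sed_d13c[i], -27.5, -20.0),
      sd_d13c = config$source_d13c_sd,
      mean_d15n = c(sed_d15n[i], veg_aq_d15n[i] + config$tef$d15n_mean,
                    veg_aq_d15n[i]),
      sd_d15n = config$source_d15n_sd,
      stringsAsFactors = FALSE
    )
  }
  sources <- lapply(seq_len(n), source_means)
  names(sources) <- tmpl$lake_id

  # implied true TP: consumer mean d15N over the aquatic-vegetation baseline
  true_tp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!has_lep[i]) next
    src <- sources[[i]]
    mu_c <- sum(diets[i, ] * (src$mean_d15n + config$tef$d15n_mean))
    true_tp[i] <- (mu_c - veg_aq_d15n[i]) / config$tef$d15n_mean + 1
  }

  # synthetic map coordinates: east-west position from the coast distance,
  # north-south scattered (used for geographic distance matrices)
  lake_x <- tmpl$dist_coast_m
  lake_y <- stats::runif(n, 0, 5000)

  list(template = tmpl, fsc = fsc, veg_ndvi = veg_ndvi,
       lake_x = lake_x, lake_y = lake_y,
       near_lake_ndvi_aug = near_lake_ndvi_aug,
       transects = transects, droppings = droppings,
       sed_afdm = sed_afdm, soil_afdm = soil_afdm,
       sed_n = sed_n, soil_n = soil_n, sed_c = sed_c, sed_cn = sed_cn,
       sed_d13c = sed_d13c, sed_d15n = sed_d15n,
       soil_d13c = soil_d13c, soil_d15n = soil_d15n,
       veg_aq_d15n = veg_aq_d15n, veg_terr_d15n = veg_terr_d15n,
       diets = diets, sources = sources, true_tp = true_tp,
       slopes = config[c("snow_distance_slope", "ndvi_snow_slope",
                         "droppings_ndvi_slope", "grazing_delta_slope",
                         "d15n_droppings_slope", "d13c_openness_slope",
                         "afdm_ndvi_slope", "n_ndvi_slope",
                         "diet_cpct_slope")])
}

#' Synthetic DEM and lake mask for one catchment
#'
#' A radial bowl draining to a central lake, with smooth ridged noise; the
#' lake is a disc whose cell count realises the lake's published
#' lake-to-catchment ratio against the full grid. Elevation increases away
#' from the lake, so the high-elevation margin is where snow persists.
#'
#' @param lake_index Row of the lake template (1-based).
#' @param config A [study_config()].
#' @return List with `dem` (matrix, m), `lake_mask` (logical matrix),
#'   `cell_size`.
#' @export
generate_dem <- function(lake_index, config) {
  set.seed(.substream_seed(config$seed, lake_index, 2L))
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  tmpl <- .lake_template(config)
  lc <- tmpl$lc_ratio[lake_index]
  n_cells <- nr * nc
  n_lake <- max(4, round(lc * n_cells))

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # lake touches the south edge, so the lake itself is the grid's drain and
  # the whole grid is its catchment (realising the planted L/C ratio)
  cr <- nr; cc <- (nc + 1) / 2
  r2 <- (rows - cr)^2 + (cols - cc)^2
  lake_mask <- matrix(rank(r2, ties.method = "first") <= n_lake, nr, nc)

  # bowl rising away from the lake; relief noise kept well below the
  # per-cell bowl gradient so every land cell drains lakewards
  dist <- sqrt(r2) * config$cell_size
  ridges <- 0.5 * sin(rows / nr * 4 * pi + stats::runif(1, 0, 2 * pi)) *
    cos(cols / nc * 4 * pi + stats::runif(1, 0, 2 * pi))
  dem <- 5 + 0.12 * dist + ridges +
    matrix(stats::rnorm(n_cells, 0, 0.15), nr, nc)
  lake_level <- min(dem[lake_mask])
  dem[lake_mask] <- lake_level
  list(dem = dem, lake_mask = lake_mask, cell_size = config$cell_size)
}

#' Synthetic reflectance scene for one lake and month
#'
#' Plants a snow mask over the highest-elevation land cells so that the
#' snow fraction matches the ground-truth FSC for that lake and month to
#' within one cell, then assigns separable reflectances: snow is bright in
#' Green and Red and dark in SWIR; vegetated land has NIR > Red with the
#' lake's planted NDVI; water is dark everywhere (high NDSI but failing the
#' Red test). In August, near-lake vegetation NDVI is reduced by goose
#' grazing in proportion to the dropping rank.
#'
#' @param lake_index Row of the lake template.
#' @param month One of the configured months.
#' @param config A [study_config()].
#' @param truth Planted truth from [generate_study()] (regenerated when
#'   omitted).
#' @param dem Output of [generate_dem()] (regenerated when omitted).
#' @return List of class `scene_bundle`: `green`, `red`, `nir`, `swir`
#'   matrices in [0, 1], `snow_mask`, `month`, `cell_size`.
#' @export
generate_scene <- function(lake_index, month, config, truth = NULL,
                           dem = NULL) {
  if (!month %in% config$months) stop("unknown month: ", month)
  if (is.null(truth)) truth <- .plant_truth(config)
  if (is.null(dem)) dem <- generate_dem(lake_index, config)
  set.seed(.substream_seed(config$seed,
                           lake_index,
                           10L + match(month, c("Apr", "May", "Jun", "Aug"))))
  lake <- dem$lake_mask
  nr <- nrow(lake); nc <- ncol(lake)
  land <- !lake
  n_land <- sum(land)
  fsc <- truth$fsc[lake_index, month]
  n_snow <- round(fsc * n_land)

  # snow occupies the highest-elevation land cells (contiguous margin)
  snow <- matrix(FALSE, nr, nc)
  if (n_snow > 0) {
    elev_land <- dem$dem
    elev_land[!land] <- -Inf
    ord <- order(elev_land, decreasing = TRUE)[seq_len(n_snow)]
    snow[ord] <- TRUE
  }

  v <- truth$veg_ndvi[lake_index]
  vgrid <- matrix(v + stats::rnorm(nr * nc, 0, 0.02), nr, nc)
  if (month == "Aug") {
    ring <- lake_buffer(lake, distance_m = 100, cell_size = dem$cell_size)
    vgrid[ring] <- vgrid[ring] +
      config$grazing_delta_slope * truth$droppings[lake_index]
  }
  vgrid <- matrix(pmin(pmax(vgrid, -0.9), 0.9), nr, nc)

  green <- matrix(0.15, nr, nc); red <- matrix(0.12, nr, nc)
  swir <- matrix(0.35, nr, nc)
  nir <- red * (1 + vgrid) / (1 - vgrid)

  green[snow] <- 0.75 + stats::runif(sum(snow), 0, 0.1)
  red[snow] <- 0.65 + stats::runif(sum(snow), 0, 0.1)
  swir[snow] <- 0.04 + stats::runif(sum(snow), 0, 0.03)
  nir[snow] <- 0.6

  green[lake] <- 0.06; red[lake] <- 0.05
  swir[lake] <- 0.02; nir[lake] <- 0.03

  clamp01 <- function(m) matrix(pmin(pmax(m, 0), 1), nr, nc)
  structure(list(green = clamp01(green), red = clamp01(red),
                 nir = clamp01(nir), swir = clamp01(swir),
                 snow_mask = snow, month = month,
                 cell_size = dem$cell_size),
            class = "scene_bundle")
}

#' Synthetic food-web samples for one lake
#'
#' Draws substrate, vegetation, zooplankton and goose-dropping aliquots from
#' the planted per-lake distributions, and - where the top consumer occurs -
#' consumer individuals from the TEF-shifted mixture model under the lake's
#' true diet vector (mixture mean shifted by the TEF means, variances
#' combining source and TEF SDs).
#'
#' @param lake_index Row of the lake template.
#' @param config A [study_config()].
#' @param truth Planted truth (regenerated when omitted).
#' @return Data frame of isotope samples: `lake_id`, `component`, `d13c`,
#'   `d15n`, `c_pct`, `n_pct`, `afdm_pct`.
#' @export
generate_foodweb_samples <- function(lake_index, config, truth = NULL) {
  if (is.null(truth)) truth <- .plant_truth(config)
  set.seed(.substream_seed(config$seed, lake_index, 30L))
  tmpl <- truth$template
  id <- tmpl$lake_id[lake_index]
  ns <- config$n_sites
  rows <- list()
  add <- function(component, d13c, d15n, c_pct = NA, n_pct = NA,
                  afdm_pct = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      lake_id = id, component = component, d13c = d13c, d15n = d15n,
      c_pct = c_pct, n_pct = n_pct, afdm_pct = afdm_pct,
      stringsAsFactors = FALSE)
  }

  n_site_pct <- function(mu, sd) pmax(0.005, stats::rnorm(ns, mu, sd))
  src <- truth$sources[[lake_index]]
  sed_src <- src[src$name == "sediment", ]
  sed_n <- n_site_pct(truth$sed_n[lake_index], config$n_sd)
  # isotope aliquots of diet sources are drawn from the configured source
  # distributions, so the mixing model sees a consistent generating process
  add("sediment",
      d13c = stats::rnorm(ns, sed_src$mean_d13c, sed_src$sd_d13c),
      d15n = stats::rnorm(ns, sed_src$mean_d15n, sed_src$sd_d15n),
      c_pct = truth$sed_cn[lake_index] * sed_n,
      n_pct = sed_n,
      afdm_pct = pmax(0.1, stats::rnorm(ns, truth$sed_afdm[lake_index],
                                        config$afdm_sd)))
  soil_n <- n_site_pct(truth$soil_n[lake_index], config$n_sd)
  add("soil",
      d13c = stats::rnorm(ns, truth$soil_d13c[lake_index], config$d13c_sd),
      d15n = stats::rnorm(ns, truth$soil_d15n[lake_index],
                          config$d15n_sd * 2),
      c_pct = 12 * soil_n,
      n_pct = soil_n,
      afdm_pct = pmax(0.1, stats::rnorm(ns, truth$soil_afdm[lake_index],
                                        config$afdm_sd)))
  if (tmpl$has_benthic_vegetation[lake_index]) {
    veg <- src[src$name == "vegetation_aquatic", ]
    add("vegetation_aquatic",
        d13c = stats::rnorm(ns, veg$mean_d13c, veg$sd_d13c),
        d15n = stats::rnorm(ns, veg$mean_d15n, veg$sd_d15n))
  }
  add("vegetation_terrestrial",
      d13c = stats::rnorm(ns, -27, 1),
      d15n = stats::rnorm(ns, truth$veg_terr_d15n[lake_index], 0.5))
  add("droppings",
      d13c = stats::rnorm(3, -26, 1),
      d15n = stats::rnorm(3, 4.3 + 0.8 * truth$droppings[lake_index], 1))

  if (tmpl$has_lepidurus[lake_index]) {
    daph <- src[src$name == "daphnia", ]
    add("daphnia",
        d13c = stats::rnorm(ns, daph$mean_d13c, daph$sd_d13c),
        d15n = stats::rnorm(ns, daph$mean_d15n, daph$sd_d15n))
    p <- truth$diets[lake_index, ]
    if (abs(sum(p) - 1) > 1e-9) stop("true diet vector must sum to 1")
    tef <- config$tef
    mu13 <- sum(p * (src$mean_d13c + tef$d13c_mean))
    v13 <- sum(p^2 * (src$sd_d13c^2 + tef$d13c_sd^2))
    mu15 <- sum(p * (src$mean_d15n + tef$d15n_mean))
    v15 <- sum(p^2 * (src$sd_d15n^2 + tef$d15n_sd^2))
    add("lepidurus",
        d13c = stats::rnorm(config$n_consumers, mu13, sqrt(v13)),
        d15n = stats::rnorm(config$n_consumers, mu15, sqrt(v15)))
  }
  do.call(rbind, rows)
}

#' Generate the full synthetic study
#'
#' Produces every dataset the pipeline consumes - DEMs, monthly scenes,
#' per-lake metadata, dropping transects and food-web samples - together
#' with the planted ground truth. Byte-identical for identical
#' (config, seed).
#'
#' @param config A [study_config()].
#' @return List with `study` (elements `lakes`, `dems`, `scenes`, `samples`,
#'   `droppings`, `config`) and `truth` (planted state, see source).
#' @export
generate_study <- function(config = study_config()) {
  truth <- .plant_truth(config)
  tmpl <- truth$template
  n <- nrow(tmpl)
  dems <- lapply(seq_len(n), generate_dem, config = config)
  scenes <- lapply(seq_len(n), function(i) {
    sc <- lapply(config$months, function(m) {
      generate_scene(i, m, config, truth = truth, dem = dems[[i]])
    })
    names(sc) <- config$months
    sc
  })
  names(dems) <- tmpl$lake_id
  names(scenes) <- tmpl$lake_id
  samples <- do.call(rbind, lapply(seq_len(n), generate_foodweb_samples,
                                   config = config, truth = truth))
  droppings <- data.frame(lake_id = tmpl$lake_id,
                          rank_1 = truth$transects[, 1],
                          rank_2 = truth$transects[, 2],
                          rank_3 = truth$transects[, 3])
  droppings$score <- apply(truth$transects, 1, droppings_score)
  lakes <- tmpl
  list(study = list(lakes = lakes, dems = dems, scenes = scenes,
                    samples = samples, droppings = droppings,
                    config = config),
       truth = truth)
}
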