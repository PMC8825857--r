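# Full-study orchestration: terrain -> indices -> food-web metrics -> diet
# mixing -> hypothesis battery. Each stage consumes only the outputs of the
# stages before it; a failure aborts with a stage-named error.

#' Default hypothesis battery
#'
#' One row per regression tested by the study: response, predictor,
#' aggregation level, lake exclusions and the expected sign used by
#' synthetic-recovery tests. Signs are declared exactly for the hypotheses
#' whose signal and noise the generator controls directly; consumer-level
#' responses (d15N of the top consumer, trophic position, link count) mix
#' several planted channels with diet-composition variability and therefore
#' carry no expected sign.
#'
#' @return Data frame with columns `name`, `response`, `predictor`,
#'   `aggregation`, `exclude`, `expected_sign`.
#' @export
default_hypotheses <- function() {
  h <- function(name, response, predictor, expected_sign = NA,
                exclude = "") {
    data.frame(name = name, response = response, predictor = predictor,
               aggregation = "lake_mean", exclude = exclude,
               expected_sign = expected_sign, stringsAsFactors = FALSE)
  }
  rbind(
    h("fsc_vs_distance", "fsc_june", "dist_km", 1),
    h("ndvi_vs_fsc", "mean_ndvi", "fsc_june", -1),
    h("droppings_vs_ndvi", "droppings", "mean_ndvi", 1),
    h("droppings_vs_delta_ndvi", "droppings", "delta_ndvi", -1,
      exclude = "3,8"),
    h("sed_afdm_vs_near_lake_ndvi", "sed_afdm", "near_lake_ndvi_aug", 1),
    h("sed_n_vs_near_lake_ndvi", "sed_n", "near_lake_ndvi_aug", 1),
    h("soil_afdm_vs_near_lake_ndvi", "soil_afdm", "near_lake_ndvi_aug", 1),
    h("soil_n_vs_near_lake_ndvi", "soil_n", "near_lake_ndvi_aug", 1),
    h("sed_d15n_vs_droppings", "sed_d15n", "droppings", 1),
    h("soil_d15n_vs_droppings", "soil_d15n", "droppings", 1),
    h("veg_aq_d15n_vs_droppings", "veg_aq_d15n", "droppings", 1),
    h("lep_d15n_vs_droppings", "lep_d15n", "droppings"),
    h("sed_d13c_vs_lc_ratio", "sed_d13c", "lc_ratio", 1),
    h("sed_diet_vs_sed_c", "p_sediment", "sed_c", -1),
    h("links_vs_sed_diet", "links", "p_sediment"),
    h("tp_vs_daphnia_diet", "tp", "p_daphnia"),
    h("tp_vs_sed_afdm", "tp", "sed_afdm")
  )
}

#' Pipeline configuration
#'
#' Bundles the synthetic-study configuration with the analysis parameters.
#'
#' @param study A [study_config()].
#' @param n_perm Permutations for every permutation test (default 9999).
#' @param n_boot Bootstrap resamples for slope CIs (default 1999).
#' @param mixing A [mixing_config()] for the diet model.
#' @param snow_thresholds `c(ndsi_min, red_min)` for [classify_snow()].
#' @param buffer_m Near-lake buffer distance (m), default 100.
#' @param hypotheses Hypothesis battery data frame
#'   (default [default_hypotheses()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(),
                            n_perm = 9999, n_boot = 1999,
                            mixing = mixing_config(seed = study$seed),
                            snow_thresholds = c(0.40, 0.20),
                            buffer_m = 100,
                            hypotheses = default_hypotheses()) {
  structure(list(study = study, n_perm = n_perm, n_boot = n_boot,
                 mixing = mixing, snow_thresholds = snow_thresholds,
                 buffer_m = buffer_m, hypotheses = hypotheses),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full study pipeline
#'
#' Executes, in order: synthetic-study generation; catchment delineation and
#' lake-to-catchment ratios; NDVI/NDSI/snow-cover summaries; dropping scores
#' and lake categorisation; isotope aggregation, baselines and trophic
#' positions; diet mixing models for the lakes holding the top consumer;
#' the hypothesis battery; PERMANOVA between lakes; the isotopic-vs-
#' geographic Mantel test; category-by-compartment two-way ANOVAs; and the
#' presence/absence t and chi-square tests.
#'
#' @param config A [pipeline_config()].
#' @return A `study_report` list; see [write_report()] for its layout.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  gen <- .stage("simulate", generate_study(config$study))
  study <- gen$study
  truth <- gen$truth
  lakes <- study$lakes
  n <- nrow(lakes)
  cs <- config$study$cell_size

  # terrain: catchment per lake from the filled DEM
  terr <- .stage("terrain", lapply(seq_len(n), function(i) {
    d <- study$dems[[i]]
    filled <- fill_depressions(d$dem)
    flow <- d8_flow_directions(filled, cell_size = cs)
    catch <- delineate_catchment(flow, d$lake_mask,
                                 lake_id = lakes$lake_id[i])
    list(flow = flow, catchment = catch,
         lc_ratio = openness_ratio(catch$lake_area_m2, catch$area_m2))
  }))

  # indices: FSC per month and the NDVI summary set per lake
  idx <- .stage("indices", lapply(seq_len(n), function(i) {
    d <- study$dems[[i]]
    catch <- terr[[i]]$catchment
    buf <- lake_buffer(d$lake_mask, distance_m = config$buffer_m,
                       cell_size = cs)
    fsc <- vapply(config$study$months, function(m) {
      sc <- study$scenes[[i]][[m]]
      snow <- classify_snow(ndsi(sc$green, sc$swir), sc$red,
                            config$snow_thresholds)
      snow_cover_fraction(snow, catch$mask, d$lake_mask)
    }, numeric(1))
    ndvi_m <- lapply(study$scenes[[i]], function(sc) ndvi(sc$nir, sc$red))
    summaries <- ndvi_summaries(ndvi_m, catch$mask, d$lake_mask, buf)
    c(list(fsc = fsc), summaries)
  }))

  # food-web metrics: categories, dropping scores, lake-level chemistry, TP
  fw <- .stage("foodweb", {
    samples <- study$samples
    agg <- function(component, var) {
      vapply(lakes$lake_id, function(id) {
        sel <- samples$lake_id == id & samples$component == component
        if (!any(sel)) return(NA_real_)
        mean(samples[[var]][sel], na.rm = TRUE)
      }, numeric(1))
    }
    category <- vapply(seq_len(n), function(i) {
      classify_lake_category(lakes$dist_coast_m[i], lakes$has_glacier[i],
                             lakes$substrate[i])
    }, character(1))
    tp <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (!lakes$has_lepidurus[i]) next
      base <- baseline_d15n(samples, lakes$lake_id[i])
      cons <- samples$d15n[samples$lake_id == lakes$lake_id[i] &
                             samples$component == "lepidurus"]
      tp[i] <- trophic_position(cons, base,
                                config$study$tef$d15n_mean)$lake_tp
    }
    list(category = category,
         droppings = study$droppings$score,
         sed_d13c = agg("sediment", "d13c"),
         sed_d15n = agg("sediment", "d15n"),
         sed_afdm = agg("sediment", "afdm_pct"),
         sed_n = agg("sediment", "n_pct"),
         sed_c = agg("sediment", "c_pct"),
         soil_d13c = agg("soil", "d13c"),
         soil_d15n = agg("soil", "d15n"),
         soil_afdm = agg("soil", "afdm_pct"),
         soil_n = agg("soil", "n_pct"),
         veg_aq_d15n = agg("vegetation_aquatic", "d15n"),
         lep_d15n = agg("lepidurus", "d15n"),
         tp = tp)
  })

  # diet mixing per consumer lake
  diet <- .stage("diet", {
    posteriors <- vector("list", n)
    p_sediment <- rep(NA_real_, n)
    p_daphnia <- rep(NA_real_, n)
    links <- rep(NA_real_, n)
    samples <- study$samples
    src_names <- c("sediment", "daphnia", "vegetation_aquatic")
    for (i in seq_len(n)) {
      if (!lakes$has_lepidurus[i]) next
      id <- lakes$lake_id[i]
      src <- do.call(rbind, lapply(src_names, function(s) {
        sel <- samples$lake_id == id & samples$component == s
        if (!any(sel)) return(NULL)
        data.frame(name = s,
                   mean_d13c = mean(samples$d13c[sel]),
                   sd_d13c = stats::sd(samples$d13c[sel]),
                   mean_d15n = mean(samples$d15n[sel]),
                   sd_d15n = stats::sd(samples$d15n[sel]))
      }))
      cons <- samples[samples$lake_id == id &
                        samples$component == "lepidurus",
                      c("d13c", "d15n")]
      mc <- config$mixing
      mc$seed <- .substream_seed(config$mixing$seed, i, 40L)
      post <- fit_diet_mcmc(cons, src, config$study$tef, mc)
      posteriors[[i]] <- post
      med <- post$summary$median
      names(med) <- post$summary$source
      p_sediment[i] <- med["sediment"]
      p_daphnia[i] <- unname(med["daphnia"])
      links[i] <- trophic_link_count(post)
    }
    any_consumer <- any(lakes$has_lepidurus)
    list(posteriors = posteriors, p_sediment = p_sediment,
         p_daphnia = p_daphnia, links = links,
         skipped = !any_consumer)
  })

  lake_table <- data.frame(
    lake_id = lakes$lake_id,
    category = fw$category,
    dist_coast_m = lakes$dist_coast_m,
    dist_km = lakes$dist_coast_m / 1000,
    lc_ratio = vapply(terr, `[[`, numeric(1), "lc_ratio"),
    fsc_june = vapply(idx, function(x) unname(x$fsc["Jun"]), numeric(1)),
    mean_ndvi = vapply(idx, `[[`, numeric(1), "mean_ndvi"),
    near_lake_ndvi_aug = vapply(idx, `[[`, numeric(1), "near_lake_ndvi"),
    catchment_ndvi_aug = vapply(idx, `[[`, numeric(1), "catchment_ndvi"),
    delta_ndvi = vapply(idx, `[[`, numeric(1), "delta_ndvi"),
    ndvi_seasonal_change = vapply(idx, `[[`, numeric(1), "seasonal_change"),
    droppings = fw$droppings,
    sed_d13c = fw$sed_d13c, sed_d15n = fw$sed_d15n,
    sed_afdm = fw$sed_afdm, sed_n = fw$sed_n, sed_c = fw$sed_c,
    soil_d13c = fw$soil_d13c, soil_d15n = fw$soil_d15n,
    soil_afdm = fw$soil_afdm, soil_n = fw$soil_n,
    veg_aq_d15n = fw$veg_aq_d15n, lep_d15n = fw$lep_d15n,
    tp = fw$tp,
    p_sediment = diet$p_sediment, p_daphnia = diet$p_daphnia,
    links = diet$links,
    has_lepidurus = lakes$has_lepidurus,
    has_benthic_vegetation = lakes$has_benthic_vegetation,
    stringsAsFactors = FALSE
  )

  # hypothesis battery
  regressions <- .stage("stats", {
    hyp <- config$hypotheses
    out <- vector("list", nrow(hyp))
    for (j in seq_len(nrow(hyp))) {
      row <- hyp[j, ]
      tab <- lake_table
      if (nzchar(row$exclude)) {
        excl <- as.numeric(strsplit(row$exclude, ",")[[1]])
        tab <- tab[!tab$lake_id %in% excl, ]
      }
      x <- tab[[row$predictor]]
      y <- tab[[row$response]]
      fit <- ols_permutation_fit(
        x, y, n_perm = config$n_perm, n_boot = config$n_boot,
        seed = .substream_seed(config$study$seed, j, 50L))
      sign_ok <- if (is.na(row$expected_sign)) NA else
        fit$significant && sign(fit$slope) == row$expected_sign
      out[[j]] <- data.frame(
        name = row$name, response = row$response,
        predictor = row$predictor, n = fit$n,
        slope = fit$slope, r_squared = fit$r_squared,
        permutation_p = fit$permutation_p,
        ci_low = fit$boot_ci[1], ci_high = fit$boot_ci[2],
        aic = fit$aic, significant = fit$significant,
        expected_sign = row$expected_sign, sign_recovered = sign_ok,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  multivar <- .stage("stats", {
    samples <- study$samples
    seed0 <- .substream_seed(config$study$seed, 0L, 60L)
    perma <- lapply(c(sediment = "sediment", soil = "soil"), function(comp) {
      sel <- samples$component == comp
      permanova_one_way(samples[sel, c("d13c", "d15n")],
                        samples$lake_id[sel],
                        n_perm = config$n_perm, seed = seed0)
    })
    geo <- stats::dist(cbind(truth$lake_x, truth$lake_y))
    mantel <- lapply(c(sediment = "sed", soil = "soil"), function(pre) {
      iso <- stats::dist(cbind(fw[[paste0(pre, "_d13c")]],
                               fw[[paste0(pre, "_d15n")]]))
      mantel_test(iso, geo, n_perm = config$n_perm, seed = seed0)
    })

    # category x compartment ANOVAs on the substrate variables
    comp_long <- function(sed_var, soil_var) {
      data.frame(
        value = c(lake_table[[sed_var]], lake_table[[soil_var]]),
        category = rep(lake_table$category, 2),
        compartment = rep(c("aquatic", "terrestrial"),
                          each = nrow(lake_table)))
    }
    anovas <- lapply(list(d15n = c("sed_d15n", "soil_d15n"),
                          d13c = c("sed_d13c", "soil_d13c"),
                          afdm = c("sed_afdm", "soil_afdm"),
                          n = c("sed_n", "soil_n")), function(v) {
      d <- comp_long(v[1], v[2])
      two_way_anova(d$value, d$category, d$compartment)
    })

    # lakes with vs without the top consumer
    pres <- lake_table$has_lepidurus
    t_tests <- lapply(list(dist = "dist_coast_m", droppings = "droppings",
                           sed_afdm = "sed_afdm", sed_n = "sed_n",
                           sed_d13c = "sed_d13c", sed_d15n = "sed_d15n"),
                      function(v) {
      t_test(lake_table[[v]][pres], lake_table[[v]][!pres])
    })
    chi <- chi_square_2x2(occurrence_table(
      data.frame(has_lepidurus = lake_table$has_lepidurus,
                 has_benthic_vegetation = lake_table$has_benthic_vegetation)))
    list(permanova = perma, mantel = mantel, anovas = anovas,
         t_tests = t_tests, chi_square = chi)
  })

  structure(list(lake_table = lake_table, regressions = regressions,
                 diet = diet, permanova = multivar$permanova,
                 mantel = multivar$mantel, anovas = multivar$anovas,
                 t_tests = multivar$t_tests,
                 chi_square = multivar$chi_square,
                 truth = truth, config = config),
            class = "study_report")
}

#' Write a study report to disk
#'
#' Emits the lake table and regression battery as CSV, the diet summaries as
#' one CSV row per lake and source, the remaining tests as JSON, and a config
#' snapshot (seeds included) sufficient to reproduce the run.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$lake_table, file.path(out_dir, "lake_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$regressions,
                   file.path(out_dir, "regressions.csv"), row.names = FALSE)
  diets <- do.call(rbind, lapply(seq_along(report$diet$posteriors),
                                 function(i) {
    post <- report$diet$posteriors[[i]]
    if (is.null(post)) return(NULL)
    cbind(lake_id = report$lake_table$lake_id[i], post$summary)
  }))
  if (!is.null(diets)) {
    utils::write.csv(diets, file.path(out_dir, "diet_summaries.csv"),
                     row.names = FALSE)
  } else {
    cat("diet stage skipped: no lake holds the top consumer\n",
        file = file.path(out_dir, "diet_summaries.csv"))
  }
  tests <- list(permanova = report$permanova, mantel = report$mantel,
                anovas = lapply(report$anovas, as.data.frame),
                t_tests = report$t_tests, chi_square = report$chi_square,
                diet_stage_skipped = report$diet$skipped)
  jsonlite::write_json(tests, file.path(out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  cfg <- report$config
  snapshot <- list(seed = cfg$study$seed, n_perm = cfg$n_perm,
                   n_boot = cfg$n_boot,
                   mixing = unclass(cfg$mixing),
                   snow_thresholds = cfg$snow_thresholds,
                   buffer_m = cfg$buffer_m,
                   study = unclass(cfg$study)[!vapply(unclass(cfg$study),
                                                      is.list, logical(1))])
  jsonlite::write_json(snapshot, file.path(out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}
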