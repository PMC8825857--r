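#' Delta notation from isotope ratios
#'
#' Converts a heavy-to-light isotope ratio into per-mil delta notation
#' relative to a standard: delta = (R_sample - R_standard) / R_standard * 1000.
#' For carbon the standard is Vienna Pee Dee Belemnite; for nitrogen,
#' atmospheric N2.
#'
#' @param r_sample Isotope ratio(s) of the sample, >= 0.
#' @param r_standard Isotope ratio of the reference standard, > 0.
#' @return Per-mil delta value(s).
#' @seealso [ratio_from_delta()] for the inverse.
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (!is.numeric(r_standard) || any(r_standard <= 0)) {
    stop("r_standard must be positive")
  }
  if (any(r_sample < 0)) stop("r_sample must be non-negative")
  (r_sample - r_standard) / r_standard * 1000
}

#' Isotope ratio from delta notation
#'
#' @param delta Per-mil delta value(s).
#' @param r_standard Isotope ratio of the reference standard, > 0.
#' @return Isotope ratio(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  if (!is.numeric(r_standard) || any(r_standard <= 0)) {
    stop("r_standard must be positive")
  }
  r_standard * (1 + delta / 1000)
}

#' Ash-free dry matter percentage
#'
#' AFDM% is the mass lost on muffle combustion expressed per 100 g dry
#' weight: 100 * (dry - ash) / dry. It proxies the organic-matter quantity of
#' sediment and soil.
#'
#' @param dry_mass_g Dry mass before combustion (g), > 0.
#' @param ash_mass_g Ash mass after combustion (g), 0 <= ash <= dry.
#' @return AFDM as a percentage in [0, 100].
#' @export
afdm_percent <- function(dry_mass_g, ash_mass_g) {
  if (any(dry_mass_g <= 0)) stop("dry mass must be positive")
  if (any(ash_mass_g < 0) || any(ash_mass_g > dry_mass_g)) {
    stop("ash mass must lie in [0, dry mass]")
  }
  100 * (dry_mass_g - ash_mass_g) / dry_mass_g
}

#' Mass-based C:N ratio
#'
#' Ratio of elemental carbon to nitrogen percentages. A lower C:N indicates
#' higher resource quality: relative carbon excess signals nutrient
#' limitation for consumers.
#'
#' @param c_pct Carbon content (% of dry mass).
#' @param n_pct Nitrogen content (% of dry mass).
#' @return c_pct / n_pct; `NA` with a warning where `n_pct` is zero.
#' @export
cn_ratio <- function(c_pct, n_pct) {
  out <- ifelse(n_pct > 0, c_pct / n_pct, NA_real_)
  if (anyNA(out)) warning("C:N undefined where N% = 0; returning NA")
  out
}

#' Goose-dropping score from transect ranks
#'
#' Each lake's goose-dropping abundance is surveyed on three shore-parallel
#' transects, ranked on a semi-quantitative ordinal scale: absent = 0,
#' low = 1, medium = 2, high = 3, very high = 4. The lake score is the mean
#' of the three transect ranks and may be non-integer.
#'
#' @param transect_ranks Integer vector of exactly three ranks in 0..4.
#' @return The mean rank, a score in [0, 4].
#' @export
droppings_score <- function(transect_ranks) {
  if (length(transect_ranks) != 3) {
    stop("exactly three transect ranks are required")
  }
  if (any(!transect_ranks %in% 0:4)) {
    stop("transect ranks must be integers in 0..4")
  }
  mean(transect_ranks)
}

#' d15N baseline from aquatic vegetation
#'
#' The isotopic baseline of each lake is the mean d15N of its aquatic
#' vegetation samples. Zooplankton is deliberately not used as a baseline:
#' it is absent from several lakes and integrates two food chains with
#' different baselines.
#'
#' @param samples Data frame of isotope samples with columns `lake_id`,
#'   `component` and `d15n`.
#' @param lake_id Lake to compute the baseline for.
#' @return Mean d15N (per mil) of aquatic vegetation in that lake.
#' @export
baseline_d15n <- function(samples, lake_id) {
  sel <- samples$lake_id == lake_id &
    samples$component == "vegetation_aquatic"
  if (!any(sel)) {
    stop("no aquatic vegetation samples in lake ", lake_id,
         "; trophic position undefined")
  }
  mean(samples$d15n[sel])
}

#' Trophic position from d15N
#'
#' TP = (d15N_consumer - d15N_baseline) / TEF + 1, where TEF is the per-step
#' trophic enrichment factor for nitrogen. The added 1 places a consumer
#' exactly one enrichment step above the primary-producer baseline at TP = 2.
#' The lake-level TP is the mean over specimens.
#'
#' Values below 1 are arithmetically possible (specimen d15N below baseline)
#' and are reported with a warning rather than clamped, so that data problems
#' stay visible.
#'
#' @param consumer_d15n Vector of per-specimen consumer d15N (per mil).
#' @param baseline_d15n Baseline d15N (per mil).
#' @param tef_d15n_mean Per-step nitrogen enrichment (per mil), > 0;
#'   default 2.3.
#' @return List with `tp` (per-specimen trophic positions) and `lake_tp`
#'   (their mean).
#' @export
trophic_position <- function(consumer_d15n, baseline_d15n,
                             tef_d15n_mean = 2.3) {
  if (length(consumer_d15n) == 0) stop("no consumer d15N values supplied")
  if (tef_d15n_mean <= 0) stop("TEF must be positive")
  tp <- (consumer_d15n - baseline_d15n) / tef_d15n_mean + 1
  if (any(tp < 1)) {
    warning("trophic position below 1 for ", sum(tp < 1),
            " specimen(s); check baseline")
  }
  list(tp = tp, lake_tp = mean(tp))
}

#' Default trophic enrichment factors
#'
#' Whole-organism per-step enrichment between the top consumer and its food
#' sources: 0.4 +/- 0.2 per mil for d13C and 2.3 +/- 0.5 per mil for d15N,
#' values broadly applied for aquatic invertebrates including polar
#' crustaceans.
#'
#' @param d13c_mean,d13c_sd,d15n_mean,d15n_sd Override individual components.
#' @return List with elements `d13c_mean`, `d13c_sd`, `d15n_mean`, `d15n_sd`.
#' @export
trophic_enrichment <- function(d13c_mean = 0.4, d13c_sd = 0.2,
                               d15n_mean = 2.3, d15n_sd = 0.5) {
  if (d13c_sd < 0 || d15n_sd < 0) stop("TEF standard deviations must be >= 0")
  list(d13c_mean = d13c_mean, d13c_sd = d13c_sd,
       d15n_mean = d15n_mean, d15n_sd = d15n_sd)
}

#' Classify a lake into the four study categories
#'
#' Lakes with a permanent glacier in the catchment are `glacier`; otherwise
#' lakes within `coastal_max_m` of the coast are coastal, split into
#' `muddy_coastal` / `sandy_coastal` by substrate; the rest are `lowland`.
#' The default 250 m threshold separates the study's coastal lakes
#' (<= 240 m) from its lowland lakes (>= 515 m) with margin on both sides.
#'
#' @param dist_coast_m Distance from lake centre to the coast (m).
#' @param has_glacier Logical: permanent glacier within the catchment?
#' @param substrate "muddy" or "sandy"; required for coastal lakes, may be
#'   `NA` otherwise.
#' @param coastal_max_m Coastal distance threshold (m), default 250.
#' @return One of "muddy_coastal", "sandy_coastal", "lowland", "glacier".
#' @export
classify_lake_category <- function(dist_coast_m, has_glacier, substrate = NA,
                                   coastal_max_m = 250) {
  if (isTRUE(has_glacier)) return("glacier")
  if (dist_coast_m <= coastal_max_m) {
    if (is.na(substrate) || !substrate %in% c("muddy", "sandy")) {
      stop("substrate ('muddy' or 'sandy') required for a coastal lake")
    }
    return(paste0(substrate, "_coastal"))
  }
  "lowland"
}
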