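#!/usr/bin/env Rscript
# Stage 5: hypothesis battery and multivariate tests.
#
# Runs the study's full statistical programme over the lake table: the
# permutation-tested regressions (9999 permutations, 1999 bootstrap
# resamples, dual significance criterion), one-way PERMANOVA between lakes
# on (d13C, d15N), the isotopic-vs-geographic Mantel tests, the category x
# compartment two-way ANOVAs, and the consumer presence/absence t and
# chi-square tests.

suppressPackageStartupMessages(library(arclakes))

lake_tab <- read.csv("results/tables/lake_table.csv")
diets <- read.csv("results/tables/diet_summaries.csv")
links <- read.csv("results/tables/trophic_links.csv")
samples <- read.csv("results/synthetic/samples.csv")
lakes <- read.csv("results/synthetic/lakes.csv")

wide <- reshape(diets[, c("lake_id", "source", "median")],
                idvar = "lake_id", timevar = "source", direction = "wide")
names(wide) <- sub("^median\\.", "p_", names(wide))
tab <- merge(merge(lake_tab, wide, all.x = TRUE),
             links[, c("lake_id", "links")], all.x = TRUE)
tab$p_sediment <- tab$p_sediment
tab$p_daphnia <- tab$p_daphnia
tab <- merge(tab, lakes[, c("lake_id", "has_lepidurus",
                            "has_benthic_vegetation")])

hyp <- default_hypotheses()
res <- list()
for (j in seq_len(nrow(hyp))) {
  row <- hyp[j, ]
  d <- tab
  if (nzchar(row$exclude)) {
    d <- d[!d$lake_id %in% as.numeric(strsplit(row$exclude, ",")[[1]]), ]
  }
  fit <- ols_permutation_fit(d[[row$predictor]], d[[row$response]],
                             n_perm = 9999, n_boot = 1999, seed = 100 + j)
  res[[j]] <- data.frame(name = row$name, n = fit$n, slope = fit$slope,
                         r_squared = fit$r_squared,
                         permutation_p = fit$permutation_p,
                         ci_low = fit$boot_ci[1], ci_high = fit$boot_ci[2],
                         significant = fit$significant)
}
battery <- do.call(rbind, res)
write.csv(battery, "results/tables/regressions.csv", row.names = FALSE)

sed <- samples[samples$component == "sediment", ]
perma <- permanova_one_way(sed[, c("d13c", "d15n")], sed$lake_id,
                           n_perm = 9999, seed = 42)
cat(sprintf("PERMANOVA sediment between lakes: F = %.1f, p = %.4f\n",
            perma$pseudo_f, perma$p_value))

anova_d15n <- two_way_anova(
  c(tab$sed_d15n, tab$soil_d15n),
  rep(tab$category, 2),
  rep(c("aquatic", "terrestrial"), each = nrow(tab)))
print(anova_d15n)

pres <- tab$has_lepidurus
tt <- t_test(tab$dist_km[pres], tab$dist_km[!pres])
cat(sprintf("Coast distance, consumer vs no-consumer lakes: t = %.2f, p = %.3f\n",
            tt$t, tt$p_value))
chi <- chi_square_2x2(occurrence_table(tab))
cat(sprintf("Consumer x benthic vegetation: chi2 = %.1f, p = %.4f\n",
            chi$chi2, chi$p_value))

cat("\nSignificant regressions (dual criterion):",
    sum(battery$significant), "of", nrow(battery), "\n")
print(battery[battery$significant,
              c("name", "slope", "r_squared", "permutation_p")],
      digits = 2, row.names = FALSE)
cat("Wrote results/tables/regressions.csv\n")
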