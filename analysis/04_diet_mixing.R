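#!/usr/bin/env Rscript
# Stage 4: Bayesian diet-mixing models for the top consumer.
#
# For each lake where the consumer occurs, source distributions (sediment,
# zooplankton, benthic vegetation) are summarised from the stage-1 samples
# and the per-individual consumer isotopes are fitted with the TEF-shifted
# mixture model (3 chains x 10000 iterations). Outputs one row per lake and
# source with posterior mean/median/95% interval and split-Rhat, plus the
# derived trophic-link count.

suppressPackageStartupMessages(library(arclakes))

src <- "results/synthetic"
samples <- read.csv(file.path(src, "samples.csv"))
lakes <- read.csv(file.path(src, "lakes.csv"))
tef <- trophic_enrichment()
src_names <- c("sediment", "daphnia", "vegetation_aquatic")

rows <- list(); links <- list()
for (i in which(lakes$has_lepidurus)) {
  id <- lakes$lake_id[i]
  sources <- do.call(rbind, lapply(src_names, function(s) {
    sel <- samples$lake_id == id & samples$component == s
    if (!any(sel)) return(NULL)
    data.frame(name = s,
               mean_d13c = mean(samples$d13c[sel]),
               sd_d13c = sd(samples$d13c[sel]),
               mean_d15n = mean(samples$d15n[sel]),
               sd_d15n = sd(samples$d15n[sel]))
  }))
  cons <- samples[samples$lake_id == id & samples$component == "lepidurus",
                  c("d13c", "d15n")]
  post <- fit_diet_mcmc(cons, sources, tef,
                        mixing_config(seed = 1000 + id))
  rows[[length(rows) + 1]] <- cbind(lake_id = id, post$summary)
  links[[length(links) + 1]] <- data.frame(
    lake_id = id, links = trophic_link_count(post),
    converged = post$converged)
}
diets <- do.call(rbind, rows)
link_tab <- do.call(rbind, links)
write.csv(diets, "results/tables/diet_summaries.csv", row.names = FALSE)
write.csv(link_tab, "results/tables/trophic_links.csv", row.names = FALSE)

cat("Fitted diets for", nrow(link_tab), "lakes; all chains converged:",
    all(link_tab$converged), "\n")
med <- tapply(diets$median, diets$source, mean)
cat("Mean posterior median contribution - ",
    paste(names(med), round(med, 2), collapse = ", "), "\n")
cat("Trophic links per lake:",
    paste(range(link_tab$links), collapse = " - "), "\n")
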