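#!/usr/bin/env Rscript
# Stage 6: baseline community statistics at the survey time points T1 and
# T3: Hellinger PCA of host genus composition, PERMANOVA with transect
# nested in site, SIMPER decomposition of between-site Bray-Curtis
# dissimilarity, and Hill diversity per transect sample.

suppressPackageStartupMessages(library(crabfate))

ds <- read_dataset("results/survey/colonies.csv", "results/survey/dwellings.csv")
cm <- community_matrix(ds$colony_table, time_points = c(1L, 3L))
meta <- attr(cm, "meta")
dir.create("results/community", recursive = TRUE, showWarnings = FALSE)

hel <- hellinger(cm)
pca <- comm_pca(hel)
write.csv(data.frame(sample = rownames(cm), meta,
                     pca$scores[, 1:min(3, ncol(pca$scores))]),
          "results/community/ordination_scores.csv", row.names = FALSE)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pca$variance_explained[1], 100 * pca$variance_explained[2]))

pmv <- permanova(dist(hel), site = meta$site, transect = meta$transect,
                 time_point = meta$time_point, n_perm = 999, seed = 42)
print(pmv)
jsonlite::write_json(pmv$terms, "results/community/permanova.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

smp <- simper(relative_abundance(cm), groups = meta$site)
write.csv(smp$contributions, "results/community/simper.csv", row.names = FALSE)
message(sprintf("SIMPER: mean between-site dissimilarity %.3f; top genus %s (%.1f%%)",
                smp$mean_dissimilarity, smp$contributions$genus[1],
                smp$contributions$contribution_pct[1]))

div <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i) {
  h <- hill_numbers(cm[i, ])
  data.frame(meta[i, ], N0 = h$N0, N1 = h$N1, N2 = h$N2)
}))
write.csv(div, "results/community/diversity.csv", row.names = FALSE)
message(sprintf("Hill diversity per transect: N0 %.1f, N1 %.2f, N2 %.2f (means)",
                mean(div$N0), mean(div$N1), mean(div$N2)))
message("community artifacts written to results/community/")
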