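#!/usr/bin/env Rscript
# Group-level validation of spontaneous functional connectivity: per channel
# pair, session correlations are averaged to one value per patient and a
# one-sample t-test against zero is computed per study arm (minimum-sample
# thresholds: 10 of 23 patients without diversion, 5 of 7 with). Reports how
# well the t-map signs recover the generator's clustered positive /
# interhemispheric anti-correlated structure.

library(ventsfc)

montage <- generate_montage()
records <- read_pipeline_records("results/pipeline", montage)
tgt <- default_target_correlation(montage)

for (g in c("no_diversion", "diversion")) {
  recs <- Filter(function(r) r$group == g, records)
  mp <- c(no_diversion = 10, diversion = 5)[[g]]
  tm <- group_tmap(recs, min_patients = mp)
  ok <- !tm$low_confidence & !is.na(tm$t)
  agree <- mean(sign(tm$t[ok]) == sign(tgt[cbind(tm$ch_i, tm$ch_j)])[ok])
  cat(sprintf("%s: %d/%d pairs tested (threshold %d patients), %d significant at alpha 0.05\n",
              g, sum(ok), nrow(tm), mp, sum(tm$p[ok] < 0.05)))
  cat(sprintf("  t-map sign agreement with generator targets: %.1f%%\n",
              100 * agree))
  write.csv(tm, sprintf("results/tmap_%s.csv", g), row.names = FALSE)
}

# cluster summaries of the first diversion patient, for orientation
div <- Filter(function(r) r$group == "diversion", records)
cs <- cluster_summary(div[[1]]$conn, montage$clusters)
cat("example cluster |sFC| (first diversion session):\n")
print(round(cs, 3))
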