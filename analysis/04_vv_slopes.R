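#!/usr/bin/env Rscript
# Relate |sFC| to ventricle volume with the three incremental estimators:
# per-patient OLS, linear mixed effects (random intercept, random VV slope
# where it converges), and LME additionally adjusting for gestational age.
# Each channel pair uses the volume of its own hemisphere's ventricle
# (interhemispheric pairs: mean of left and right). Hemisphere-level pooled
# t-tests aggregate the group-level slopes of all within-hemisphere pairs.
# The generator's true coupling slope is -0.002 per mL.

library(ventsfc)

montage <- generate_montage()
records <- read_pipeline_records("results/pipeline", montage)

for (g in c("no_diversion", "diversion")) {
  recs <- Filter(function(r) r$group == g, records)
  long <- sfc_long(recs, montage)
  cat(sprintf("\n== %s (%d sessions, %d pairs) ==\n", g,
              length(recs), length(unique(long$pair_id))))
  for (mth in c("ols", "lme", "lme_ga")) {
    res <- switch(mth,
                  ols = suppressWarnings(slope_ols(long)),
                  lme = slope_lme(long),
                  lme_ga = slope_lme(long, include_ga = TRUE))
    cat(sprintf("-- %s --\n", res$method))
    print(format(res$hemispheres, digits = 3), row.names = FALSE)
    write.csv(res$pairs, sprintf("results/slopes_%s_%s.csv", g, mth),
              row.names = FALSE)
    write.csv(res$hemispheres,
              sprintf("results/slopes_%s_%s_hemisphere.csv", g, mth),
              row.names = FALSE)
  }
  ga <- ga_posthoc(long)
  cat("-- GA post-hoc (VV and mean |sFC| across gestational age) --\n")
  print(format(ga, digits = 3), row.names = FALSE)
  write.csv(ga, sprintf("results/ga_posthoc_%s.csv", g), row.names = FALSE)
}
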