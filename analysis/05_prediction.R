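#!/usr/bin/env Rscript
# Stage 5: predict amygdala-dmPFC functional connectivity from behavioral
# ambiguity sensitivity and compare cohorts against controls.
#
# Reads results/behavior_fits.csv (stage 2); writes
# results/prediction_comparisons.csv.

library(ambiguitynet)

fits <- utils::read.csv(file.path("results", "behavior_fits.csv"),
                        stringsAsFactors = FALSE)
by_group <- split(fits$delta_rt_s, fits$group_label)

model <- prediction_model()          # published a = 2.4739, b = -0.1329
gp <- compare_groups_prediction(by_group, control_label = "control",
                                model = model)

message(sprintf("predicted connectivity, control mean: %.3f",
                mean(gp$predicted$control)))
for (i in seq_len(nrow(gp$comparisons))) {
  r <- gp$comparisons[i, ]
  message(sprintf(
    "%s vs control: mean diff %.3f, t(%g) = %.2f, p = %.3g, d = %.2f",
    r$group, r$mean_diff, r$df, r$t, r$p_value, r$cohens_d))
}

utils::write.csv(gp$comparisons,
                 file.path("results", "prediction_comparisons.csv"),
                 row.names = FALSE)
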