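#!/usr/bin/env Rscript
# Step 2: life-history estimation.
#
# Pre-estimates the weight-length allometry and hatch length from the
# simulated data, then fits the biphasic growth model per sex: females with
# the published structure (a_mat ~ line*food, r ~ food, beta ~ food; random
# effect on beta), males starting from a_mat ~ food, r ~ food,
# beta ~ line + food (random effects on r and beta) followed by backward
# elimination. Tables go to results/growth/.
#
# Run analysis/01_simulate.R first.

library(biphasr)

data_dir <- "results/data"
out <- "results/growth"

## Allometry and hatch length, estimated before the growth model
traj <- read.csv(file.path(data_dir, "growth_F.csv"))
trajM <- read.csv(file.path(data_dir, "growth_M.csv"))
ap <- fit_allometry(rbind(traj, trajM)) # pooled over sexes, as published
message(sprintf("allometry: alpha = %.2f, b = %.3f mg/mm^alpha", ap$alpha, ap$b))

hatch <- read.csv(file.path(data_dir, "hatch_lengths.csv"))
L0est <- estimate_L0(hatch)
message(sprintf(
  "hatch length: %.2f mm (SD %.2f, n = %d); sex F%d,%d = %.2f (p = %.2f); line F = %.2f (p = %.2f)",
  L0est$L0, L0est$sd, L0est$n, L0est$sex_test$df1, L0est$sex_test$df2,
  L0est$sex_test$F, L0est$sex_test$p, L0est$line_test$F, L0est$line_test$p))
message("model constant L0 fixed at 4.0 mm; c fixed at 0.15")

for (sex in c("F", "M")) {
  message("\n== ", if (sex == "F") "females" else "males", " ==")
  fit <- run_fit_growth(file.path(data_dir, paste0("growth_", sex, ".csv")),
                        out, sex = sex, backward = (sex == "M"))
  print(fit)
}
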