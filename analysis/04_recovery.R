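#!/usr/bin/env Rscript
# Step 4: parameter-recovery check (reduced).
#
# A quick five-replicate version of the recovery experiment the acceptance
# script runs at full size (20 replicates): simulate each published design
# at its generating values, refit, and tabulate the median recovered
# parameters next to the truth. Writes results/recovery/summary.csv.

library(biphasr)

seeds <- 1:5
out <- "results/recovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (sex in c("F", "M")) {
  cfg <- synth_config(sex)
  rec <- recover_growth(sex, seeds = seeds, config = cfg)
  gp <- rec$group_params
  for (i in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[i, ]
    sel <- gp$line == g$line & gp$food == g$food
    for (param in c("a_mat", "r", "beta"))
      rows[[length(rows) + 1]] <- data.frame(
        sex = sex, line = g$line, food = g$food, parameter = param,
        truth = g[[param]], median_estimate = median(gp[sel, param]))
  }
}
summary <- do.call(rbind, rows)
write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)

message("median recovered growth parameters over ", length(seeds),
        " replicates:")
print(summary, digits = 3, row.names = FALSE)
dev <- with(summary, abs(median_estimate - truth) / ifelse(truth > 1, truth, 1))
message(sprintf("largest relative deviation: %.1f%% (%s %s %s %s)",
                100 * max(dev), summary$sex[which.max(dev)],
                summary$line[which.max(dev)], summary$food[which.max(dev)],
                summary$parameter[which.max(dev)]))
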