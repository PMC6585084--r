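#!/usr/bin/env Rscript
# Step 1: generate the synthetic study for both sexes.
#
# Emulates the rearing experiment (2 selection lines x 2 food levels;
# 143 female / 116 male growth trajectories; 80 female / 107 male behaviour
# assays) at the published generating parameter values, and writes the
# trajectory and behaviour tables plus the generating truth under
# results/data/.

library(biphasr)

seed <- 20190619
out <- "results/data"

for (sex in c("F", "M")) {
  paths <- run_simulate(out, sex = sex, seed = seed)
  d <- read.csv(paths[["growth"]])
  b <- read.csv(paths[["behavior"]])
  message(sprintf(
    "%s: %d fish x %d occasions (ages %d..%d dph), %d behaviour assays on %d fish",
    sex, length(unique(d$fish_id)), length(unique(d$age)),
    min(d$age), max(d$age), nrow(b), length(unique(b$fish_id))))
  message(sprintf("   zero fractions: bites %.2f, freezing %.2f",
                  mean(b$bites == 0), mean(b$freeze_s == 0)))
}

# hatch-length subsamples (0 dph photographs) for the L0 pre-estimation
hatch <- rbind(generate_hatch(synth_config("F"), seed),
               generate_hatch(synth_config("M"), seed))
write.csv(hatch, file.path(out, "hatch_lengths.csv"), row.names = FALSE)
message("wrote ", file.path(out, "hatch_lengths.csv"),
        sprintf(" (%d fish, mean %.2f mm)", nrow(hatch), mean(hatch$length)))
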