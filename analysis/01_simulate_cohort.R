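#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Emulates the two-lab design: 10 experts (2 in lab A at 120 Hz, 8 in lab B
# at 60 Hz) and 10 novices (6 in A, 4 in B), each performing 20 metronome-
# paced bowing cycles (0.75 s per bow). Experts follow the expert_like
# coordination preset (shoulder+elbow transport, rectangular velocity,
# wrist compensation), novices the novice_like preset (shoulder-only,
# bell-shaped velocity). Trials are written in the package's wide-TSV +
# YAML exchange format under results/trials/.

library(bowfreeze)
options(bowfreeze.verbose = TRUE)

SEED <- 20140819 %% 100000  # cohort master seed, kept below 2^31
dir.create("results/trials", recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(n_expert = 10, n_novice = 10, seed = SEED)

for (sim in cohort) {
  id <- sim$trial$meta$participant_id
  write_trial(sim$trial, file.path("results/trials", paste0(id, ".tsv")))
}

groups <- vapply(cohort, function(x) x$trial$meta$group, character(1))
labs <- vapply(cohort, function(x) x$trial$meta$lab, character(1))
cat(sprintf("simulated %d participants (seed %d):\n", length(cohort), SEED))
print(table(group = groups, lab = labs))
cat("trials written to results/trials/\n")
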