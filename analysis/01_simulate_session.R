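#!/usr/bin/env Rscript
# Simulate one two-area laminar session with known ground truth and write it
# in the on-disk formats the rest of the workflow reads.

library(ripplepipe)

out_dir <- "results/session01"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config()
sim <- simulate_session(cfg, n_trials = 120, seed = 42,
                        session_id = "session01")

for (area in names(sim$recordings))
  write_recording(sim$recordings[[area]],
                  file.path(out_dir, paste0("session01.", area)))
write.csv(sim$trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
write_spikes(sim$spikes, file.path(out_dir, "spikes.csv"))
write.csv(sim$ground_truth, file.path(out_dir, "ground_truth.csv"),
          row.names = FALSE)

cat(sprintf(
  "session01: %d trials, %.0f s of 16-channel LFP per area at %g Hz\n",
  nrow(sim$trials), ncol(sim$recordings$V1$data) / cfg$fs, cfg$fs))
cat(sprintf("injected ripples: %d (V1: %d, V4: %d; %d cross-area partners)\n",
            nrow(sim$ground_truth),
            sum(sim$ground_truth$area == "V1"),
            sum(sim$ground_truth$area == "V4"),
            sum(sim$ground_truth$is_partner)))
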