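#!/usr/bin/env Rscript

# Stage 1: simulate the full study — 12 participants, four sessions each
# (reactive/scanning x down-up/up-down), hexagonal protocol with 48/96/96/48
# blocks — and write the raw trial table. Also writes the protocol
# description and a few example gaze traces in the documented CSV schema so
# stage 2 has raw material to run the detector on.

suppressPackageStartupMessages(library(saccadapt))

seed <- 1
out_dir <- "results"
dir.create(file.path(out_dir, "gaze"), recursive = TRUE,
           showWarnings = FALSE)

message("Simulating 12-participant cohort ...")
trials <- simulate_cohort(n_participants = 12, seed = seed)
write.table(trials, file.path(out_dir, "trials.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("  ", nrow(trials), " trials across ",
        length(unique(trials$session)), " sessions -> results/trials.tsv")

proto <- build_protocol("reactive", "down-up")
jsonlite::write_json(
  list(saccade_type = proto$saccade_type,
       direction_order = proto$direction_order,
       blocks = proto$blocks, hexagon = proto$hexagon,
       inter_target_distance = proto$inter_target_distance,
       timing = proto$timing),
  file.path(out_dir, "protocol.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

# raw gaze traces for the first 24 trials of one session (1 kHz, with the
# session's true latencies and amplitudes)
message("Synthesizing example gaze traces ...")
ses <- simulate_session(proto, seed = seed, gaze = TRUE,
                        blink_rate = 0.05)
gz <- attr(ses, "gaze")
for (i in 1:24) {
  write_gaze_csv(gz[[i]], file.path(out_dir, "gaze",
                                    sprintf("trial_%04d.csv", i)))
}
write.table(ses[1:24, ], file.path(out_dir, "gaze_trials.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("  24 traces -> results/gaze/trial_*.csv")
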