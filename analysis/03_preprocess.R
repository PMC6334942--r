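#!/usr/bin/env Rscript

# Stage 3: quality control and gain normalisation. Applies the four
# rejection rules (blink; amplitude < 3 dva; > 3 two-sided MADs from the
# block median; start point > 1.5 dva from the pre-saccadic target) and
# converts amplitudes, peak velocities and durations to gains relative to
# the per-direction medians of the first baseline block.

suppressPackageStartupMessages(library(saccadapt))

trials <- read.table("results/trials.tsv", sep = "\t", header = TRUE)
message("Loaded ", nrow(trials), " trials")

trials <- reject_trials(trials)
counts <- attr(trials, "qc_counts")
message(sprintf(
  "QC: %d blink, %d low-amplitude, %d MAD outlier, %d start-point (%.1f%% valid)",
  counts$blink, counts$amplitude_low, counts$amplitude_outlier,
  counts$startpoint_deviation, 100 * mean(trials$qc_valid)))

trials <- normalize_gain(trials)
write.table(trials, "results/gains.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
jsonlite::write_json(
  list(counts = counts, prop_valid = mean(trials$qc_valid),
       n_trials = nrow(trials)),
  "results/qc.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("  -> results/gains.tsv, results/qc.json")
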