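#!/usr/bin/env Rscript

# Stage 5: assemble the full report bundle (latencies with rm-ANOVA,
# block transitions, timescale bootstrap, dual-state contrasts, kinematic
# changes, awareness) and render summary figures.

suppressPackageStartupMessages(library(saccadapt))

trials <- read.table("results/gains.tsv", sep = "\t", header = TRUE)
rep <- build_report(trials, n_folds = 2000, seed = 1,
                    out_dir = "results/report")
message("Report written to results/report/report.json")

lat <- rep$latency$conditions
message(sprintf("  latency: reactive %.0f ms, scanning %.0f ms",
                mean(lat$mean[lat$saccade_type == "reactive"]),
                mean(lat$mean[lat$saccade_type == "scanning"])))
message(sprintf("  slow ratio: reactive %.3f, scanning %.3f",
                rep$dual_state$slow_ratio$reactive$mean,
                rep$dual_state$slow_ratio$scanning$mean))

# figures: adaptation time-courses and awareness, smoothed over the
# hexagonal period
dir.create("results/report", showWarnings = FALSE)
png("results/report/timecourses.png", width = 1200, height = 800, res = 120)
par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
for (st in c("reactive", "scanning")) {
  for (ord in c("down-up", "up-down")) {
    sel <- trials$saccade_type == st & trials$direction_order == ord
    sub <- trials[sel, ]
    avg <- aggregate(gain ~ trial, data = sub, FUN = mean, na.rm = TRUE)
    blocks <- sub$block[match(avg$trial, sub$trial)]
    sm <- running_average(avg$gain, window = 6, blocks = blocks)
    plot(avg$trial, sm, type = "l", ylim = c(0.7, 1.3),
         xlab = "trial", ylab = "gain", main = paste(st, ord))
    abline(v = cumsum(c(48, 96, 96)) + 0.5, lty = 3)
    abline(h = 1, col = "grey")
  }
}
dev.off()

png("results/report/awareness.png", width = 900, height = 500, res = 120)
aw <- rep$awareness
aw2 <- aw[aw$block == 2, ]
bp <- barplot(aw2$prop_seen,
              names.arg = paste(aw2$saccade_type, aw2$gain_direction),
              ylab = "proportion seen", las = 2, ylim = c(0, 1))
dev.off()
message("  figures -> results/report/*.png")
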