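#!/usr/bin/env Rscript
# Call gain/loss states at the 0.2/-0.2 log2 cutoffs, summarize per-sample
# CNA burden, build the 1-Mb genome-wide frequency profile, call arm-level
# events (>50% of an arm) and measure the arm gain/loss frequency
# correlation. Expects results/cohort.seg from 01_simulate_cohort.R.

suppressPackageStartupMessages(library(cnascape))

out <- "results"
build <- toy_build()
cohort <- read_seg(file.path(out, "cohort.seg"), build)
bins <- make_bins(build, 1e6)

calls <- call_states(cohort, gain_thr = 0.2, loss_thr = -0.2)
write_table(calls, file.path(out, "calls.tsv"))

burden <- burden_summary(calls)
write_table(burden$per_sample, file.path(out, "burden.tsv"))
message(sprintf("burden: %.1f events/sample, mean event size %.2f Mb, %.1f%% genome altered",
                burden$cohort$mean_events,
                burden$cohort$mean_event_size / 1e6,
                100 * burden$cohort$mean_frac_altered))

freq <- frequency_profile(calls, bins)
write_table(freq, file.path(out, "frequency.tsv"))
p <- plot_frequency_profile(freq)
ggplot2::ggsave(file.path(out, "frequency_profile.png"), p,
                width = 10, height = 3, dpi = 150)

arm_events <- call_arm_events(calls, build)
write_table(arm_events, file.path(out, "arm_events.tsv"))
corr <- arm_gain_loss_correlation(arm_events, length(cohort$samples), build)
write_table(corr$arm_freqs, file.path(out, "arm_frequencies.tsv"))
message(sprintf("arm events: %d; gain/loss frequency correlation r = %.3f (p = %.2g)",
                nrow(arm_events), corr$r, corr$p))
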