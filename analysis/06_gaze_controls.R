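#!/usr/bin/env Rscript
# Stage 6: eye-movement control analyses.
#
# Under the generator's default colour-independent gaze (fixational
# jitter only), the gaze-bias statistic should average near 0.5 -- the
# gaze spends equal time nearest target- and distractor-coloured items --
# saccade/blink counts should not differ between fast and slow trials,
# and nearly all gaze samples should stay within 1 degree of fixation.

suppressPackageStartupMessages(library(riftsearch))
cfg <- read_sim_config("results/config.json")
exp <- generate_experiment(cfg)   # with layouts and gaze traces
trials <- median_split(exclude_trials(exp$trials)$trials)

bias <- vapply(seq_len(nrow(trials)), function(i) {
  k <- trials$trial_index[i] + 1L
  gaze_bias(exp$gaze[[k]], exp$layouts[[k]])$fraction
}, 0)
cat(sprintf("gaze bias: mean %.3f (se %.3f) over %d trials\n",
            mean(bias), sd(bias) / sqrt(length(bias)), length(bias)))

counts <- event_counts_by_split(exp$gaze, trials)
print(counts$summary, row.names = FALSE)
fast <- counts$per_trial$split == "fast"
tt <- t.test(counts$per_trial$saccades[fast],
             counts$per_trial$saccades[!fast])
cat(sprintf("fast vs slow saccade counts: t = %.2f, p = %.3f\n",
            tt$statistic, tt$p.value))

hm <- fixation_heatmap(exp$gaze)
cat(sprintf("fraction of gaze samples within the 1-degree box: %.3f\n",
            hm$fraction_in_box))

write.csv(counts$summary, "results/gaze_event_counts.csv",
          row.names = FALSE)
write.csv(data.frame(trial_index = trials$trial_index, bias = bias,
                     split = trials$split),
          "results/gaze_bias.csv", row.names = FALSE)
cat("wrote results/gaze_bias.csv, results/gaze_event_counts.csv\n")
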