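#!/usr/bin/env Rscript
# Stage 2: behavioural performance.
#
# Excludes no-response trials and reaction times at or below 200 ms, then
# summarises mean reaction time and sensitivity (d') per condition cell
# and attaches the fast/slow median-split labels used by later control
# analyses. Expected pattern: faster and more sensitive search under
# guidance and for the smaller set size.

suppressPackageStartupMessages(library(riftsearch))
trials <- read_trial_table("results/trials.csv")

excl <- exclude_trials(trials)
cat(sprintf("excluded %d of %d trials (%s)\n", nrow(excl$log), nrow(trials),
            paste(names(table(excl$log$reason)),
                  table(excl$log$reason), collapse = ", ")))
write.csv(excl$log, "results/exclusion_log.csv", row.names = FALSE)

summ <- condition_summary(excl$trials)
print(summ, row.names = FALSE)
write.csv(summ, "results/behaviour_summary.csv", row.names = FALSE)

split <- median_split(excl$trials)
write_trial_table(split, "results/trials_clean.csv")
cat("wrote results/behaviour_summary.csv, results/trials_clean.csv\n")
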