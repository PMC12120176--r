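#!/usr/bin/env Rscript
# Per-tool three-zone calibration: PP3/BP4 likelihood ratios, evidence
# strengths and uninformative fractions at the study thresholds, plus an
# exhaustive threshold search for the pathogenicity score.

library(pp3bp4)

analysis <- read_variant_table("results/analysis_cohort.tsv")
manifest <- run_pipeline(analysis_config(seed = 20240101), "results",
                         stages = "calibrate", variant_table = analysis)
calib <- utils::read.delim("results/calibration.tsv")
for (i in seq_len(nrow(calib))) {
  message(sprintf("%-8s BP4 log2 LR %+0.2f (%s) | PP3 log2 LR %+0.2f (%s) | gray %.0f%%",
                  calib$tool[i], calib$log2_lr_benign[i],
                  calib$strength_benign[i], calib$log2_lr_path[i],
                  calib$strength_path[i], 100 * calib$gray_fraction[i]))
}

# trade-off search: maximise evidence strength on both sides while
# minimising the uninformative fraction
grid <- sort(unique(c(seq(0.05, 0.95, by = 0.05), 0.65, 0.75)))
front <- search_thresholds(analysis, "AM", grid,
                           min_abs_log2_each_side = 2,
                           max_gray_fraction = 0.25)
write_results_table(front, "results/threshold_search_am.tsv")
message(sprintf("Threshold search (pathogenicity score): %d Pareto-optimal pairs; best: <= %.2f / >= %.2f, gray %.1f%%.",
                nrow(front), front$benign_cut[1], front$path_cut[1],
                100 * front$gray_fraction[1]))
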