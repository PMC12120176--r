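#!/usr/bin/env Rscript
# RSA-stratified likelihood ratios, tool-pair concordance, and the cascade
# (RSA -> pathogenicity score -> stability score) evidence assignment.

library(pp3bp4)

analysis <- read_variant_table("results/analysis_cohort.tsv")
run_pipeline(analysis_config(seed = 20240101), "results",
             stages = "stratify", variant_table = analysis)

strat <- utils::read.delim("results/stratified.tsv")
ddg <- strat[strat$tool == "DDG_AF", ]
message("Stability-score benignity evidence by RSA bin (significant?):")
for (i in seq_len(nrow(ddg))) {
  message(sprintf("  %-8s log2 LR %+0.2f  significant benignity: %s",
                  ddg$stratum[i], ddg$log2_lr_benign[i],
                  ddg$significant_benign[i]))
}

cc <- concordance_evaluate(analysis, three_zone("AM", 0.65, 0.75),
                           three_zone("DDG_AF", 1.5, 2.5))
message(sprintf("Concordance (pathogenicity + stability): PP3 log2 LR %+0.2f, BP4 %+0.2f, uninformative %.0f%%.",
                cc$lr_path$log2_lr, cc$lr_benign$log2_lr,
                100 * cc$uninformative_fraction))

casc <- cascade_assign(analysis, default_cascade())
message(sprintf("Cascade assignment: %.0f%% of variants uninformative after leaf demotion.",
                100 * casc$gray_fraction))
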