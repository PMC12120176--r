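#!/usr/bin/env Rscript
# Discrimination analysis: auROCs with paired bootstrap comparisons,
# correlations with the MAVE functional score, and the diagnostic test
# evaluation of the pathogenicity-score PP3 threshold.

library(pp3bp4)

analysis <- read_variant_table("results/analysis_cohort.tsv")
run_pipeline(analysis_config(seed = 20240101), "results",
             stages = "evaluate", variant_table = analysis)
disc <- utils::read.delim("results/discrimination.tsv")
for (i in seq_len(nrow(disc))) {
  message(sprintf("%-8s auROC %.3f | r(MAVE) %+0.2f", disc$tool[i],
                  disc$auroc[i], disc$r_mave[i]))
}

lab <- analysis$functional_class == "LOF"
cmp <- bootstrap_auroc_test(analysis$AM, analysis$DDG_PDB, lab,
                            n_boot = 2000, seed = 20240101)
message(sprintf("Pathogenicity score vs experimental-template stability score: delta auROC %+0.3f, p = %.2g (2,000 bootstraps).",
                cmp$delta_auroc, cmp$p_value))

ct <- count_zones(analysis, three_zone("AM", 0.75, 0.75))
dm <- diagnostic_metrics(tp = ct$lof_path, fn = ct$lof_benign,
                         fp = ct$func_path, tn = ct$func_benign)
print(dm)
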