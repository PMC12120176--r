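#!/usr/bin/env Rscript
# Assign MAVE functional classes and RSA bins, then restrict to the
# LoF/FUNC analysis cohort (dropping intermediate variants, whose link with
# disease predisposition is unclear).

library(pp3bp4)

cohort <- read_variant_table("results/simulated_cohort.tsv")
cohort <- classify_variants(cohort)
analysis <- build_analysis_cohort(cohort)
write_results_table(as.data.frame(analysis), "results/analysis_cohort.tsv")

cc <- attr(analysis, "class_counts")
message(sprintf("Analysis cohort: %d variants (%d LoF + %d FUNC); %d INT filtered out.",
                nrow(analysis), cc["LOF"], cc["FUNC"], cc["INT"]))
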