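#!/usr/bin/env Rscript
# Assemble the full-run manifest and render the human-readable report.

library(pp3bp4)

analysis <- read_variant_table("results/analysis_cohort.tsv")
manifest <- run_pipeline(analysis_config(seed = 20240101), "results",
                         stages = c("classify", "calibrate", "stratify",
                                    "evaluate", "burden"),
                         variant_table = analysis)
render_report(manifest, "results/report.md")
message("Report written to results/report.md")
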