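#!/usr/bin/env Rscript
# Stage 4: deviations from normative ageing.
#
# Computes observed-minus-predicted MS deviations for patients and controls
# against the normative model, tests them per region within the five age
# categories (FDR q < 0.01), and classifies each significant deviation as
# consistent or inconsistent with accelerated ageing via the slope-sign rule.

suppressPackageStartupMessages(library(msageing))
seed <- 2026L

model <- read_normative_model("results/tables/normative_model.csv")
demo_cc <- read.csv("results/tables/demographics_casecontrol.csv")
ms_cc <- read_regional_ms("results/tables/regional_ms_casecontrol.csv")

report <- function(group_label) {
  keep <- demo_cc$group == group_label
  dev <- suppressWarnings(
    compute_deviations(ms_cc[keep, ], demo_cc[keep, ], model, policy = "drop"))
  tst <- test_deviations(dev, model, fdr_q = 0.01, seed = seed)
  s <- summarize_deviations(tst)
  cat(sprintf("\n%s (n = %d):\n", group_label, sum(keep)))
  print(s$by_category, row.names = FALSE)
  cat(sprintf("Distinct significant regions: %d; accelerated-consistent: %d (%.0f%%)\n",
              s$overall$n_significant_regions, s$overall$n_consistent_regions,
              s$overall$pct_consistent))
  write.csv(tst, sprintf("results/tables/deviation_tests_%s.csv", group_label),
            row.names = FALSE)
  s
}

s_pat <- report("patient")
s_ctrl <- report("control")
cat(sprintf("\nPatients show %d deviant regions vs %d in controls.\n",
            s_pat$overall$n_significant_regions,
            s_ctrl$overall$n_significant_regions))
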