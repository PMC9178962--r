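#!/usr/bin/env Rscript
# Stage 6: brain-age gaps.
#
# Trains the lasso age model on normative regional MS (5-fold CV), reports
# the raw gap-age correlation on held-out normative data (regression to the
# mean), and compares patient vs control brain-age gaps.

suppressPackageStartupMessages(library(msageing))
seed <- 2026L

demo_norm <- read.csv("results/tables/demographics_normative.csv")
ms_norm <- read_regional_ms("results/tables/regional_ms_normative.csv")
demo_cc <- read.csv("results/tables/demographics_casecontrol.csv")
ms_cc <- read_regional_ms("results/tables/regional_ms_casecontrol.csv")

train_idx <- seq_len(500)
model <- train_age_model(ms_norm[train_idx, ], demo_norm$age[train_idx],
                         seed = seed)
print(model)
write_brain_age_model(model, "results/tables/brain_age_model.json")

bias <- estimate_bias_correction(model, ms_norm[-train_idx, ],
                                 demo_norm$age[-train_idx])
cat(sprintf("Held-out raw gap-age correlation: %.3f (bias slope %.3f)\n",
            bias$gap_age_correlation, bias$slope))

gaps <- compute_gaps(model, ms_cc, demo_cc$age)
cmp <- compare_gaps(gaps, demo_cc$group)
cat(sprintf("Brain-age gap, patient minus control: %+.2f years (t = %.1f, p = %.2g)\n",
            cmp$difference, cmp$t, cmp$p))
write.csv(gaps, "results/tables/brain_age_gaps.csv", row.names = FALSE)
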