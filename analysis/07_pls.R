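#!/usr/bin/env Rscript
# Stage 7: PLS of regional MS against age and PAL errors.
#
# Two-component PLS2 regression of the 230x360 MS block (115 controls + 115
# patients with PAL available) on the 230x2 outcome block (age, PAL total
# errors), with 5000-permutation component significance, score-outcome
# correlations, group comparison of component scores, and the correlation
# of loading maps with the case-control t map.

suppressPackageStartupMessages(library(msageing))
seed <- 2026L

demo_cc <- read.csv("results/tables/demographics_casecontrol.csv")
ms_cc <- read_regional_ms("results/tables/regional_ms_casecontrol.csv")
pal <- read.csv("results/tables/pal_scores.csv")
cc <- read.csv("results/tables/case_control_map.csv")

set.seed(seed)
avail <- unlist(lapply(split(demo_cc$subject_id, demo_cc$group),
                       sample, size = 115))
idx <- demo_cc$subject_id %in% avail
Y <- cbind(age = demo_cc$age[idx],
           pal_errors = pal$total_errors[match(demo_cc$subject_id[idx],
                                               pal$subject_id)])
X <- ms_cc[idx, ]

fit <- fit_pls(X, Y, n_components = 2)
print(fit)
sig <- pls_permutation(X, Y, n_components = 2, n_perm = 5000, seed = seed + 1)
cat(sprintf("Permutation p: PLS1 %.4f, PLS2 %.4f (5000 shuffles)\n",
            sig$p[1], sig$p[2]))

cat("\nScore-outcome correlations:\n")
print(score_outcome_correlations(fit, Y), row.names = FALSE)

grp <- group_score_comparison(fit, demo_cc$group[idx], n_perm = 1000,
                              seed = seed + 2)
cat("\nGroup comparison of component scores (control minus patient):\n")
print(grp, row.names = FALSE)

lm_cor <- loading_map_correlation(fit, setNames(cc$t, cc$region),
                                  n_perm = 1000, seed = seed + 3)
cat("\nLoading map vs case-control t map:\n")
print(lm_cor, row.names = FALSE)

write.csv(data.frame(region = rownames(fit$x_loadings), fit$x_loadings),
          "results/tables/pls_loadings.csv", row.names = FALSE)
write.csv(data.frame(subject_id = demo_cc$subject_id[idx], fit$scores),
          "results/tables/pls_scores.csv", row.names = FALSE)
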