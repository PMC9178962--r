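# End-to-end synthetic pipeline: simulate -> MS -> normative trajectories ->
# deviations -> case-control -> brain age -> PLS. All randomness flows from
# the single run seed through fixed per-stage offsets, so a config run twice
# produces bit-identical bundles.

#' Pipeline run configuration
#'
#' Defaults mirror the study conditions: a normative cohort of 665 subjects
#' aged 20-80, a case-control cohort of 148 controls and 183 patients aged
#' 18-59, patient MS profiles shifted +10 years along decreasing
#' trajectories, PAL available for 115 subjects per group, FDR q = 0.01,
#' reference ages 27/60, five age categories 20-30/30-35/35-40/40-45/45-60.
#'
#' @param seed run seed; every stage derives its own seed from it.
#' @param n_normative,normative_age_range normative cohort size and ages.
#' @param n_control,n_patient,casecontrol_age_range case-control cohort sizes
#'   and age span.
#' @param mode `"ms"` (generate regional MS directly) or `"feature"`
#'   (generate raw 7-feature tables and derive MS).
#' @param delta_years,injection_regions patient aged-injection settings.
#' @param reference_ages early/late ages for shape classification.
#' @param age_breaks age-category partition.
#' @param fdr_q,fdr_method FDR settings.
#' @param n_perm permutation count for the permutation-tested stages.
#' @param pls_n_perm permutations for PLS component significance.
#' @param pal_n_per_group subjects per group with PAL available.
#' @param cv_folds folds for the lasso age model.
#' @param n_components PLS components.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_normative = 665L, normative_age_range = c(20, 80),
                            n_control = 148L, n_patient = 183L,
                            casecontrol_age_range = c(18, 59),
                            mode = c("ms", "feature"),
                            delta_years = 10, injection_regions = "decreasing",
                            reference_ages = c(27, 60),
                            age_breaks = c(20, 30, 35, 40, 45, 60),
                            fdr_q = 0.01, fdr_method = "BH",
                            n_perm = 1000L, pls_n_perm = 1000L,
                            pal_n_per_group = 115L, cv_folds = 5L,
                            n_components = 2L,
                            gap_convention = "predicted_minus_calendar",
                            n_regions = 360L) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, MS construction, normative trajectory fitting,
#' deviation analysis, case-control comparison, brain-age modelling and PLS
#' in order, on synthetic cohorts generated from the ground-truth
#' trajectory set. When `out_dir` is given, every table is written as CSV
#' together with self-describing JSON metadata (config, seeds, convention
#' flags, parcellation hash).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return result bundle (named list of every stage's outputs).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  parcellation <- default_parcellation(config$n_regions)

  ## simulate ----
  trajectories <- default_trajectories(parcellation, seed = derive_seed(seed, 1),
                                       early = config$reference_ages[1],
                                       late = config$reference_ages[2])
  demo_norm <- sample_cohort(cohort_spec(config$n_normative,
                                         config$normative_age_range,
                                         group = "normative",
                                         seed = derive_seed(seed, 2)))
  demo_ctrl <- sample_cohort(cohort_spec(config$n_control,
                                         config$casecontrol_age_range,
                                         sex_ratio = 0.19, group = "control",
                                         seed = derive_seed(seed, 3)))
  demo_pat <- sample_cohort(cohort_spec(config$n_patient,
                                        config$casecontrol_age_range,
                                        sex_ratio = 0.10, group = "patient",
                                        seed = derive_seed(seed, 4)))
  demo_cc <- rbind(demo_ctrl, demo_pat)
  injection <- aged_injection(config$delta_years, config$injection_regions)

  gen <- function(demo, inj, off) {
    if (config$mode == "ms") {
      generate_regional_ms(demo, trajectories, inj, seed = derive_seed(seed, off))
    } else {
      ft <- generate_feature_table(demo, trajectories, inj,
                                   seed = derive_seed(seed, off),
                                   parcellation_seed = derive_seed(seed, 90))
      cohort_regional_ms(ft)
    }
  }
  ms_norm <- gen(demo_norm, NULL, 5)
  ms_cc <- gen(demo_cc, injection, 6)
  pal <- generate_pal(demo_cc, seed = derive_seed(seed, 7),
                      breaks = config$age_breaks)

  ## ms maps ----
  map_norm <- cohort_mean_map(ms_norm)
  map_ctrl <- cohort_mean_map(ms_cc[demo_cc$group == "control", , drop = FALSE])
  map_cor <- map_correlation(map_norm, map_ctrl)

  ## normative trajectories ----
  model <- fit_normative_model(ms_norm, demo_norm$age,
                               early = config$reference_ages[1],
                               late = config$reference_ages[2])

  ## deviations (patients vs normative model; controls as reference) ----
  dev_pat <- suppressWarnings(
    compute_deviations(ms_cc[demo_cc$group == "patient", , drop = FALSE],
                       demo_pat, model, breaks = config$age_breaks, policy = "drop"))
  dev_tests <- test_deviations(dev_pat, model, fdr_q = config$fdr_q,
                               fdr_method = config$fdr_method,
                               seed = derive_seed(seed, 8))
  dev_summary <- summarize_deviations(dev_tests)
  dev_ctrl <- suppressWarnings(
    compute_deviations(ms_cc[demo_cc$group == "control", , drop = FALSE],
                       demo_ctrl, model, breaks = config$age_breaks, policy = "drop"))
  dev_tests_ctrl <- test_deviations(dev_ctrl, model, fdr_q = config$fdr_q,
                                    fdr_method = config$fdr_method,
                                    seed = derive_seed(seed, 9))
  dev_summary_ctrl <- summarize_deviations(dev_tests_ctrl)

  ## case-control map ----
  cc_map <- case_control_map(ms_cc, demo_cc$group, fdr_q = config$fdr_q,
                             fdr_method = config$fdr_method,
                             n_perm = config$n_perm,
                             seed = derive_seed(seed, 10))
  t_map <- stats::setNames(cc_map$t, cc_map$region)
  hub <- hub_relationship(t_map, map_ctrl, n_perm = config$n_perm,
                          seed = derive_seed(seed, 11))

  ## brain age ----
  ba_model <- train_age_model(ms_norm, demo_norm$age, n_folds = config$cv_folds,
                              seed = derive_seed(seed, 12))
  bias <- estimate_bias_correction(ba_model, ms_norm, demo_norm$age)
  gaps <- compute_gaps(ba_model, ms_cc, demo_cc$age,
                       convention = config$gap_convention)
  gap_cmp <- compare_gaps(gaps, demo_cc$group)

  ## PAL model + PLS (on the PAL-available complete subset) ----
  avail <- withr_seed(derive_seed(seed, 13), {
    pick <- function(g) sample(demo_cc$subject_id[demo_cc$group == g],
                               min(config$pal_n_per_group, sum(demo_cc$group == g)))
    c(pick("control"), pick("patient"))
  })
  idx <- demo_cc$subject_id %in% avail
  pal_fit <- pal_model(pal[match(demo_cc$subject_id[idx], pal$subject_id), ],
                       demo_cc[idx, ], breaks = config$age_breaks)
  Y <- cbind(age = demo_cc$age[idx],
             pal_errors = pal$total_errors[match(demo_cc$subject_id[idx],
                                                 pal$subject_id)])
  X <- ms_cc[idx, , drop = FALSE]
  pls <- fit_pls(X, Y, n_components = config$n_components)
  pls_sig <- pls_permutation(X, Y, n_components = config$n_components,
                             n_perm = config$pls_n_perm,
                             seed = derive_seed(seed, 14))
  pls_cor <- score_outcome_correlations(pls, Y)
  pls_groups <- group_score_comparison(pls, demo_cc$group[idx],
                                       n_perm = config$n_perm,
                                       seed = derive_seed(seed, 15))
  pls_vs_t <- loading_map_correlation(pls, t_map, n_perm = config$n_perm,
                                      seed = derive_seed(seed, 16))

  bundle <- list(config = config, parcellation = parcellation,
                 trajectories = trajectories,
                 demographics = list(normative = demo_norm, casecontrol = demo_cc),
                 ms = list(normative = ms_norm, casecontrol = ms_cc),
                 maps = list(normative = map_norm, control = map_ctrl,
                             correlation = map_cor),
                 normative_model = model,
                 deviations = list(patient_tests = dev_tests,
                                   patient_summary = dev_summary,
                                   control_tests = dev_tests_ctrl,
                                   control_summary = dev_summary_ctrl),
                 case_control = list(map = cc_map, hub = hub),
                 brain_age = list(model = ba_model, bias = bias, gaps = gaps,
                                  comparison = gap_cmp),
                 pal = list(table = pal, fit = pal_fit),
                 pls = list(fit = pls, significance = pls_sig,
                            score_correlations = pls_cor,
                            group_comparison = pls_groups,
                            t_map_correlation = pls_vs_t))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Write the bundle's tabular artifacts plus self-describing metadata.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(bundle$demographics$normative, fp("demographics_normative.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$demographics$casecontrol, fp("demographics_casecontrol.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$trajectories, fp("ground_truth_trajectories.csv"),
                   row.names = FALSE, quote = FALSE)
  write_regional_ms(bundle$ms$normative, fp("regional_ms_normative.csv"))
  write_regional_ms(bundle$ms$casecontrol, fp("regional_ms_casecontrol.csv"))
  write_normative_model(bundle$normative_model, fp("normative_model.csv"))
  utils::write.csv(bundle$deviations$patient_tests, fp("deviation_tests_patient.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$case_control$map, fp("case_control_map.csv"),
                   row.names = FALSE, quote = FALSE)
  write_brain_age_model(bundle$brain_age$model, fp("brain_age_model.json"))
  utils::write.csv(bundle$brain_age$gaps, fp("brain_age_gaps.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$pal$table, fp("pal_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(region = rownames(bundle$pls$fit$x_loadings),
                              bundle$pls$fit$x_loadings), fp("pls_loadings.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    map_correlation_normative_vs_control = bundle$maps$correlation$r,
    trajectory_categories = as.list(table(bundle$normative_model$trajectories$category)),
    n_excluded_regions = bundle$normative_model$n_excluded,
    deviations_patient = bundle$deviations$patient_summary,
    deviations_control = bundle$deviations$control_summary$overall,
    n_significant_case_control_fdr = sum(bundle$case_control$map$significant),
    n_significant_case_control_perm = sum(bundle$case_control$map$p_perm < bundle$config$fdr_q,
                                          na.rm = TRUE),
    hub_relationship = bundle$case_control$hub[c("r", "p_perm")],
    brain_age = bundle$brain_age$comparison,
    pal_effects = bundle$pal$fit$effects,
    pls_pct_var = bundle$pls$fit$pct_var_y,
    pls_p = bundle$pls$significance$p
  )
  meta <- run_metadata(bundle$config, bundle$parcellation)
  jsonlite::write_json(list(metadata = meta, summary = summary),
                       fp("run_summary.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(out_dir)
}
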