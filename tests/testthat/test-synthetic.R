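# Synthetic cohort generator: reproducibility, ground-truth closure,
# PAL calibration, and the feature-level mode.

test_that("cohort sampling is seeded, bounded, and validates its spec", {
  s <- cohort_spec(10, c(20, 80), seed = 1)
  expect_identical(sample_cohort(s), sample_cohort(s))
  big <- sample_cohort(cohort_spec(665, c(20, 80), seed = 2))
  expect_true(all(big$age >= 20 & big$age <= 80))
  expect_equal(nrow(big), 665L)
  expect_false(any(duplicated(big$subject_id)))
  # uniform-moment check: mean age within 3 SE of 50 at n = 5000
  huge <- sample_cohort(cohort_spec(5000, c(20, 80), seed = 3))
  se <- (80 - 20) / sqrt(12) / sqrt(5000)
  expect_lt(abs(mean(huge$age) - 50), 3 * se)
  expect_error(cohort_spec(1, c(20, 80)), "n_subjects")
  expect_error(cohort_spec(10, c(80, 20)), "age_range")
  expect_error(cohort_spec(10, c(20, 80), sex_ratio = 2), "sex_ratio")
})

test_that("noise-free regional MS lies exactly on its trajectory", {
  tr <- default_trajectories(default_parcellation(12), seed = 4,
                             class_counts = c(increasing = 4L, decreasing = 4L,
                                              convex = 2L, concave = 2L),
                             noise_sd = 0)
  demo <- sample_cohort(cohort_spec(15, c(20, 80), seed = 5))
  ms <- generate_regional_ms(demo, tr, seed = 6, subject_sd = 0)
  expect_equal(unname(ms), unname(evaluate_trajectories(tr, demo$age)),
               tolerance = 1e-12)
})

test_that("aged injection shifts patient evaluation ages only where affected", {
  tr <- default_trajectories(default_parcellation(10), seed = 7,
                             class_counts = c(increasing = 4L, decreasing = 4L,
                                              convex = 1L, concave = 1L),
                             noise_sd = 0)
  demo <- rbind(sample_cohort(cohort_spec(5, c(25, 50), group = "control", seed = 8)),
                sample_cohort(cohort_spec(5, c(25, 50), group = "patient", seed = 9)))
  affected <- tr$region[tr$shape == "decreasing"]
  ms <- generate_regional_ms(demo, tr, aged_injection(10, affected),
                             seed = 10, subject_sd = 0)
  pat <- demo$group == "patient"
  expect_equal(unname(ms[pat, affected]),
               unname(evaluate_trajectories(tr, demo$age[pat] + 10)[, affected]),
               tolerance = 1e-12)
  unaffected <- setdiff(tr$region, affected)
  expect_equal(unname(ms[, unaffected]),
               unname(evaluate_trajectories(tr, demo$age)[, unaffected]),
               tolerance = 1e-12)
  expect_error(generate_regional_ms(demo, tr, aged_injection(10, "no_such_region")),
               "not in parcellation")
})

test_that("refitting recovers the generating quadratics within 3 SE", {
  tr <- default_trajectories(seed = 11)
  demo <- sample_cohort(cohort_spec(665, c(20, 80), group = "normative", seed = 12))
  ms <- generate_regional_ms(demo, tr, seed = 13)
  fit <- fit_trajectories(ms, demo$age, degree = 2)
  m <- merge(tr, fit, by = "region", suffixes = c(".true", ".fit"))
  z <- c((m$a0.fit - m$a0.true) / m$se_a0,
         (m$a1.fit - m$a1.true) / m$se_a1,
         (m$a2.fit - m$a2.true) / m$se_a2)
  # |z| <= 3 holds for ~99.7% of coefficients; allow binomial slack
  expect_gt(mean(abs(z) <= 3), 0.985)
})

test_that("PAL generation honours its spec and calibrated effect sizes", {
  demo <- rbind(sample_cohort(cohort_spec(40, c(25, 55), group = "control", seed = 14)),
                sample_cohort(cohort_spec(40, c(25, 55), group = "patient", seed = 15)))
  # noise-free, pure group effect: difference exactly 10 at every age
  sp <- pal_spec(beta_intercept = 20, beta_age = 0, beta_group = 10, noise_sd = 0)
  pal <- generate_pal(demo, sp, seed = 16)
  expect_true(all(pal$total_errors[demo$group == "patient"] == 30))
  expect_true(all(pal$total_errors[demo$group == "control"] == 20))
  # intercept only: constant scores
  sp0 <- pal_spec(beta_intercept = 12, beta_age = 0, beta_group = 0, noise_sd = 0)
  expect_true(all(generate_pal(demo, sp0, seed = 17)$total_errors == 12))
  expect_error(pal_spec(noise_sd = -1), "noise_sd")
  # calibrated per-category betas: realized d within +/-0.3 of targets
  # (averaged over replicates; single-draw d at ~15 per group is too noisy)
  targets <- c("20-30" = 1.6, "30-35" = 1.1, "35-40" = 1.2,
               "40-45" = 1.6, "45-60" = 0.7)
  reps <- lapply(1:10, function(r) {
    dd <- rbind(sample_cohort(cohort_spec(115, c(18, 59), group = "control",
                                          seed = 100 + r)),
                sample_cohort(cohort_spec(115, c(18, 59), group = "patient",
                                          seed = 200 + r)))
    pp <- generate_pal(dd, seed = 300 + r)
    pal_model(pp, dd)$d_by_category$d
  })
  mean_d <- rowMeans(do.call(cbind, reps))
  expect_true(all(abs(mean_d - unname(targets)) <= 0.3))
})

test_that("feature tables are seeded, finite, and on plausible scales", {
  tr <- default_trajectories(default_parcellation(10), seed = 18,
                             class_counts = c(increasing = 4L, decreasing = 4L,
                                              convex = 1L, concave = 1L))
  demo <- sample_cohort(cohort_spec(6, c(20, 80), seed = 19))
  ft1 <- generate_feature_table(demo, tr, seed = 20)
  ft2 <- generate_feature_table(demo, tr, seed = 20)
  expect_identical(ft1, ft2)
  vals <- as.matrix(ft1[, !(names(ft1) %in% c("subject_id", "region"))])
  expect_true(all(is.finite(vals)))
  expect_true(all(ft1$gm_volume > 0 & ft1$surface_area > 0 & ft1$thickness > 0))
  expect_error(generate_feature_table(demo, tr[1, , drop = FALSE], seed = 21),
               "2 regions")
})

test_that("derived MS tracks the target trajectories (calibration run)", {
  # Fixed-seed calibration experiment: monotone-trajectory regions with
  # reference-age slopes above the documented floor must correlate >= 0.9
  # with their targets in decade-binned means; feature-derived and direct
  # MS-level fits must agree on shape classification for >= 90% of such
  # regions. Curved (convex/concave) low-amplitude trajectories resolve
  # less well in decade bins and are held to a median-correlation check.
  tr <- default_trajectories(seed = 22)
  demo <- sample_cohort(cohort_spec(600, c(20, 80), group = "normative", seed = 23))
  ft <- generate_feature_table(demo, tr, seed = 24)
  ms_f <- cohort_regional_ms(ft)
  dec <- cut(demo$age, seq(20, 80, 10), include.lowest = TRUE)
  binned <- apply(ms_f, 2, function(v) tapply(v, dec, mean))
  targ <- evaluate_trajectories(tr, seq(25, 75, 10))
  cors <- suppressWarnings( # flat noise-region targets have zero variance
    sapply(seq_len(ncol(ms_f)), function(j) cor(binned[, j], targ[, j])))
  floor_ms <- 0.0018
  min_slope <- pmin(abs(tr$a1 + 2 * tr$a2 * 27), abs(tr$a1 + 2 * tr$a2 * 60))
  monotone <- tr$shape %in% c("increasing", "decreasing") & min_slope >= floor_ms
  curved <- tr$shape %in% c("convex", "concave") & min_slope >= floor_ms
  expect_gt(mean(cors[monotone] >= 0.9), 0.95)
  # curved trajectories have lower binned-mean amplitude; recorded floor 0.5
  expect_gt(median(cors[curved]), 0.5)
  # mode agreement on shape classification
  fit_f <- fit_normative_model(ms_f, demo$age)$trajectories
  ms_d <- generate_regional_ms(demo, tr, seed = 25)
  fit_d <- fit_normative_model(ms_d, demo$age)$trajectories
  both <- fit_f$retained & fit_d$retained & (monotone | curved)
  agree <- fit_f$category[both] == fit_d$category[both]
  expect_gt(mean(agree), 0.9)
})
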