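# Deviation computation, age categories, one-sample tests, and the
# accelerated-ageing direction rules.

fake_model <- function(trdf, age_range = c(20, 80)) {
  trdf$retained <- trdf$retained %||% TRUE
  structure(list(trajectories = trdf, reference_ages = c(early = 27, late = 60),
                 age_range = age_range, n_subjects = 100L, n_excluded = 0L),
            class = "normative_model")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("age categories use half-open intervals with a closed top", {
  expect_equal(as.character(assign_age_category(25)), "20-30")
  expect_equal(as.character(assign_age_category(30)), "30-35")
  expect_equal(as.character(assign_age_category(60)), "45-60")
  expect_error(assign_age_category(18), "outside")
  expect_warning(out <- assign_age_category(c(18, 25), policy = "drop"), "NA")
  expect_true(is.na(out[1]) && !is.na(out[2]))
})

test_that("deviations are observed minus predicted on retained regions", {
  tr <- data.frame(region = c("r1", "r2"), a0 = c(0.5, 0.1),
                   a1 = c(-0.005, 0), a2 = c(0, 0),
                   adj_r2 = c(0.5, 0.5), retained = c(TRUE, TRUE),
                   stringsAsFactors = FALSE)
  model <- fake_model(tr)
  demo <- data.frame(subject_id = "s1", age = 40, group = "patient",
                     stringsAsFactors = FALSE)
  # trajectory predicts 0.30 at age 40; observed 0.25 -> deviation -0.05
  ms <- matrix(c(0.25, 0.1), 1, 2, dimnames = list("s1", c("r1", "r2")))
  dev <- compute_deviations(ms, demo, model)
  expect_equal(dev$deviation[dev$region == "r1"], -0.05)
  expect_equal(dev$deviation[dev$region == "r2"], 0)
  # ages outside the normative range are flagged (age 25 is a valid
  # category but below this model's fitting range)
  model_narrow <- fake_model(tr, age_range = c(30, 80))
  demo2 <- data.frame(subject_id = "s2", age = 25, group = "patient")
  rownames(ms) <- "s2"
  expect_warning(dev2 <- compute_deviations(ms, demo2, model_narrow), "extrapolated")
  expect_true(all(dev2$extrapolated))
})

test_that("normative subjects deviate from their own model by ~0", {
  w <- make_small_world(seed = 41)
  # normative ages run to 80 while categories stop at 60: NA categories expected
  dev <- suppressWarnings(compute_deviations(w$ms, w$demographics, w$model))
  per_region <- tapply(dev$deviation, dev$region, mean)
  n_cat <- table(dev$category[!duplicated(dev$subject_id)])
  se <- tapply(dev$deviation, dev$region, sd) /
    sqrt(tapply(dev$deviation, dev$region, length))
  expect_gt(mean(abs(per_region) <= 3 * se), 0.98)
})

test_that("one-sample deviation tests match the t formula and control FDR", {
  tr <- data.frame(region = sprintf("r%02d", 1:20), a0 = 0.3, a1 = -0.002,
                   a2 = 0, adj_r2 = 0.5, retained = TRUE, stringsAsFactors = FALSE)
  model <- fake_model(tr)
  set.seed(42)
  # region r01 carries mean -0.05 with SD 0.05 at n = 40: |t| = sqrt(40)
  n <- 40
  base <- as.numeric(scale(rnorm(n)))
  dev_list <- lapply(seq_len(20), function(j) {
    x <- if (j == 1) base * 0.05 - 0.05 else base * 0.05
    data.frame(subject_id = sprintf("s%02d", 1:n), age = 25, group = "patient",
               category = factor("20-30", levels = c("20-30", "30-35")),
               extrapolated = FALSE, region = sprintf("r%02d", j),
               observed = NA_real_, predicted = NA_real_, deviation = x,
               stringsAsFactors = FALSE)
  })
  dev <- do.call(rbind, dev_list)
  res <- test_deviations(dev, model, fdr_q = 0.01)
  r1 <- res[res$region == "r01", ]
  expect_equal(r1$t, -sqrt(40), tolerance = 1e-10)
  expect_lt(r1$q, 0.01)
  expect_true(r1$significant)
  # decreasing trajectory + negative deviation = accelerated-consistent
  expect_equal(r1$direction, -1L)
  expect_true(r1$accelerated_consistent)
  # BH q-values never fall below p
  expect_true(all(res$q >= res$p - 1e-15))
  # zero-deviation regions are flagged non-significant with undefined t
  dev0 <- dev; dev0$deviation <- 0
  res0 <- test_deviations(dev0, model)
  expect_true(all(!res0$significant))
  expect_true(all(is.na(res0$t)))
})

test_that("sign-flip permutation p agrees with the parametric p in scale", {
  tr <- data.frame(region = sprintf("r%d", 1:5), a0 = 0.3, a1 = -0.002, a2 = 0,
                   adj_r2 = 0.5, retained = TRUE, stringsAsFactors = FALSE)
  model <- fake_model(tr)
  set.seed(43)
  dev <- do.call(rbind, lapply(1:5, function(j) {
    data.frame(subject_id = sprintf("s%02d", 1:30), age = 25, group = "patient",
               category = factor("20-30", levels = "20-30"), extrapolated = FALSE,
               region = sprintf("r%d", j), observed = NA, predicted = NA,
               deviation = rnorm(30, if (j == 1) -0.08 else 0, 0.05))
  }))
  res <- test_deviations(dev, model, n_perm = 499, seed = 7)
  expect_equal(res$p_perm[res$region == "r1"], 1 / 500, tolerance = 1e-12)
  expect_true(all(res$p_perm[res$region != "r1"] > 0.05))
})

test_that("the uniform direction rule reproduces the four enumerated cases", {
  # decreasing trajectory: negative deviations are accelerated-consistent
  expect_equal(accelerated_direction(-0.002, 0, 30, 35), -1L)
  # increasing trajectory: positive deviations
  expect_equal(accelerated_direction(0.002, 0, 30, 35), 1L)
  # convex, turning point 43.5: +1 for a category wholly before the peak
  expect_equal(accelerated_direction(0.0087, -1e-4, 20, 30), 1L)
  # convex, turning point below the category: -1
  expect_equal(accelerated_direction(0.0087, -1e-4, 45, 60), -1L)
  # concave mirror images
  expect_equal(accelerated_direction(-0.0087, 1e-4, 20, 30), -1L)
  expect_equal(accelerated_direction(-0.0087, 1e-4, 45, 60), 1L)
  # turning point inside the category: indeterminate
  tp37 <- c(a1 = 2 * 1e-4 * 37, a2 = -1e-4)
  expect_true(is.na(accelerated_direction(tp37["a1"], tp37["a2"], 35, 40)))
})

test_that("uniform and enumerated direction rules agree on random cases", {
  set.seed(44)
  breaks <- c(20, 30, 35, 40, 45, 60)
  n_checked <- 0L
  for (i in 1:1000) {
    a1 <- runif(1, -0.02, 0.02)
    a2 <- runif(1, -3e-4, 3e-4)
    ci <- sample(5, 1)
    lo <- breaks[ci]; hi <- breaks[ci + 1]
    expect_identical(accelerated_direction(a1, a2, lo, hi),
                     enumerated_direction_oracle(a1, a2, lo, hi))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})

test_that("deviation summaries count consistent regions correctly", {
  tests <- data.frame(region = c("r1", "r2", "r3"), category = "20-30",
                      n = 10, mean_deviation = c(-0.1, 0.1, 0), sd = 0.05,
                      t = c(-5, 5, 0), p = c(1e-4, 1e-4, 0.9),
                      q = c(1e-3, 1e-3, 0.9), p_perm = NA,
                      direction = c(-1L, -1L, -1L),
                      significant = c(TRUE, TRUE, FALSE),
                      accelerated_consistent = c(TRUE, FALSE, NA),
                      stringsAsFactors = FALSE)
  s <- summarize_deviations(tests)
  expect_equal(s$overall$n_significant_regions, 2L)
  expect_equal(s$overall$n_consistent_regions, 1L)
  expect_equal(s$overall$pct_consistent, 50)
  none <- summarize_deviations(tests[tests$significant == FALSE, ])
  expect_true(is.na(none$overall$pct_consistent))
})
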