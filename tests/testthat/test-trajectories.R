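# Polynomial trajectory fitting, model comparison, shape classification.

test_that("noise-free quadratics are recovered exactly", {
  age <- 20:80
  y <- 0.2 - 0.004 * age + 2e-5 * age^2
  fit <- fit_polynomial(age, y, degree = 2)
  expect_equal(unname(fit$coefficients), c(0.2, -0.004, 2e-5), tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(31)
  age <- runif(40, 20, 80)
  y <- 0.1 + 0.002 * age - 1e-5 * age^2 + rnorm(40, 0, 0.05)
  for (deg in 1:3) {
    fit <- fit_polynomial(age, y, degree = deg)
    expect_equal(unname(fit$coefficients), unname(polyfit_oracle(age, y, deg)),
                 tolerance = 1e-8)
  }
  expect_error(fit_polynomial(rep(30, 10), rnorm(10), 2), "rank|equal")
  expect_error(fit_polynomial(age[1:3], y[1:3], 3), "degree")
})

test_that("age-independent data yields negative adjusted R2 and exclusion", {
  set.seed(32)
  age <- runif(665, 20, 80)
  # across many null regions, roughly the Beta-law share has adj R2 < 0
  y <- matrix(rnorm(665 * 100, 0.2, 0.03), 665, 100,
              dimnames = list(NULL, sprintf("r%03d", 1:100)))
  model <- fit_normative_model(y, age)
  theory <- pbeta(2 / 664, 1, (665 - 3) / 2)
  expect_lt(abs(mean(!model$trajectories$retained) - theory),
            3 * sqrt(theory * (1 - theory) / 100))
  expect_identical(model$trajectories$retained, model$trajectories$adj_r2 >= 0)
  expect_true(all(is.na(model$trajectories$category[!model$trajectories$retained])))
})

test_that("degree comparison selects the generating polynomial degree", {
  set.seed(33)
  age <- runif(200, 20, 80)
  # noise-free quadratic: quadratic beats linear decisively, selected degree 2
  y0 <- matrix(0.3 - 0.005 * age + 4e-5 * age^2, ncol = 1)
  cd0 <- compare_degrees(y0, age)
  expect_equal(cd0$per_region$selected, 2L)
  expect_lt(cd0$per_region$p21, 1e-10)
  # noisy quadratics: degree 2 selected in >= 95% of regions
  quad <- sapply(1:60, function(j) 0.3 - 0.005 * age + 4e-5 * age^2 +
                   rnorm(200, 0, 0.01))
  cd <- compare_degrees(quad, age)
  expect_gte(mean(cd$per_region$selected == 2L), 0.95)
  expect_equal(cd$summary$cohort_degree, 2L)
  # purely linear data: the quadratic term is significant at about alpha
  lin <- sapply(1:60, function(j) 0.3 - 0.002 * age + rnorm(200, 0, 0.01))
  cdl <- compare_degrees(lin, age)
  expect_lte(mean(cdl$per_region$p21 < 0.05), 0.10 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("shape classification follows slope signs at the reference ages", {
  expect_equal(classify_trajectory(0.001, 0), "increasing")
  expect_equal(classify_trajectory(-0.001, 0), "decreasing")
  expect_equal(classify_trajectory(0.0087, -1e-4), "convex")
  expect_equal(classify_trajectory(-0.0087, 1e-4), "concave")
  # slope arithmetic behind the convex example
  expect_equal(trajectory_slope(0.0087, -1e-4, 27), 0.0033)
  expect_equal(trajectory_slope(0.0087, -1e-4, 60), -0.0033)
  expect_equal(turning_point(0.0087, -1e-4), 43.5)
  # zero slope at a reference age counts as the positive side
  a2 <- 1e-5
  expect_equal(classify_trajectory(-2 * a2 * 27, a2), "increasing")
})

test_that("turning point matches a grid-search extremum oracle", {
  set.seed(34)
  for (i in 1:20) {
    a1 <- runif(1, -0.01, 0.01); a2 <- runif(1, -2e-4, 2e-4)
    if (abs(a2) < 1e-8) next
    grid <- seq(-200, 300, by = 0.001)
    vals <- a1 * grid + a2 * grid^2
    opt <- grid[if (a2 < 0) which.max(vals) else which.min(vals)]
    expect_equal(turning_point(a1, a2), opt, tolerance = 1e-2)
  }
  expect_true(is.na(turning_point(0.001, 0)))
})

test_that("trajectory prediction is plain polynomial evaluation", {
  expect_equal(predict_trajectory(0.25, 0.001, -1e-5, 0), 0.25)
  set.seed(35)
  a <- rnorm(3, 0, 0.01); ages <- runif(20, 0, 100)
  horner <- a[1] + ages * (a[2] + ages * a[3])
  expect_equal(predict_trajectory(a[1], a[2], a[3], ages), horner,
               tolerance = 1e-14)
})

test_that("the normative model partitions retained regions over four shapes", {
  w <- make_small_world(seed = 36)
  tr <- w$model$trajectories
  expect_equal(sum(table(tr$category)), sum(tr$retained))
  expect_setequal(unique(na.omit(tr$category)),
                  c("increasing", "decreasing", "convex", "concave"))
  # classification matches ground truth for regions above the slope floor
  m <- merge(w$trajectories, tr, by = "region", suffixes = c(".t", ".f"))
  shaped <- m$shape != "noise"
  expect_gt(mean(m$category[shaped] == m$shape[shaped], na.rm = TRUE), 0.95)
})

test_that("normative prediction evaluates the stored quadratics", {
  w <- make_small_world(seed = 37)
  tr <- w$model$trajectories
  reg <- tr$region[tr$retained][1:3]
  pred <- predict_normative(w$model, c(30, 50), regions = reg)
  i <- match(reg, tr$region)
  expect_equal(pred[1, ], setNames(tr$a0[i] + tr$a1[i] * 30 + tr$a2[i] * 900, reg),
               tolerance = 1e-12)
  expect_error(predict_normative(w$model, 40, regions = "nope"), "unknown")
})
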