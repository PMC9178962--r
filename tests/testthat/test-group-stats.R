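# Case-control maps, effect sizes, hub relationship, PAL model.

test_that("Cohen's d follows the pooled-SD definition", {
  set.seed(51)
  expect_error(cohens_d(rnorm(20), numeric(0)), "non-empty")
  x <- rnorm(30)
  expect_equal(cohens_d(x, x), 0)
  # means 1 and 0, both SD exactly 1, equal n: d = 1
  a <- as.numeric(scale(rnorm(25))) + 1
  b <- as.numeric(scale(rnorm(25)))
  expect_equal(cohens_d(a, b), 1, tolerance = 1e-12)
  # large-n recovery of the population d
  big_a <- rnorm(20000, 1, 1); big_b <- rnorm(20000, 0, 1)
  expect_lt(abs(cohens_d(big_a, big_b) - 1), 3 * sqrt(2 / 20000 + 1 / 40000))
  expect_warning(cohens_d(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("case-control t map matches the pooled-variance oracle", {
  # 4-subject toy table, hand-computed pooled t
  ms <- matrix(c(1.0, 1.2, 0.4, 0.6,
                 0.5, 0.7, 0.5, 0.7), 4, 2,
               dimnames = list(sprintf("s%d", 1:4), c("rA", "rB")))
  g <- c("control", "control", "patient", "patient")
  res <- case_control_map(ms, g)
  sp <- sqrt(((2 - 1) * var(c(1.0, 1.2)) + (2 - 1) * var(c(0.4, 0.6))) / 2)
  t_hand <- (1.1 - 0.5) / (sp * sqrt(1 / 2 + 1 / 2))
  expect_equal(res$t[res$region == "rA"], t_hand, tolerance = 1e-12)
  expect_equal(res$t[res$region == "rB"], 0, tolerance = 1e-12)
  # identical groups: nothing significant
  ms_same <- rbind(ms[1:2, ], ms[1:2, ])
  res_same <- case_control_map(ms_same, g)
  expect_true(all(res_same$t == 0))
  expect_true(all(!res_same$significant))
  expect_error(case_control_map(ms, c("a", "a", "a", "b")), "2 subjects")
})

test_that("swapping group labels negates t and preserves q", {
  set.seed(52)
  ms <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, sprintf("r%d", 1:8)))
  g <- rep(c("control", "patient"), each = 20)
  g_swapped <- ifelse(g == "control", "patient", "control")
  r1 <- case_control_map(ms, g)
  r2 <- case_control_map(ms, g_swapped)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_equal(r1$q, r2$q, tolerance = 1e-12)
})

test_that("a one-SD regional shift is detected at the study sizes", {
  set.seed(53)
  n1 <- 148; n2 <- 183
  ms <- matrix(rnorm((n1 + n2) * 30, 0.2, 0.03), n1 + n2, 30,
               dimnames = list(NULL, sprintf("r%d", 1:30)))
  g <- rep(c("control", "patient"), c(n1, n2))
  ms[g == "patient", 7] <- ms[g == "patient", 7] - 0.03 # one pooled SD
  res <- case_control_map(ms, g, n_perm = 199, seed = 5)
  expect_true(res$significant[7])
  expect_equal(res$p_perm[7], 1 / 200)
  expect_lt(sum(res$significant[-7]), 3)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(54)
  ps <- replicate(150, {
    ms <- matrix(rnorm(24), 24, 1)
    g <- rep(c("control", "patient"), each = 12)
    case_control_map(ms, g, n_perm = 99, seed = sample.int(1e6, 1))$p_perm
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("hub relationship recovers proportional maps", {
  set.seed(55)
  hub <- setNames(runif(20, -0.1, 0.3), sprintf("r%d", 1:20))
  expect_equal(hub_relationship(3 * hub + 1, hub, n_perm = 99)$r, 1)
  out <- hub_relationship(setNames(rnorm(20), names(hub)), hub, n_perm = 199)
  expect_gte(out$p_perm, 1 / 200)
})

test_that("the PAL linear model recovers additive effects and flat interactions", {
  demo <- data.frame(subject_id = sprintf("s%d", 1:8),
                     age = c(25, 35, 45, 55, 25, 35, 45, 55),
                     group = rep(c("control", "patient"), each = 4),
                     stringsAsFactors = FALSE)
  beh <- data.frame(subject_id = demo$subject_id,
                    total_errors = 5 + 0.5 * demo$age +
                      10 * (demo$group == "patient"),
                    stringsAsFactors = FALSE)
  fit <- suppressWarnings(pal_model(beh, demo)) # perfect fit warns in summary
  # pure additive generation: the interaction explains none of the variance
  expect_lt(fit$interaction$ss_fraction, 1e-10)
  expect_gt(fit$effects$F[fit$effects$term == "group"], 1e6)
  # coefficients against the normal-equations oracle on a noisy toy table
  set.seed(56)
  beh$total_errors <- beh$total_errors + round(rnorm(8, 0, 2))
  fit2 <- pal_model(beh, demo)
  X <- cbind(1, as.numeric(demo$group == "patient"), demo$age)
  cf <- drop(solve(t(X) %*% X, t(X) %*% beh$total_errors))
  expect_equal(unname(coef(fit2$model)), cf, tolerance = 1e-10)
})

test_that("Storey q-values reduce to scaled BH and stay in range", {
  set.seed(57)
  p <- c(runif(80), rbeta(20, 0.2, 5))
  q <- storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  expect_equal(q, pmin(1, pi0 * p.adjust(p, "BH")), tolerance = 1e-12)
})
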