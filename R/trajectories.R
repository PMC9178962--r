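# Normative age trajectories of regional mean MS.
#
# Per-region ordinary least squares polynomial fits of regional mean MS on
# age in a healthy reference cohort, screened by adjusted R-squared, with a
# four-way shape classification from the trajectory slope (first derivative
# of the quadratic) at an early and a late reference age.

#' Fit a polynomial age trajectory for one region
#'
#' Ordinary least squares fit of `y` on age of the requested degree. Age is
#' centred internally for conditioning; coefficients are reported on the
#' raw-age scale (`a0 + a1 t + a2 t^2 + ...`). Adjusted R-squared uses
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)` with p = degree.
#'
#' @param age,y numeric vectors of equal length.
#' @param degree polynomial degree, 1 to 3.
#' @return list with `coefficients` (named `a0`..), `se` (same names),
#'   `adj_r2`, `r2`, `sigma`, `n`, `degree`, `rss`.
#' @export
fit_polynomial <- function(age, y, degree = 2L) {
  stopifnot(degree %in% 1:3, length(age) == length(y))
  n <- length(age)
  if (n <= degree + 1L) stop_msa("need n > degree + 1 (n = %d, degree = %d)", n, degree)
  if (stats::sd(age) == 0) stop_msa("ages are all equal; design is rank deficient")
  fit <- fit_trajectories(matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                          age, degree = degree)
  cf <- unlist(fit[1, paste0("a", 0:degree)])
  se <- unlist(fit[1, paste0("se_a", 0:degree)])
  list(coefficients = cf, se = se, adj_r2 = fit$adj_r2[1], r2 = fit$r2[1],
       sigma = fit$sigma[1], n = n, degree = degree, rss = fit$rss[1])
}

# Vectorized OLS polynomial fits for every column of a subjects x regions
# matrix against age. Centred-age design; coefficients mapped back to the
# raw-age scale together with their standard errors.
fit_trajectories <- function(ms, age, degree = 2L) {
  ms <- as.matrix(ms)
  n <- nrow(ms)
  if (length(age) != n) stop_msa("age length (%d) != number of subjects (%d)", length(age), n)
  mu <- mean(age)
  ac <- age - mu
  X <- stats::poly(ac, degree = degree, raw = TRUE)
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_msa("rank-deficient design (degree %d)", degree)
  C <- qr.coef(qrX, ms)                       # (degree+1) x regions, centred scale
  fitted <- X %*% C
  res <- ms - fitted
  rss <- colSums(res^2)
  tss <- colSums(sweep(ms, 2L, colMeans(ms))^2)
  r2 <- 1 - rss / tss
  p <- degree
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sigma2 <- rss / (n - p - 1)
  XtXinv <- chol2inv(qr.R(qrX))
  # map centred-age coefficients b(c) to raw-age coefficients: y = sum b_k (t - mu)^k
  Tm <- raw_from_centred(degree, mu)          # (degree+1) x (degree+1)
  B <- Tm %*% C
  cov_raw <- Tm %*% XtXinv %*% t(Tm)
  SE <- sqrt(outer(diag(cov_raw), sigma2))
  out <- data.frame(region = colnames(ms) %||% sprintf("y%d", seq_len(ncol(ms))),
                    stringsAsFactors = FALSE)
  for (k in 0:degree) out[[paste0("a", k)]] <- B[k + 1L, ]
  for (k in 0:degree) out[[paste0("se_a", k)]] <- SE[k + 1L, ]
  out$r2 <- r2
  out$adj_r2 <- adj_r2
  out$sigma <- sqrt(sigma2)
  out$rss <- rss
  out$n <- n
  rownames(out) <- NULL
  out
}

# Matrix mapping coefficients of sum b_k (t - mu)^k to coefficients of
# sum a_k t^k (binomial expansion).
raw_from_centred <- function(degree, mu) {
  Tm <- matrix(0, degree + 1L, degree + 1L)
  for (k in 0:degree) {
    for (j in 0:k) {
      Tm[j + 1L, k + 1L] <- choose(k, j) * (-mu)^(k - j)
    }
  }
  Tm
}

#' Nested polynomial model comparison across regions
#'
#' For each region, nested-model F-tests compare degree 2 vs 1 and degree 3
#' vs 2; cohort-level summary reports the share of regions where the
#' quadratic beats the linear fit at `alpha` and where the cubic beats the
#' quadratic. Degree 2 is selected for a region when the quadratic term is
#' significant and the cubic term is not; degree 1 when neither is; degree 3
#' when the cubic term is.
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @param age numeric vector of ages.
#' @param alpha significance level for the F-tests (default 0.05).
#' @return list with `per_region` data frame (`F21, p21, F32, p32,
#'   selected`) and `summary` (shares and the cohort-level selected degree).
#' @export
compare_degrees <- function(ms, age, alpha = 0.05) {
  fits <- lapply(1:3, function(d) fit_trajectories(ms, age, degree = d))
  n <- nrow(as.matrix(ms))
  f_nested <- function(rss_small, rss_big, df_extra, df_resid) {
    Fv <- pmax(0, (rss_small - rss_big) / df_extra) / (rss_big / df_resid)
    list(F = Fv, p = stats::pf(Fv, df_extra, df_resid, lower.tail = FALSE))
  }
  t21 <- f_nested(fits[[1]]$rss, fits[[2]]$rss, 1, n - 3)
  t32 <- f_nested(fits[[2]]$rss, fits[[3]]$rss, 1, n - 4)
  sel <- ifelse(t32$p < alpha, 3L, ifelse(t21$p < alpha, 2L, 1L))
  per_region <- data.frame(region = fits[[1]]$region,
                           F21 = t21$F, p21 = t21$p, F32 = t32$F, p32 = t32$p,
                           selected = sel, stringsAsFactors = FALSE)
  share21 <- mean(t21$p < alpha)
  share32 <- mean(t32$p < alpha)
  list(per_region = per_region,
       summary = list(alpha = alpha,
                      share_quadratic_beats_linear = share21,
                      share_cubic_beats_quadratic = share32,
                      cohort_degree = if (share21 > share32) 2L else 3L))
}

#' Slope of a quadratic trajectory at an age
#'
#' @param a1,a2 linear and quadratic coefficients (vectorized).
#' @param age age in years.
#' @return `a1 + 2 a2 age`.
#' @export
trajectory_slope <- function(a1, a2, age) a1 + 2 * a2 * age

#' Classify trajectory shape from slope signs at two reference ages
#'
#' Categories follow the sign pair (slope at the early age, slope at the
#' late age): (+,+) increasing, (-,-) decreasing, (+,-) convex (single
#' peak), (-,+) concave (single trough). A slope of exactly zero counts as
#' the positive side (measure-zero tie-break, documented).
#'
#' @param a1,a2 quadratic coefficients (vectorized).
#' @param early,late reference ages in years (defaults 27 and 60).
#' @return character vector of categories.
#' @export
classify_trajectory <- function(a1, a2, early = 27, late = 60) {
  se <- trajectory_slope(a1, a2, early) >= 0
  sl <- trajectory_slope(a1, a2, late) >= 0
  ifelse(se & sl, "increasing",
         ifelse(!se & !sl, "decreasing",
                ifelse(se & !sl, "convex", "concave")))
}

#' Turning point of a quadratic trajectory
#'
#' @param a1,a2 quadratic coefficients (vectorized).
#' @return `-a1 / (2 a2)`, or `NA` when `a2 = 0`.
#' @export
turning_point <- function(a1, a2) ifelse(a2 == 0, NA_real_, -a1 / (2 * a2))

#' Predict regional mean MS from a trajectory
#'
#' @param a0,a1,a2 quadratic coefficients.
#' @param age age(s) in years.
#' @return `a0 + a1 age + a2 age^2`.
#' @export
predict_trajectory <- function(a0, a1, a2, age) a0 + a1 * age + a2 * age^2

#' Fit the normative model: per-region quadratic trajectories with screening
#'
#' Fits a quadratic trajectory of regional mean MS on age for every region
#' of a normative cohort, excludes regions with negative adjusted R-squared
#' (the fit explains no variance), and classifies retained regions by slope
#' sign at the two reference ages.
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @param age numeric vector of ages (same subjects).
#' @param early,late reference ages for shape classification.
#' @return object of class `normative_model`: list with `trajectories`
#'   (data frame: region, a0..a2, se_a0..se_a2, adj_r2, retained, category,
#'   turning_point), `reference_ages`, `age_range`, `n_subjects`,
#'   `n_excluded`.
#' @export
fit_normative_model <- function(ms, age, early = 27, late = 60) {
  fits <- fit_trajectories(ms, age, degree = 2L)
  fits$retained <- fits$adj_r2 >= 0
  fits$category <- ifelse(fits$retained,
                          classify_trajectory(fits$a1, fits$a2, early, late),
                          NA_character_)
  fits$turning_point <- ifelse(fits$retained, turning_point(fits$a1, fits$a2),
                               NA_real_)
  structure(list(trajectories = fits,
                 reference_ages = c(early = early, late = late),
                 age_range = range(age),
                 n_subjects = nrow(as.matrix(ms)),
                 n_excluded = sum(!fits$retained)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative MS trajectory model: %d regions (%d retained, %d excluded by adj R^2 < 0)\n",
              nrow(x$trajectories), sum(x$trajectories$retained), x$n_excluded))
  cat(sprintf("  fitted on %d subjects, ages %.1f-%.1f; reference ages %g/%g\n",
              x$n_subjects, x$age_range[1], x$age_range[2],
              x$reference_ages["early"], x$reference_ages["late"]))
  print(table(x$trajectories$category, useNA = "ifany"))
  invisible(x)
}

#' Predicted regional mean MS for subjects under a normative model
#'
#' @param model a `normative_model`.
#' @param ages numeric vector of ages.
#' @param regions regions to predict (default: retained regions).
#' @return matrix, length(ages) x regions.
#' @export
predict_normative <- function(model, ages, regions = NULL) {
  tr <- model$trajectories
  if (is.null(regions)) regions <- tr$region[tr$retained]
  miss <- setdiff(regions, tr$region)
  if (length(miss)) stop_msa("unknown regions: %s", paste(utils::head(miss, 5), collapse = ", "))
  tr <- tr[match(regions, tr$region), ]
  X <- cbind(1, ages, ages^2)
  out <- X %*% t(as.matrix(tr[, c("a0", "a1", "a2")]))
  colnames(out) <- regions
  out
}
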