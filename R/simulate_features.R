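# Feature-level synthetic generator.
#
# Rather than emitting regional mean MS directly, this mode emits raw
# 7-feature regional tables whose derived MS networks track the target
# trajectories. Construction: each region has a fixed unit-norm 7-feature
# template; a subject's regional profile mixes a shared per-subject factor
# (loading lambda) with template-plus-noise, and raw features are per-feature
# affine transforms of the profile onto plausible scales. Because the MS
# computation z-scores features across regions within subject, the map from
# lambda to realized regional mean MS is monotone but has no useful closed
# form; it is estimated numerically once and cached.

FEATURE_NAMES <- c("gm_volume", "surface_area", "thickness", "mean_curvature",
                   "gaussian_curvature", "folding_index", "intrinsic_curvature")

# Per-feature affine scales (location, scale). Locations are large relative
# to scales for the strictly-positive features so positivity holds for any
# plausible profile draw; a hard floor guards the tail.
FEATURE_SCALES <- data.frame(
  feature = FEATURE_NAMES,
  location = c(4200, 320, 2.5, 0.125, 0.02, 15, 0.55),
  scale = c(450, 34, 0.24, 0.012, 0.15, 1.5, 0.05),
  positive = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

.calibration_cache <- new.env(parent = emptyenv())

# Estimate the monotone map lambda -> expected realized regional mean MS by
# simulating a small cohort over a lambda grid and isotonic smoothing.
similarity_calibration <- function(template_weight = 0.3, profile_noise = 0.5,
                                   n_subjects = 150L, n_regions = 120L,
                                   seed = 20201L) {
  key <- sprintf("tw%.3f_pn%.3f_n%d_m%d_s%d", template_weight, profile_noise,
                 n_subjects, n_regions, seed)
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  lam <- seq(0.03, 0.95, length.out = n_regions)
  realized <- withr_seed(seed, {
    acc <- matrix(0, n_subjects, n_regions)
    tmpl <- matrix(stats::rnorm(n_regions * 7), n_regions, 7)
    tmpl <- tmpl / sqrt(rowSums(tmpl^2))
    for (s in seq_len(n_subjects)) {
      g <- stats::rnorm(7)
      g <- (g - mean(g)) / stats::sd(g)  # fixed sample moments: stable subject gain
      eta <- matrix(stats::rnorm(n_regions * 7), n_regions, 7)
      e <- template_weight * tmpl + sqrt(1 - template_weight^2) * eta
      z <- lam %o% g + profile_noise * sqrt(1 - lam^2) * e
      acc[s, ] <- regional_mean_ms(compute_ms_matrix(zscore_features(z)))
    }
    colMeans(acc)
  })
  iso <- stats::isoreg(lam, realized)
  fit <- unique(data.frame(lambda = iso$x, ms = iso$yf))
  # strictly increasing grid for inversion
  fit$ms <- cummax(fit$ms + seq_len(nrow(fit)) * 1e-9)
  map <- list(
    ms_range = range(fit$ms),
    lambda_of_ms = stats::approxfun(fit$ms, fit$lambda, rule = 2),
    ms_of_lambda = stats::approxfun(fit$lambda, fit$ms, rule = 2)
  )
  .calibration_cache[[key]] <- map
  map
}

#' Generate a raw 7-feature regional table tracking target trajectories
#'
#' Emits one row per subject x region with the seven morphometric features
#' (grey-matter volume, surface area, cortical thickness, mean curvature,
#' Gaussian curvature, folding index, intrinsic curvature index) on
#' plausible raw scales. The regional mean MS computed from the table by
#' [cohort_regional_ms()] tracks each region's target trajectory up to one
#' global increasing affine map (which preserves per-region trajectory
#' shapes and slope signs) plus sampling noise from the 7-point
#' correlations.
#'
#' @inheritParams generate_regional_ms
#' @param parcellation_seed seed for the fixed per-region templates.
#' @param template_weight weight of the region template in the residual
#'   profile (region identity across subjects).
#' @param profile_noise scale of the independent profile noise relative to
#'   the shared factor (default 0.5: keeps MS matrices far from degeneracy
#'   while the regional mean MS retains a resolvable age signal).
#' @return data frame `subject_id, region` plus the 7 feature columns, with
#'   attribute `"target_affine"` recording the global map applied to the
#'   targets.
#' @export
generate_feature_table <- function(demographics, trajectories, injection = NULL,
                                   seed = 1L, parcellation_seed = 99L,
                                   template_weight = 0.3, profile_noise = 0.5) {
  R <- nrow(trajectories)
  if (R < 2L) stop_msa("need at least 2 regions (correlations undefined)")
  n <- nrow(demographics)
  ages <- effective_ages(demographics, trajectories, injection)
  # targets per subject x region from ground-truth quadratics
  A0 <- matrix(trajectories$a0, n, R, byrow = TRUE)
  A1 <- matrix(trajectories$a1, n, R, byrow = TRUE)
  A2 <- matrix(trajectories$a2, n, R, byrow = TRUE)
  target <- A0 + A1 * ages + A2 * ages^2

  cal <- similarity_calibration(template_weight = template_weight,
                                profile_noise = profile_noise)
  # Map targets linearly onto (nearly) the full factor-loading range. The
  # realized regional mean MS is then a smooth monotone function of the
  # target (approximately affine over the band, per the cached numerical
  # calibration), which preserves per-region trajectory shapes and slope
  # signs while using the generator's full dynamic range.
  lam_band <- c(0.05, 0.95)
  tr <- range(target)
  slope <- diff(lam_band) / max(diff(tr), 1e-12)
  affine <- c(intercept = lam_band[1] - slope * tr[1], slope = slope)
  lambda <- affine[1] + affine[2] * target
  lambda <- pmin(pmax(lambda, 0.01), 0.97)

  templates <- withr_seed(parcellation_seed, {
    tm <- matrix(stats::rnorm(R * 7), R, 7)
    tm / sqrt(rowSums(tm^2))
  })

  out <- withr_seed(seed, {
    rows <- vector("list", n)
    for (s in seq_len(n)) {
      g <- stats::rnorm(7)
      g <- (g - mean(g)) / stats::sd(g)  # fixed sample moments: stable subject gain
      eta <- matrix(stats::rnorm(R * 7), R, 7)
      e <- template_weight * templates + sqrt(1 - template_weight^2) * eta
      lam <- lambda[s, ]
      z <- lam %o% g + profile_noise * sqrt(1 - lam^2) * e
      x <- sweep(sweep(z, 2L, FEATURE_SCALES$scale, "*"), 2L,
                 FEATURE_SCALES$location, "+")
      pos <- FEATURE_SCALES$positive
      x[, pos] <- pmax(x[, pos], rep(FEATURE_SCALES$location[pos] / 50,
                                     each = R))
      colnames(x) <- FEATURE_NAMES
      rows[[s]] <- data.frame(subject_id = demographics$subject_id[s],
                              region = trajectories$region, x,
                              stringsAsFactors = FALSE, row.names = NULL)
    }
    do.call(rbind, rows)
  })
  attr(out, "target_affine") <- affine
  out
}
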