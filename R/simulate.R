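# Synthetic cohort generator.
#
# Generates normative and case-control cohorts with known ground-truth
# quadratic age trajectories of regional mean MS, optional "aged" patient
# injections (trajectory evaluated at age + delta years), and paired
# associates learning (PAL) scores with main effects of age and group.
# Every downstream stage of the pipeline is testable against this ground
# truth without MRI data.

#' Cohort specification
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range numeric length-2, lower < upper, in years.
#' @param sex_ratio fraction female in \[0, 1\].
#' @param group group label: `"normative"`, `"control"` or `"patient"`.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, age_range, sex_ratio = 0.5,
                        group = c("normative", "control", "patient"),
                        seed = 1L) {
  group <- match.arg(group)
  if (!is.numeric(n_subjects) || n_subjects < 2) stop_msa("n_subjects must be >= 2")
  if (length(age_range) != 2L || age_range[1] >= age_range[2])
    stop_msa("age_range must be [lo, hi] with lo < hi")
  if (sex_ratio < 0 || sex_ratio > 1) stop_msa("sex_ratio must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 sex_ratio = sex_ratio, group = group, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a demographics table from a cohort specification
#'
#' Ages are drawn uniformly on the age range (the density is configurable
#' through `age_sampler`); sex is Bernoulli with the requested female
#' fraction. Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param age_sampler optional function `n -> ages` overriding the uniform
#'   default.
#' @return data frame with columns `subject_id`, `age`, `sex`, `group`.
#' @export
sample_cohort <- function(spec, age_sampler = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_subjects
    ages <- if (is.null(age_sampler))
      stats::runif(n, spec$age_range[1], spec$age_range[2]) else age_sampler(n)
    data.frame(
      subject_id = sprintf("%s_%04d", substr(spec$group, 1, 4), seq_len(n)),
      age = ages,
      sex = ifelse(stats::runif(n) < spec$sex_ratio, "F", "M"),
      group = spec$group,
      stringsAsFactors = FALSE
    )
  })
}

# Detectability floor (MS units per year): the minimum |trajectory slope| at
# the reference ages that the default study sizes can reliably resolve.
# Default trajectories are drawn at or above this floor.
MS_SLOPE_FLOOR <- 0.0018

#' Default ground-truth trajectory set
#'
#' One quadratic age trajectory of regional mean MS per region. 312 regions
#' carry shaped trajectories with slope magnitudes at the reference ages
#' drawn from `slope_range`, split over the four shape classes in the
#' proportions reported for healthy ageing (increasing/decreasing/
#' convex/concave about 105/103/49/55); the remaining regions are flat pure
#' noise, exercising the adjusted-R-squared exclusion rule. Baselines are
#' coupled to shape so that high-MS regions decline and low-MS regions rise
#' with age (trajectories tend towards zero), which also makes case-control
#' difference maps correlate with the hub map as observed empirically.
#'
#' @param regions character vector of region labels.
#' @param seed RNG seed for the draw.
#' @param class_counts named integer vector over
#'   `increasing/decreasing/convex/concave`; remaining regions become noise.
#'   `NULL` (default) scales the reported proportions to the region count.
#' @param slope_range magnitude range (MS/year) for slopes at the reference
#'   ages; the lower end is the documented detectability floor.
#' @param noise_sd residual between-subject SD in MS units.
#' @param early,late reference ages (years) at which slope signs define the
#'   shape classes.
#' @return data frame `region, a0, a1, a2, noise_sd, shape` of class
#'   `trajectory_table`; MS value at age t is `a0 + a1 t + a2 t^2`.
#' @export
default_trajectories <- function(regions = default_parcellation(),
                                 seed = 42L,
                                 class_counts = NULL,
                                 slope_range = c(MS_SLOPE_FLOOR, 0.0045),
                                 noise_sd = 0.03,
                                 early = 27, late = 60) {
  n <- length(regions)
  if (is.null(class_counts)) {
    prop <- c(increasing = 105, decreasing = 103, convex = 49, concave = 55) / 360
    class_counts <- floor(prop * n)
  }
  n_shaped <- sum(class_counts)
  if (n_shaped > n) stop_msa("class_counts exceed number of regions")
  shapes <- c(rep(names(class_counts), class_counts), rep("noise", n - n_shaped))
  withr_seed(seed, {
    shapes <- sample(shapes)
    s_early <- stats::runif(n, slope_range[1], slope_range[2])
    s_late <- stats::runif(n, slope_range[1], slope_range[2])
    sign_early <- ifelse(shapes %in% c("increasing", "convex"), 1, -1)
    sign_late <- ifelse(shapes %in% c("increasing", "concave"), 1, -1)
    s_early <- s_early * sign_early
    s_late <- s_late * sign_late
    # slope(t) = a1 + 2 a2 t; solve from slopes at the two reference ages
    a2 <- (s_late - s_early) / (2 * (late - early))
    a1 <- s_early - 2 * a2 * early
    base20 <- ifelse(shapes == "increasing", stats::runif(n, -0.25, -0.05),
              ifelse(shapes == "decreasing", stats::runif(n, 0.20, 0.45),
              ifelse(shapes == "convex", stats::runif(n, -0.10, 0.05),
              ifelse(shapes == "concave", stats::runif(n, 0.10, 0.30),
                     stats::runif(n, -0.10, 0.30)))))
    a1[shapes == "noise"] <- 0
    a2[shapes == "noise"] <- 0
    a0 <- base20 - a1 * 20 - a2 * 400
    structure(data.frame(region = regions, a0 = a0, a1 = a1, a2 = a2,
                         noise_sd = noise_sd, shape = shapes,
                         stringsAsFactors = FALSE),
              class = c("trajectory_table", "data.frame"),
              slope_floor = slope_range[1], reference_ages = c(early, late))
  })
}

#' Evaluate ground-truth trajectories at given ages
#'
#' @param trajectories a trajectory table (`region, a0, a1, a2, ...`).
#' @param ages numeric vector of ages.
#' @return matrix, length(ages) x regions.
#' @export
evaluate_trajectories <- function(trajectories, ages) {
  X <- cbind(1, ages, ages^2)
  B <- t(as.matrix(trajectories[, c("a0", "a1", "a2")]))
  out <- X %*% B
  colnames(out) <- trajectories$region
  out
}

#' Aged-injection specification
#'
#' Shifts the trajectory evaluation age of patient subjects by
#' `delta_years` in the affected regions, planting a known
#' accelerated-ageing (or decelerated, if negative) signal.
#'
#' @param delta_years shift in years applied to the evaluation age.
#' @param regions character vector of affected region labels, or the
#'   keywords `"decreasing"` (default: all regions whose ground-truth
#'   trajectory is decreasing) or `"all"`.
#' @return object of class `aged_injection`.
#' @export
aged_injection <- function(delta_years = 10, regions = "decreasing") {
  if (!is.finite(delta_years)) stop_msa("delta_years must be finite")
  structure(list(delta_years = delta_years, regions = regions),
            class = "aged_injection")
}

resolve_injection_regions <- function(injection, trajectories) {
  r <- injection$regions
  if (identical(r, "all")) return(trajectories$region)
  if (identical(r, "decreasing")) {
    if (!"shape" %in% names(trajectories))
      stop_msa("trajectory table has no shape column; name regions explicitly")
    return(trajectories$region[trajectories$shape == "decreasing"])
  }
  unknown <- setdiff(r, trajectories$region)
  if (length(unknown)) stop_msa("injection regions not in parcellation: %s",
                                paste(utils::head(unknown, 5), collapse = ", "))
  r
}

# Effective evaluation ages: subjects x regions. Patients get age + delta in
# affected regions.
effective_ages <- function(demographics, trajectories, injection) {
  ages <- matrix(demographics$age, nrow(demographics), nrow(trajectories),
                 dimnames = list(demographics$subject_id, trajectories$region))
  if (!is.null(injection)) {
    affected <- resolve_injection_regions(injection, trajectories)
    pat <- demographics$group == "patient"
    if (any(pat) && length(affected))
      ages[pat, affected] <- ages[pat, affected] + injection$delta_years
  }
  ages
}

#' Generate regional mean MS directly from ground-truth trajectories
#'
#' `value(s, r) = a0_r + a1_r age_eff + a2_r age_eff^2 + u_s + eps`, with
#' `eps ~ N(0, noise_sd_r^2)` and `u_s ~ N(0, subject_sd^2)` a subject-level
#' offset shared across regions (real MS data shows such global offsets).
#' Patient subjects are evaluated at `age + delta_years` in the injected
#' regions.
#'
#' @param demographics data frame from [sample_cohort()].
#' @param trajectories trajectory table covering every region.
#' @param injection optional [aged_injection()].
#' @param seed RNG seed.
#' @param subject_sd SD of the shared per-subject MS offset (MS units).
#' @return subjects x regions matrix of regional mean MS.
#' @export
generate_regional_ms <- function(demographics, trajectories, injection = NULL,
                                 seed = 1L, subject_sd = 0.02) {
  ages <- effective_ages(demographics, trajectories, injection)
  n <- nrow(demographics); R <- nrow(trajectories)
  A0 <- matrix(trajectories$a0, n, R, byrow = TRUE)
  A1 <- matrix(trajectories$a1, n, R, byrow = TRUE)
  A2 <- matrix(trajectories$a2, n, R, byrow = TRUE)
  mu <- A0 + A1 * ages + A2 * ages^2
  withr_seed(seed, {
    eps <- matrix(stats::rnorm(n * R), n, R) *
      matrix(trajectories$noise_sd, n, R, byrow = TRUE)
    u <- if (subject_sd > 0) stats::rnorm(n, 0, subject_sd) else numeric(n)
    out <- mu + eps + u
    dimnames(out) <- dimnames(ages)
    out
  })
}

#' PAL outcome specification
#'
#' Total errors are `beta_intercept + beta_age * age + group_effect + eps`,
#' truncated at zero and rounded (scores are counts); the first-trial memory
#' score is a decreasing function of total errors. The group effect may vary
#' by age category; the default step effects (16/11/12/16/7 errors for
#' 20-30/30-35/35-40/40-45/45-60) are calibrated so that, with `noise_sd =
#' 10`, the per-category control-vs-patient Cohen's d approximates the
#' reported targets 1.6/1.1/1.2/1.6/0.7.
#'
#' @param beta_intercept expected errors at age 0 (before truncation).
#' @param beta_age errors per year of age.
#' @param beta_group patient excess errors: scalar, or named vector keyed by
#'   age-category label.
#' @param noise_sd residual SD in error counts.
#' @param max_first_trial maximum attainable first-trial memory score.
#' @return object of class `pal_spec`.
#' @export
pal_spec <- function(beta_intercept = 12, beta_age = 0.45,
                     beta_group = c("20-30" = 16, "30-35" = 11, "35-40" = 12,
                                    "40-45" = 16, "45-60" = 7),
                     noise_sd = 10, max_first_trial = 25) {
  if (noise_sd < 0) stop_msa("noise_sd must be >= 0")
  structure(list(beta_intercept = beta_intercept, beta_age = beta_age,
                 beta_group = beta_group, noise_sd = noise_sd,
                 max_first_trial = max_first_trial),
            class = "pal_spec")
}

#' Generate PAL behavioural scores
#'
#' @param demographics data frame with `subject_id`, `age`, `group`.
#' @param spec a [pal_spec()].
#' @param seed RNG seed.
#' @param breaks age-category boundaries used when `beta_group` is
#'   per-category.
#' @return data frame `subject_id, total_errors, first_trial_memory`.
#' @export
generate_pal <- function(demographics, spec = pal_spec(), seed = 1L,
                         breaks = c(20, 30, 35, 40, 45, 60)) {
  stopifnot(inherits(spec, "pal_spec"))
  age <- demographics$age
  patient <- demographics$group == "patient"
  if (length(spec$beta_group) == 1L && is.null(names(spec$beta_group))) {
    ge <- rep(spec$beta_group, length(age))
  } else {
    cat_lab <- assign_age_category(pmin(pmax(age, breaks[1]), breaks[length(breaks)]),
                                   breaks = breaks, policy = "drop")
    ge <- unname(spec$beta_group[as.character(cat_lab)])
    ge[is.na(ge)] <- spec$beta_group[[1L]]
  }
  withr_seed(seed, {
    mu <- spec$beta_intercept + spec$beta_age * age + ifelse(patient, ge, 0)
    errors <- round(pmax(0, mu + stats::rnorm(length(age), 0, spec$noise_sd)))
    fts <- round(pmin(spec$max_first_trial,
                      pmax(0, spec$max_first_trial - 0.25 * errors +
                             stats::rnorm(length(age), 0, 1.5))))
    data.frame(subject_id = demographics$subject_id,
               total_errors = as.integer(errors),
               first_trial_memory = as.integer(fts),
               stringsAsFactors = FALSE)
  })
}
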