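# Deviations from normative ageing.
#
# A subject's deviation in a region is observed regional mean MS minus the
# value the normative trajectory predicts at the subject's age (the
# observed-minus-predicted convention makes the accelerated-ageing
# direction rules internally consistent: on a decreasing trajectory, an
# older-looking brain has lower MS than predicted, i.e. a negative
# deviation). Deviations are tested within age categories by one-sample
# t-tests with FDR correction and optional sign-flip permutation.

DEFAULT_AGE_BREAKS <- c(20, 30, 35, 40, 45, 60)

#' Assign ages to age categories
#'
#' Categories are half-open intervals `[lo, hi)` except the last, which is
#' closed `[lo, hi]` (the conventional resolution of overlapping interval
#' labels such as 20-30 / 30-35).
#'
#' @param age numeric vector of ages.
#' @param breaks increasing numeric vector of category boundaries.
#' @param policy what to do with uncovered ages: `"error"` (default) or
#'   `"drop"` (assign `NA` with a warning).
#' @return factor of category labels (`"20-30"`, ...).
#' @export
assign_age_category <- function(age, breaks = DEFAULT_AGE_BREAKS,
                                policy = c("error", "drop")) {
  policy <- match.arg(policy)
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  labels <- paste0(utils::head(breaks, -1), "-", breaks[-1])
  idx <- findInterval(age, breaks, rightmost.closed = TRUE)
  out_of_range <- idx < 1L | idx > length(labels)
  if (any(out_of_range)) {
    if (policy == "error")
      stop_msa("age(s) outside the category partition [%g, %g]: %s",
               breaks[1], breaks[length(breaks)],
               paste(utils::head(round(age[out_of_range], 1), 5), collapse = ", "))
    warning(sprintf("%d age(s) outside [%g, %g] assigned NA category",
                    sum(out_of_range), breaks[1], breaks[length(breaks)]))
    idx[out_of_range] <- NA_integer_
  }
  factor(labels[idx], levels = labels)
}

#' Compute per-subject deviations from the normative model
#'
#' Deviation = observed - predicted regional mean MS, for retained regions
#' only. Subjects whose age lies outside the normative fitting range are
#' flagged `extrapolated` (the quadratic is evaluated anyway) with a
#' warning.
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @param demographics data frame with `subject_id`, `age`, `group`
#'   matching the rows of `ms`.
#' @param model a [fit_normative_model()] result.
#' @param breaks age-category boundaries.
#' @param policy category policy for uncovered ages (see
#'   [assign_age_category()]); the pipeline uses `"drop"`.
#' @return long data frame `subject_id, age, group, category, extrapolated,
#'   region, observed, predicted, deviation` with attribute
#'   `"n_excluded_regions"`.
#' @export
compute_deviations <- function(ms, demographics, model,
                               breaks = DEFAULT_AGE_BREAKS,
                               policy = c("drop", "error")) {
  policy <- match.arg(policy)
  ms <- as.matrix(ms)
  stopifnot(nrow(ms) == nrow(demographics))
  retained <- model$trajectories$region[model$trajectories$retained]
  missing_regions <- setdiff(retained, colnames(ms))
  if (length(missing_regions))
    stop_msa("MS table lacks retained regions: %s",
             paste(utils::head(missing_regions, 5), collapse = ", "))
  obs <- ms[, retained, drop = FALSE]
  pred <- predict_normative(model, demographics$age, regions = retained)
  extrap <- demographics$age < model$age_range[1] | demographics$age > model$age_range[2]
  if (any(extrap))
    warning(sprintf("%d subject(s) outside the normative age range [%.1f, %.1f] flagged as extrapolated",
                    sum(extrap), model$age_range[1], model$age_range[2]))
  category <- assign_age_category(demographics$age, breaks = breaks, policy = policy)
  n_sub <- nrow(obs); n_reg <- length(retained)
  out <- data.frame(
    subject_id = rep(demographics$subject_id, times = n_reg),
    age = rep(demographics$age, times = n_reg),
    group = rep(demographics$group, times = n_reg),
    category = rep(category, times = n_reg),
    extrapolated = rep(extrap, times = n_reg),
    region = rep(retained, each = n_sub),
    observed = as.vector(obs),
    predicted = as.vector(pred),
    stringsAsFactors = FALSE
  )
  out$deviation <- out$observed - out$predicted
  attr(out, "n_excluded_regions") <- model$n_excluded
  attr(out, "sign_convention") <- "observed_minus_predicted"
  out
}

#' Direction of deviation consistent with accelerated ageing
#'
#' Uniform rule over a category `[lo, hi]`: if the trajectory slope is
#' positive throughout the category, positive deviations look "older"
#' (+1); if negative throughout, negative deviations do (-1); if the
#' turning point falls inside the category the direction is indeterminate
#' (`NA`). Because the slope of a quadratic is linear in age, evaluating
#' the slope sign at the category endpoints decides the whole interval.
#' This single rule reproduces the four enumerated shape-specific cases
#' (decreasing, increasing, convex and concave trajectories with the
#' turning point above or below the category).
#'
#' @param a1,a2 quadratic coefficients (vectorized).
#' @param lo,hi category bounds in years.
#' @return integer vector: +1, -1 or `NA` (indeterminate).
#' @export
accelerated_direction <- function(a1, a2, lo, hi) {
  s_lo <- trajectory_slope(a1, a2, lo) >= 0
  s_hi <- trajectory_slope(a1, a2, hi) >= 0
  ifelse(s_lo & s_hi, 1L, ifelse(!s_lo & !s_hi, -1L, NA_integer_))
}

#' Test deviations within age categories
#'
#' One-sample t-test of the mean deviation against zero for every retained
#' region within every age category, FDR-corrected across regions within
#' each category, with an optional sign-flip permutation p-value. Each
#' significant region x category cell is classified as consistent or
#' inconsistent with accelerated ageing by comparing the deviation sign
#' with [accelerated_direction()].
#'
#' @param deviations long data frame from [compute_deviations()].
#' @param model the normative model (for trajectory coefficients).
#' @param fdr_q FDR threshold (default 0.01).
#' @param fdr_method `"BH"` (default) or `"storey"`.
#' @param n_perm number of sign-flip permutations (0 = none).
#' @param seed RNG seed for permutations.
#' @param min_n minimum subjects per tested category (default 3).
#' @return data frame `region, category, n, mean_deviation, sd, t, p, q,
#'   p_perm, direction, significant, accelerated_consistent`.
#' @export
test_deviations <- function(deviations, model, fdr_q = 0.01,
                            fdr_method = c("BH", "storey"),
                            n_perm = 0L, seed = 1L, min_n = 3L) {
  fdr_method <- match.arg(fdr_method)
  dev <- deviations[!is.na(deviations$category), , drop = FALSE]
  tr <- model$trajectories
  cats <- levels(dev$category)
  bounds <- do.call(rbind, lapply(strsplit(cats, "-"), as.numeric))
  res <- vector("list", length(cats))
  for (ci in seq_along(cats)) {
    d <- dev[dev$category == cats[ci], , drop = FALSE]
    if (!nrow(d)) next
    wide <- stats::xtabs(deviation ~ subject_id + region, data = d)
    wide <- matrix(as.numeric(wide), nrow(wide), ncol(wide),
                   dimnames = dimnames(wide))
    if (nrow(wide) < min_n) next
    tt <- col_t_onesample(wide)
    zero_var <- tt$sd == 0
    p <- tt$p
    p[zero_var] <- 1 # undefined t: reported non-significant, flagged by NA t
    q <- adjust_fdr(p, fdr_method)
    p_perm <- rep(NA_real_, length(p))
    if (n_perm > 0L) {
      p_perm <- withr_seed(derive_seed(seed, ci), {
        nsub <- nrow(wide)
        obs_t <- abs(tt$t)
        exceed <- rep(0L, ncol(wide))
        for (b in seq_len(n_perm)) {
          flips <- sample(c(-1, 1), nsub, replace = TRUE)
          tb <- col_t_onesample(wide * flips)
          exceed <- exceed + (abs(tb$t) >= obs_t)
        }
        (1 + exceed) / (1 + n_perm)
      })
    }
    reg <- colnames(wide)
    ti <- match(reg, tr$region)
    dir <- accelerated_direction(tr$a1[ti], tr$a2[ti], bounds[ci, 1], bounds[ci, 2])
    sig <- !zero_var & q < fdr_q
    consistent <- ifelse(sig & !is.na(dir), sign(tt$mean) == dir, NA)
    res[[ci]] <- data.frame(region = reg,
                            category = factor(cats[ci], levels = cats), n = tt$n,
                            mean_deviation = tt$mean, sd = tt$sd,
                            t = ifelse(zero_var, NA_real_, tt$t), p = p, q = q,
                            p_perm = p_perm, direction = dir,
                            significant = sig,
                            accelerated_consistent = consistent,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "fdr") <- list(method = fdr_method, q = fdr_q, n_perm = n_perm)
  out
}

#' Summarize deviation tests across categories
#'
#' @param tests result of [test_deviations()].
#' @return list with `by_category` data frame and `overall` counts: number
#'   of distinct significant regions, number and percentage of those whose
#'   significant deviations are accelerated-consistent (a region counts as
#'   consistent if any of its significant category cells is), and the
#'   indeterminate regions.
#' @export
summarize_deviations <- function(tests) {
  sig <- tests[tests$significant, , drop = FALSE]
  by_cat <- do.call(rbind, lapply(split(tests, tests$category), function(d) {
    s <- d[d$significant, , drop = FALSE]
    data.frame(category = d$category[1],
               n_tested = nrow(d),
               n_significant = nrow(s),
               n_consistent = sum(s$accelerated_consistent, na.rm = TRUE),
               n_indeterminate = sum(is.na(s$direction)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_cat) <- NULL
  sig_regions <- unique(sig$region)
  consistent_regions <- unique(sig$region[which(sig$accelerated_consistent)])
  pct <- if (length(sig_regions)) 100 * length(consistent_regions) / length(sig_regions)
         else NA_real_
  list(by_category = by_cat,
       overall = list(
         n_significant_regions = length(sig_regions),
         n_consistent_regions = length(consistent_regions),
         pct_consistent = pct,
         indeterminate_regions = unique(sig$region[is.na(sig$direction)])
       ))
}
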