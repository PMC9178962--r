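# Case-control regional statistics, effect sizes, hub relationship, and the
# PAL behavioural model.

#' Cohen's d (pooled SD)
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled variance using the
#' `n_x + n_y - 2` denominator; no small-sample correction.
#'
#' @param x,y numeric vectors.
#' @return Cohen's d (NA with a warning when the pooled SD is zero).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop_msa("both groups must be non-empty")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    warning("pooled SD is zero or undefined; Cohen's d is NA")
    return(NA_real_)
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Regional case-control comparison map
#'
#' Per-region two-sided two-sample t-tests (pooled variance by default)
#' between control and patient subjects, FDR-corrected across regions, with
#' optional group-label permutation p-values and Cohen's d. The t sign is
#' control minus patient.
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @param group vector with levels `control` / `patient` (any two labels;
#'   the first factor level is taken as "control" side of the difference).
#' @param fdr_q FDR threshold.
#' @param fdr_method `"BH"` or `"storey"`.
#' @param n_perm label-shuffle permutations (0 = none).
#' @param seed RNG seed.
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data frame `region, mean_control, mean_patient, t, df, p, q,
#'   p_perm, d, significant`, with an `fdr` attribute recording choices.
#' @export
case_control_map <- function(ms, group, fdr_q = 0.01,
                             fdr_method = c("BH", "storey"),
                             n_perm = 0L, seed = 1L, var_equal = TRUE) {
  fdr_method <- match.arg(fdr_method)
  ms <- as.matrix(ms)
  tt <- col_t_twosample(ms, group, var_equal = var_equal)
  q <- adjust_fdr(tt$p, fdr_method)
  sp2 <- ((tt$n1 - 1) * tt$var1 + (tt$n2 - 1) * tt$var2) / (tt$n1 + tt$n2 - 2)
  d <- ifelse(sp2 > 0, (tt$mean1 - tt$mean2) / sqrt(sp2), NA_real_)
  p_perm <- rep(NA_real_, ncol(ms))
  if (n_perm > 0L) {
    p_perm <- withr_seed(seed, {
      g <- as.factor(group)
      obs <- abs(tt$t)
      exceed <- rep(0L, ncol(ms))
      for (b in seq_len(n_perm)) {
        tb <- col_t_twosample(ms, sample(g), var_equal = var_equal)
        exceed <- exceed + (abs(tb$t) >= obs)
      }
      (1 + exceed) / (1 + n_perm)
    })
  }
  out <- data.frame(region = colnames(ms) %||% seq_len(ncol(ms)),
                    mean_control = tt$mean1, mean_patient = tt$mean2,
                    t = tt$t, df = tt$df, p = tt$p, q = q, p_perm = p_perm,
                    d = d, significant = q < fdr_q,
                    stringsAsFactors = FALSE)
  attr(out, "fdr") <- list(method = fdr_method, q = fdr_q, n_perm = n_perm,
                           var_equal = var_equal, levels = tt$levels)
  out
}

#' Hub relationship: correlate a case-control map with a hub map
#'
#' Pearson correlation across regions between the case-control t map and
#' the control-group mean MS map ("hubness"), with a region-label
#' permutation p-value. A positive correlation means hubs (high mean MS)
#' show the largest control-minus-patient differences.
#'
#' @param t_map named per-region t statistics.
#' @param hub_map named per-region control mean MS.
#' @param n_perm permutations (default 1000).
#' @param seed RNG seed.
#' @return list as in [map_correlation()].
#' @export
hub_relationship <- function(t_map, hub_map, n_perm = 1000L, seed = 1L) {
  map_correlation(t_map, hub_map, n_perm = n_perm, seed = seed)
}

#' Linear model of PAL errors on group and age
#'
#' Fits `total_errors ~ group + age` and reports partial F-tests for the
#' two main effects (the additive model matches the reported df structure),
#' then tests the group-by-age interaction by comparing the additive and
#' interaction models. Also returns the per-age-category Cohen's d for the
#' control-vs-patient difference.
#'
#' @param behaviour data frame with `subject_id`, `total_errors`.
#' @param demographics data frame with `subject_id`, `age`, `group`.
#' @param breaks age-category boundaries for the effect-size table.
#' @return list with `effects` (term, F, df1, df2, p), `interaction`
#'   (F, p), `d_by_category` data frame, `n`, and the fitted `model`.
#' @export
pal_model <- function(behaviour, demographics, breaks = DEFAULT_AGE_BREAKS) {
  d <- merge(demographics, behaviour, by = "subject_id")
  d <- d[stats::complete.cases(d[, c("total_errors", "age", "group")]), ]
  if (!all(table(d$group) >= 2L)) stop_msa("each group needs at least 2 complete rows")
  d$group <- factor(d$group)
  fit_add <- stats::lm(total_errors ~ group + age, data = d)
  fit_int <- stats::lm(total_errors ~ group * age, data = d)
  dr <- stats::drop1(fit_add, test = "F")
  effects <- data.frame(term = rownames(dr)[-1],
                        F = dr$`F value`[-1],
                        df1 = dr$Df[-1],
                        df2 = stats::df.residual(fit_add),
                        p = dr$`Pr(>F)`[-1],
                        stringsAsFactors = FALSE)
  an <- stats::anova(fit_add, fit_int)
  tss <- sum((d$total_errors - mean(d$total_errors))^2)
  interaction <- list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                      p = an$`Pr(>F)`[2],
                      ss_fraction = an$`Sum of Sq`[2] / tss)
  cats <- assign_age_category(pmin(pmax(d$age, breaks[1]), breaks[length(breaks)]),
                              breaks = breaks, policy = "drop")
  lv <- levels(d$group)
  d_by_category <- do.call(rbind, lapply(levels(cats), function(cl) {
    dd <- d[which(cats == cl), ]
    x <- dd$total_errors[dd$group == lv[1]]
    y <- dd$total_errors[dd$group == lv[2]]
    data.frame(category = cl, n_control = length(x), n_patient = length(y),
               d = if (length(x) > 1 && length(y) > 1)
                 abs(cohens_d(x, y)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(effects = effects, interaction = interaction,
       d_by_category = d_by_category, n = nrow(d), model = fit_add)
}
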