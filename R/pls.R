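# Two-block partial least squares (PLS2) regression of regional MS on an
# outcome block (age, PAL total errors), with permutation significance.
#
# Sequential deflation PLS2: each component's predictor weight vector is
# the leading left singular vector of the current cross-covariance X'Y;
# scores are X projections; X (and Y) are deflated by the component. Both
# blocks are z-scored first (age in years and error counts live on
# different scales). Components are sign-aligned so that each score vector
# correlates non-negatively with the first outcome column.

#' Fit a PLS2 regression
#'
#' @param X subjects x predictors matrix (regional mean MS).
#' @param Y subjects x outcomes matrix (e.g. age and PAL total errors).
#' @param n_components number of components (default 2).
#' @param scale z-score both blocks first (default TRUE; recorded).
#' @return object of class `pls_fit`: `x_weights`, `x_loadings`,
#'   `y_loadings` (all per component), `scores` (subjects x components),
#'   `pct_var_y` (% outcome-block variance explained per component),
#'   `cum_pct_var_y`, dropped predictor columns, and scaling info.
#' @export
fit_pls <- function(X, Y, n_components = 2L, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_msa("X and Y must have the same rows")
  n <- nrow(X)
  if (n <= n_components) stop_msa("need more subjects than components")
  if (any(!stats::complete.cases(X)) || any(!stats::complete.cases(Y)))
    stop_msa("missing values in the blocks; drop incomplete subjects first")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(ncol(Y)))
  x_sd <- apply(X, 2L, stats::sd)
  dropped <- colnames(X)[x_sd == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d constant predictor column(s)", length(dropped)))
    X <- X[, x_sd > 0, drop = FALSE]
  }
  if (any(apply(Y, 2L, stats::sd) == 0)) stop_msa("constant outcome column")
  if (scale) {
    X <- base::scale(X)
    Y0 <- base::scale(Y)
  } else {
    X <- base::scale(X, scale = FALSE)
    Y0 <- base::scale(Y, scale = FALSE)
  }
  ssy_total <- sum(Y0^2)
  p <- ncol(X); q <- ncol(Y0)
  W <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  C <- matrix(0, q, n_components, dimnames = list(colnames(Y0), NULL))
  Tt <- matrix(0, n, n_components)
  pct <- numeric(n_components)
  Xk <- X; Yk <- Y0
  for (k in seq_len(n_components)) {
    M <- crossprod(Xk, Yk)
    sv <- svd(M, nu = 1, nv = 0)
    w <- sv$u[, 1]
    t_k <- drop(Xk %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) stop_msa("degenerate component %d (no covariance left)", k)
    p_k <- drop(crossprod(Xk, t_k)) / tt
    c_k <- drop(crossprod(Yk, t_k)) / tt
    # sign alignment: score correlates non-negatively with first outcome col
    if (stats::cor(t_k, Y0[, 1]) < 0) {
      w <- -w; t_k <- -t_k; p_k <- -p_k; c_k <- -c_k
    }
    W[, k] <- w; P[, k] <- p_k; C[, k] <- c_k; Tt[, k] <- t_k
    pct[k] <- 100 * tt * sum(c_k^2) / ssy_total
    Xk <- Xk - tcrossprod(t_k, p_k)
    Yk <- Yk - tcrossprod(t_k, c_k)
  }
  structure(list(x_weights = W, x_loadings = P, y_loadings = C, scores = Tt,
                 pct_var_y = pct, cum_pct_var_y = cumsum(pct),
                 n_components = n_components, n = n, scaled = scale,
                 dropped_predictors = dropped,
                 outcome_names = colnames(Y0)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS2 fit: %d components on %d subjects x %d predictors\n",
              x$n_components, x$n, nrow(x$x_weights)))
  cat(sprintf("  %% outcome-block variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f", x$pct_var_y), collapse = ", "),
              max(x$cum_pct_var_y)))
  invisible(x)
}

#' Permutation significance of PLS components
#'
#' Rebuilds the null by shuffling outcome rows jointly against predictor
#' rows (preserving the age-PAL coupling) and refitting; the statistic per
#' component is its % outcome variance explained. P-values use the add-one
#' estimator `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param X,Y the blocks as in [fit_pls()].
#' @param n_components number of components.
#' @param n_perm number of permutations (default 5000; < 100 warns).
#' @param seed RNG seed.
#' @param scale passed to [fit_pls()].
#' @return list `p` (per component), `observed` (% variance), `n_perm`.
#' @export
pls_permutation <- function(X, Y, n_components = 2L, n_perm = 5000L, seed = 1L,
                            scale = TRUE) {
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  fit <- fit_pls(X, Y, n_components = n_components, scale = scale)
  obs <- fit$pct_var_y
  Y <- as.matrix(Y)
  exceed <- withr_seed(seed, {
    ex <- rep(0L, n_components)
    for (b in seq_len(n_perm)) {
      fb <- fit_pls(X, Y[sample(nrow(Y)), , drop = FALSE],
                    n_components = n_components, scale = scale)
      ex <- ex + (fb$pct_var_y >= obs)
    }
    ex
  })
  list(p = (1 + exceed) / (1 + n_perm), observed = obs, n_perm = n_perm)
}

#' Correlations between component scores and outcomes
#'
#' @param fit a `pls_fit`.
#' @param Y outcomes matrix (same rows as the fit).
#' @return data frame `component, outcome, r, p`.
#' @export
score_outcome_correlations <- function(fit, Y) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%d", seq_len(ncol(Y)))
  out <- expand.grid(component = seq_len(fit$n_components),
                     outcome = colnames(Y), stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    ct <- stats::cor.test(fit$scores[, out$component[i]], Y[, out$outcome[i]])
    out$r[i] <- unname(ct$estimate); out$p[i] <- ct$p.value
  }
  out
}

#' Group comparison of component scores
#'
#' Two-sample t-test on each component's subject scores with a group-label
#' permutation p-value.
#'
#' @param fit a `pls_fit`.
#' @param group group labels aligned with the fitted subjects.
#' @param n_perm label permutations (default 1000).
#' @param seed RNG seed.
#' @return data frame `component, t, df, p, p_perm` (t is first level minus
#'   second level of `factor(group)`).
#' @export
group_score_comparison <- function(fit, group, n_perm = 1000L, seed = 1L) {
  g <- factor(group)
  tt <- col_t_twosample(fit$scores, g)
  p_perm <- withr_seed(seed, {
    obs <- abs(tt$t)
    exceed <- rep(0L, fit$n_components)
    for (b in seq_len(n_perm)) {
      tb <- col_t_twosample(fit$scores, sample(g))
      exceed <- exceed + (abs(tb$t) >= obs)
    }
    (1 + exceed) / (1 + n_perm)
  })
  data.frame(component = seq_len(fit$n_components), t = tt$t, df = tt$df,
             p = tt$p, p_perm = p_perm)
}

#' Correlate component loading maps with a case-control t map
#'
#' @param fit a `pls_fit`.
#' @param t_map named per-region t statistics over the fitted predictors.
#' @param n_perm region-label permutations.
#' @param seed RNG seed.
#' @return data frame `component, r, p_perm`.
#' @export
loading_map_correlation <- function(fit, t_map, n_perm = 1000L, seed = 1L) {
  regions <- rownames(fit$x_loadings)
  if (!setequal(regions, names(t_map)))
    stop_msa("t map and loadings cover different region sets")
  t_map <- t_map[regions]
  out <- data.frame(component = seq_len(fit$n_components),
                    r = NA_real_, p_perm = NA_real_)
  for (k in seq_len(fit$n_components)) {
    mc <- map_correlation(fit$x_loadings[, k], t_map, n_perm = n_perm,
                          seed = derive_seed(seed, k))
    out$r[k] <- mc$r; out$p_perm[k] <- mc$p_perm
  }
  out
}
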