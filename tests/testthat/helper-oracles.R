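# Shared fixtures and independent oracles for the suite.
# Oracles are deliberately naive (loops, textbook formulas) and never call
# the implementation paths they check.

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# brute-force MS matrix: per-pair Pearson across features
ms_matrix_oracle <- function(z) {
  n <- nrow(z)
  m <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- pearson_oracle(z[i, ], z[j, ])
  }
  dimnames(m) <- list(rownames(z), rownames(z))
  m
}

# brute-force regional mean MS: column mean excluding the diagonal
regional_ms_oracle <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- sum(m[-j, j]) / (n - 1)
  names(out) <- colnames(m)
  out
}

# normal-equations least squares for polynomial fits
polyfit_oracle <- function(age, y, degree) {
  X <- outer(age, 0:degree, `^`)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# random feature block on raw-like scales
random_feature_block <- function(n_regions, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_regions * 7, mean = rep(c(4000, 300, 2.5, 0.1, 0, 15, 0.5),
                                              each = n_regions),
                    sd = rep(c(400, 30, 0.3, 0.02, 0.2, 2, 0.05), each = n_regions)),
              n_regions, 7)
  dimnames(x) <- list(sprintf("r%02d", seq_len(n_regions)),
                      sprintf("f%d", 1:7))
  x
}

# The four enumerated accelerated-ageing direction rules, written case by
# case (shape class first, then the turning point against the category
# bounds; a turning point strictly inside the category leaves the direction
# undetermined). Independent of the uniform slope-sign rule in the package.
enumerated_direction_oracle <- function(a1, a2, lo, hi, early = 27, late = 60) {
  s_early <- a1 + 2 * a2 * early
  s_late <- a1 + 2 * a2 * late
  shape <- if (s_early >= 0 && s_late >= 0) "increasing"
    else if (s_early < 0 && s_late < 0) "decreasing"
    else if (s_early >= 0) "convex" else "concave"
  tp <- if (a2 == 0) NA_real_ else -a1 / (2 * a2)
  if (!is.na(tp) && tp > lo && tp < hi) return(NA_integer_)
  switch(shape,
    increasing = 1L,
    decreasing = -1L,
    convex = if (tp >= hi) 1L else -1L,
    concave = if (tp >= hi) -1L else 1L)
}

# small synthetic world shared by several tests
make_small_world <- function(seed = 1, n_regions = 60, n_normative = 300) {
  tr <- default_trajectories(default_parcellation(n_regions), seed = seed)
  demo <- sample_cohort(cohort_spec(n_normative, c(20, 80), group = "normative",
                                    seed = seed + 1))
  ms <- generate_regional_ms(demo, tr, seed = seed + 2)
  list(trajectories = tr, demographics = demo, ms = ms,
       model = fit_normative_model(ms, demo$age))
}
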