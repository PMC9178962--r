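# Internal helpers shared across modules.

# Derive a child seed from a run seed and a stage offset; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483647L) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_msa <- function(...) stop(sprintf(...), call. = FALSE)

# Polynomial rolling hash (mod 2^31 - 1) of a character vector, used to make
# result files self-describing (parcellation / config fingerprints).
# Deterministic fingerprint only, not cryptographic.
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\x1f"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Column-wise one-sample t-tests against zero for a subjects x regions matrix.
col_t_onesample <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  ss <- colSums(x^2) - n * m^2
  s2 <- ss / (n - 1)
  s2[s2 < 0] <- 0
  se <- sqrt(s2 / n)
  t <- ifelse(se > 0, m / se, NA_real_)
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(n = n, mean = m, sd = sqrt(s2), t = t, p = p)
}

# Column-wise two-sample t-tests (pooled variance by default) for a
# subjects x regions matrix split by a two-level grouping vector.
col_t_twosample <- function(x, g, var_equal = TRUE) {
  g <- as.factor(g)
  if (nlevels(g) != 2L) stop_msa("grouping must have exactly 2 levels, got %d", nlevels(g))
  i1 <- g == levels(g)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2L || n2 < 2L) stop_msa("each group needs at least 2 subjects (got %d and %d)", n1, n2)
  x1 <- x[i1, , drop = FALSE]; x2 <- x[!i1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- ifelse(se > 0, (m1 - m2) / se, NA_real_)
  p <- 2 * stats::pt(-abs(t), df = df)
  list(levels = levels(g), n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
       var1 = v1, var2 = v2, t = t, df = df, p = p)
}

#' Storey-style q-values
#'
#' Minimal Storey q-value estimator: the proportion of true nulls `pi0` is
#' estimated as `mean(p > lambda) / (1 - lambda)` (capped at 1) and q-values
#' are `pi0` times the Benjamini-Hochberg adjusted p-values. With `pi0 = 1`
#' this reduces exactly to BH.
#'
#' @param p numeric vector of p-values.
#' @param lambda tuning point for the `pi0` estimate (default 0.5).
#' @return numeric vector of q-values, same length as `p`.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), lambda > 0, lambda < 1)
  pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / length(p) # degenerate: everything small
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

# Dispatch on the configured FDR method.
adjust_fdr <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (method == "BH") stats::p.adjust(p, method = "BH") else storey_qvalue(p)
}
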