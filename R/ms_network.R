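# Morphometric similarity (MS) networks.
#
# An MS network treats each cortical region as a profile of structural
# features (volume, surface area, thickness, curvature measures, ...).
# After z-scoring each feature across regions within a subject, the
# similarity between two regions is the Pearson correlation of their
# feature profiles; a region's mean similarity to all other regions is its
# weighted degree ("hubness").

#' Default cortical parcellation labels
#'
#' Opaque region labels standing in for a 360-region cortical parcellation.
#' No surface geometry is attached: the parcellation is a fixed, ordered
#' label list shared by all artifacts of a run.
#'
#' @param n number of regions (default 360).
#' @return character vector of unique region labels.
#' @export
default_parcellation <- function(n = 360L) {
  sprintf("roi_%03d", seq_len(n))
}

#' Z-score a subject's region-by-feature block
#'
#' Each feature column is mean-centred and scaled to unit sample standard
#' deviation (denominator n - 1) across regions within the subject.
#'
#' @param x numeric matrix, regions x features, with dimnames.
#' @return matrix of the same shape with each column standardized.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_msa("need at least 2 regions to z-score, got %d", nrow(x))
  if (any(!is.finite(x))) stop_msa("feature block contains non-finite values")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    nm <- colnames(x)[bad] %||% as.character(bad)
    stop_msa("feature(s) constant across regions (zero variance): %s",
             paste(nm, collapse = ", "))
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

#' Morphometric similarity matrix for one subject
#'
#' Entry (r, q) is the Pearson correlation between the z-scored feature
#' profiles of regions r and q. Regions whose profile has zero variance
#' across features yield `NA` entries and are reported via the
#' `"degenerate_regions"` attribute.
#'
#' @param z z-scored regions x features matrix (see [zscore_features()]).
#' @return symmetric regions x regions correlation matrix, unit diagonal.
#' @export
compute_ms_matrix <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2L) stop_msa("need at least 2 features per region")
  profile_sd <- apply(z, 1L, stats::sd)
  degenerate <- rownames(z)[profile_sd == 0] %||% character(0)
  m <- suppressWarnings(stats::cor(t(z)))
  diag(m) <- 1
  if (length(degenerate)) {
    m[profile_sd == 0, ] <- NA_real_
    m[, profile_sd == 0] <- NA_real_
    diag(m) <- 1
  }
  attr(m, "degenerate_regions") <- degenerate
  m
}

#' Regional mean morphometric similarity (weighted degree)
#'
#' Mean of each column of the MS matrix excluding the diagonal
#' self-correlation, i.e. weighted degree divided by (N - 1). Including the
#' diagonal would inflate every value by about 1/N.
#'
#' @param m symmetric MS matrix.
#' @return named numeric vector, one mean similarity per region.
#' @export
regional_mean_ms <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_msa("MS matrix must be square")
  n <- nrow(m)
  if (n < 2L) stop_msa("MS matrix needs at least 2 regions")
  (colSums(m) - diag(m)) / (n - 1)
}

#' Regional mean MS for a whole cohort of feature tables
#'
#' Runs z-scoring, MS matrix construction and column averaging for every
#' subject in a long feature table.
#'
#' @param features data frame with columns `subject_id`, `region` and one
#'   column per feature (wide-by-feature dialect, as produced by
#'   [generate_feature_table()] or [read_feature_table()]).
#' @return numeric matrix, subjects x regions, rownames = subject ids.
#' @export
cohort_regional_ms <- function(features) {
  validate_feature_table(features)
  feat_cols <- setdiff(names(features), c("subject_id", "region"))
  subjects <- unique(features$subject_id)
  regions <- unique(features$region)
  out <- matrix(NA_real_, length(subjects), length(regions),
                dimnames = list(subjects, regions))
  idx <- split(seq_len(nrow(features)), features$subject_id)
  for (s in subjects) {
    block <- features[idx[[as.character(s)]], , drop = FALSE]
    x <- as.matrix(block[, feat_cols, drop = FALSE])
    rownames(x) <- block$region
    x <- x[regions, , drop = FALSE]
    ms <- compute_ms_matrix(zscore_features(x))
    out[as.character(s), ] <- regional_mean_ms(ms)
  }
  out
}

#' Cohort-average regional MS map
#'
#' @param ms subjects x regions matrix of regional mean MS.
#' @return named numeric vector of per-region means, with attribute
#'   `"n_subjects"`.
#' @export
cohort_mean_map <- function(ms) {
  ms <- as.matrix(ms)
  if (nrow(ms) < 1L) stop_msa("empty cohort")
  out <- colMeans(ms)
  attr(out, "n_subjects") <- nrow(ms)
  out
}

#' Correlation between two regional maps
#'
#' Pearson correlation across regions between two per-region maps, with an
#' optional permutation p-value obtained by shuffling region labels of the
#' second map.
#'
#' @param a,b named numeric vectors over the same region set.
#' @param n_perm number of label permutations (0 = analytic p only).
#' @param seed RNG seed for the permutations.
#' @param alternative `"two.sided"` (default) or `"greater"` for the
#'   permutation tail.
#' @return list with `r`, `p` (analytic) and `p_perm` (`NA` if `n_perm` = 0).
#' @export
map_correlation <- function(a, b, n_perm = 0L, seed = 1L,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a) != length(b)) stop_msa("maps have different lengths")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop_msa("maps cover different region sets")
    b <- b[names(a)]
  }
  if (length(a) < 3L) stop_msa("need at least 3 regions")
  r <- stats::cor(a, b)
  p <- stats::cor.test(a, b)$p.value
  p_perm <- NA_real_
  if (n_perm > 0L) {
    stat <- if (alternative == "two.sided") abs(r) else r
    null <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        rp <- stats::cor(a, sample(b))
        if (alternative == "two.sided") abs(rp) else rp
      }, numeric(1))
    })
    p_perm <- (1 + sum(null >= stat)) / (1 + n_perm)
  }
  list(r = r, p = p, p_perm = p_perm, n_regions = length(a))
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's random state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
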