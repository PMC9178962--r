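# Stable file formats: CSV readers/writers for the pipeline tables, a YAML
# run configuration, and self-describing JSON metadata.

validate_feature_table <- function(features) {
  need <- c("subject_id", "region")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop_msa("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  feat_cols <- setdiff(names(features), need)
  if (length(feat_cols) < 2L) stop_msa("feature table needs at least 2 feature columns")
  vals <- as.matrix(features[, feat_cols])
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1, 1]
    stop_msa("non-finite feature value at row %d", bad)
  }
  counts <- table(features$subject_id, features$region)
  if (any(counts > 1L)) {
    ij <- which(counts > 1L, arr.ind = TRUE)[1, ]
    stop_msa("duplicate rows for subject %s, region %s",
             rownames(counts)[ij[1]], colnames(counts)[ij[2]])
  }
  if (any(counts == 0L)) {
    ij <- which(counts == 0L, arr.ind = TRUE)[1, ]
    stop_msa("subject %s is missing region %s",
             rownames(counts)[ij[1]], colnames(counts)[ij[2]])
  }
  invisible(features)
}

#' Read a feature table CSV (long or wide dialect)
#'
#' The dialect is auto-detected from the header: a `feature`/`value` column
#' pair marks the long dialect (one row per subject x region x feature),
#' otherwise feature columns sit next to `subject_id`/`region` (wide).
#' The table is validated: every subject must have every region exactly
#' once, all values finite; with a parcellation, unknown region labels and
#' incomplete coverage are errors.
#'
#' @param path CSV/TSV file path (separator auto-detected).
#' @param parcellation optional character vector of expected region labels.
#' @return wide-dialect data frame `subject_id, region, <features...>`.
#' @export
read_feature_table <- function(path, parcellation = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (all(c("feature", "value") %in% names(x))) {
    wide <- stats::reshape(x, idvar = c("subject_id", "region"),
                           timevar = "feature", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    x <- wide
  }
  if (!is.null(parcellation)) {
    unknown <- setdiff(unique(x$region), parcellation)
    if (length(unknown))
      stop_msa("unknown region label(s): %s", paste(utils::head(unknown, 5), collapse = ", "))
    covered <- table(x$subject_id)
    if (any(covered != length(parcellation)))
      stop_msa("subject(s) without full parcellation coverage: %s",
               paste(utils::head(names(covered)[covered != length(parcellation)], 5),
                     collapse = ", "))
  }
  validate_feature_table(x)
  x
}

#' Write a feature table CSV
#'
#' @param features wide-dialect feature table.
#' @param path output path.
#' @param dialect `"wide"` (default) or `"long"`.
#' @export
write_feature_table <- function(features, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    feat_cols <- setdiff(names(features), c("subject_id", "region"))
    features <- do.call(rbind, lapply(feat_cols, function(f) {
      data.frame(subject_id = features$subject_id, region = features$region,
                 feature = f, value = features[[f]], stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a regional MS matrix CSV
#'
#' Wide layout: one row per subject (`subject_id` column), one column per
#' region.
#'
#' @param ms subjects x regions matrix.
#' @param path file path.
#' @return `read_regional_ms` returns the matrix with subject rownames.
#' @export
write_regional_ms <- function(ms, path) {
  df <- data.frame(subject_id = rownames(ms), as.data.frame(ms),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_regional_ms
#' @export
read_regional_ms <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  m
}

#' Write / read the normative model as CSV
#'
#' Columns: region, a0, a1, a2, adj_r2, retained, category, turning_point.
#' Reference ages, age range and cohort size travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param model a `normative_model`.
#' @param path CSV path.
#' @return `read_normative_model` reconstructs the `normative_model`.
#' @export
write_normative_model <- function(model, path) {
  tr <- model$trajectories
  keep <- c("region", "a0", "a1", "a2", "se_a0", "se_a1", "se_a2",
            "adj_r2", "retained", "category", "turning_point")
  utils::write.csv(tr[, keep], path, row.names = FALSE, quote = FALSE)
  meta <- list(reference_ages = as.list(model$reference_ages),
               age_range = model$age_range, n_subjects = model$n_subjects,
               n_excluded = model$n_excluded)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  structure(list(trajectories = tr,
                 reference_ages = c(early = meta$reference_ages$early,
                                    late = meta$reference_ages$late),
                 age_range = meta$age_range,
                 n_subjects = meta$n_subjects,
                 n_excluded = meta$n_excluded),
            class = "normative_model")
}

#' Serialize a brain-age model to JSON
#'
#' Weights are keyed by region label so the model survives column
#' reordering.
#'
#' @param model a `brain_age_model`.
#' @param path JSON path.
#' @return `read_brain_age_model` reconstructs the model.
#' @export
write_brain_age_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_brain_age_model
#' @export
read_brain_age_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- stats::setNames(as.numeric(x$weights), x$regions)
  structure(x, class = "brain_age_model")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file describing [pipeline_config()] fields.
#' @return a `pipeline_config` list.
#' @export
read_run_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Self-describing run metadata written next to every result bundle.
run_metadata <- function(config, parcellation) {
  list(package_version = as.character(utils::packageVersion("msageing")),
       config = config,
       config_hash = content_hash(utils::capture.output(utils::str(config))),
       parcellation_n = length(parcellation),
       parcellation_hash = content_hash(parcellation),
       conventions = list(deviation_sign = "observed_minus_predicted",
                          gap_sign = config$gap_convention,
                          fdr_method = config$fdr_method))
}
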