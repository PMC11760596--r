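# Epoch aggregation and feature quality control.
#
# Pipeline order is fixed: aggregate -> non-informative filter -> mean
# imputation -> correlation pruning -> log transform of skewed features ->
# per-value outlier removal -> re-imputation. No step reorders or drops
# subject-visit rows; QC acts on feature columns only.

#' Quality-control configuration
#'
#' Numeric thresholds for the feature QC pipeline. None of these are
#' dictated by the methodology itself; they are package defaults, all
#' overridable and recorded in the [run_qc()] report.
#'
#' @param min_distinct_values features with fewer distinct observed values
#'   are removed as non-informative.
#' @param max_missing_fraction features missing more than this fraction of
#'   cells are removed.
#' @param extreme_value_rule a feature containing any value with robust
#'   z-score (median/MAD scaling) beyond this cutoff is removed.
#' @param corr_threshold absolute Pearson correlation above which the
#'   later (lower-variance) member of a feature pair is pruned.
#' @param skew_threshold absolute adjusted Fisher-Pearson sample skewness
#'   above which a feature is log-transformed.
#' @param outlier_winsor_z per-value robust z beyond which an individual
#'   value is removed (set missing, then re-imputed).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_distinct_values = 5,
                      max_missing_fraction = 0.5,
                      extreme_value_rule = 6,
                      corr_threshold = 0.95,
                      skew_threshold = 2.0,
                      outlier_winsor_z = 4) {
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1) {
    digicomp_error("max_missing_fraction must be in (0, 1)", "digicomp_config_error")
  }
  if (any(c(min_distinct_values, extreme_value_rule, corr_threshold,
            skew_threshold, outlier_winsor_z) <= 0)) {
    digicomp_error("all QC thresholds must be positive", "digicomp_config_error")
  }
  structure(list(min_distinct_values = min_distinct_values,
                 max_missing_fraction = max_missing_fraction,
                 extreme_value_rule = extreme_value_rule,
                 corr_threshold = corr_threshold,
                 skew_threshold = skew_threshold,
                 outlier_winsor_z = outlier_winsor_z),
            class = "qc_config")
}

new_qc_report <- function(features, disposition) {
  data.frame(feature = features, disposition = disposition,
             transform = "none", shift = 0,
             n_imputed = 0L, n_outliers_removed = 0L,
             stringsAsFactors = FALSE)
}

#' Aggregate epoch-level features into task-level summary statistics
#'
#' Collapses repeated within-task measurements (per step, per turn, per
#' second, ...) into one column per (task, feature, statistic):
#' mean, median, standard deviation, and mean absolute deviation about the
#' mean. Missing epochs are dropped before aggregation; a group with no
#' observed epochs yields a missing cell.
#'
#' @param epochs long table with columns `subject_id`, `visit_time`,
#'   `task`, `feature_name`, `epoch_index`, `value`.
#' @param stats subset of `c("mean", "median", "sd", "mad")`.
#' @return a data.frame keyed by `subject_id`, `visit_time`, with one
#'   column per `<task>_<feature>_<stat>`.
#' @export
aggregate_epochs <- function(epochs, stats = c("mean", "median", "sd", "mad")) {
  stats <- match.arg(stats, c("mean", "median", "sd", "mad"), several.ok = TRUE)
  need <- c("subject_id", "visit_time", "task", "feature_name", "value")
  if (!all(need %in% names(epochs))) {
    digicomp_error("epochs table is missing required columns", "digicomp_input_error")
  }
  sep <- "\r"
  row_key <- paste(epochs$subject_id, epochs$visit_time, sep = sep)
  grp_key <- paste(row_key, epochs$task, epochs$feature_name, sep = sep)
  idx <- split(seq_len(nrow(epochs)), grp_key)
  fns <- list(mean = mean, median = stats::median, sd = stats::sd,
              mad = mean_abs_dev)

  urows <- unique(row_key)
  parts <- do.call(rbind, strsplit(names(idx), sep, fixed = TRUE))
  out_row <- match(paste(parts[, 1], parts[, 2], sep = sep), urows)
  col_base <- paste(parts[, 3], parts[, 4], sep = "_")

  cols <- sort(unique(as.vector(outer(col_base, stats, paste, sep = "_"))))
  M <- matrix(NA_real_, length(urows), length(cols),
              dimnames = list(NULL, cols))
  for (g in seq_along(idx)) {
    v <- epochs$value[idx[[g]]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    for (s in stats) {
      M[out_row[g], paste(col_base[g], s, sep = "_")] <- fns[[s]](v)
    }
  }
  key_parts <- do.call(rbind, strsplit(urows, sep, fixed = TRUE))
  out <- data.frame(subject_id = key_parts[, 1],
                    visit_time = as.numeric(key_parts[, 2]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(M))
  out[order(out$subject_id, out$visit_time), , drop = FALSE]
}

#' Remove non-informative features
#'
#' Drops features with too few distinct observed values, excessive
#' missingness, or extreme values (any robust z beyond the cutoff after
#' median/MAD scaling), in that order of precedence.
#'
#' @param data longitudinal dataset.
#' @param qc a [qc_config()].
#' @param features feature columns to consider (default: all).
#' @return `list(data = filtered data, report = QC report rows)`.
#' @export
filter_noninformative <- function(data, qc = qc_config(),
                                  features = feature_columns(data)) {
  if (!length(features)) {
    digicomp_error("no feature columns to filter", "digicomp_empty_panel_error")
  }
  report <- new_qc_report(features, "kept")
  for (f in features) {
    x <- data[[f]]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < qc$min_distinct_values) {
      report$disposition[report$feature == f] <- "removed_noninformative"
    } else if (mean(is.na(x)) > qc$max_missing_fraction) {
      report$disposition[report$feature == f] <- "removed_missing"
    } else if (any(abs(robust_z(obs)) > qc$extreme_value_rule)) {
      report$disposition[report$feature == f] <- "removed_extreme"
    }
  }
  drop <- report$feature[report$disposition != "kept"]
  out <- data[, setdiff(names(data), drop), drop = FALSE]
  if (!length(setdiff(features, drop))) {
    digicomp_error("all features removed by the non-informative filter",
                   "digicomp_empty_panel_error")
  }
  list(data = out, report = report)
}

#' Impute missing feature values with the feature mean
#'
#' Observed cells are unchanged, so the post-imputation column mean equals
#' the pre-imputation observed mean exactly.
#'
#' @inheritParams filter_noninformative
#' @return `list(data, report)` where the report counts imputed cells.
#' @export
impute_mean <- function(data, features = feature_columns(data)) {
  report <- new_qc_report(features, "kept")
  for (f in features) {
    x <- data[[f]]
    miss <- is.na(x)
    if (all(miss)) {
      digicomp_error(sprintf("feature '%s' has no observed values", f),
                     "digicomp_input_error")
    }
    if (any(miss)) {
      data[[f]][miss] <- mean(x[!miss])
      report$n_imputed[report$feature == f] <- sum(miss)
    }
  }
  list(data = data, report = report)
}

#' Prune highly correlated features
#'
#' Greedy pass over features in a fixed order (descending variance, ties
#' broken by name): a feature whose absolute Pearson correlation with an
#' already-retained feature exceeds the threshold is dropped, so no
#' retained pair exceeds the threshold and the higher-variance member of
#' a correlated pair survives.
#'
#' @inheritParams filter_noninformative
#' @param corr_threshold absolute correlation cutoff.
#' @return `list(data, report)`.
#' @export
prune_correlated <- function(data, corr_threshold = 0.95,
                             features = feature_columns(data)) {
  report <- new_qc_report(features, "kept")
  if (length(features) < 2) return(list(data = data, report = report))
  X <- as.matrix(data[, features, drop = FALSE])
  if (anyNA(X)) {
    digicomp_error("prune_correlated requires a complete (imputed) matrix",
                   "digicomp_input_error")
  }
  v <- apply(X, 2, stats::var)
  ord <- features[order(-v, features)]
  kept <- character(0)
  for (f in ord) {
    if (length(kept)) {
      r <- suppressWarnings(stats::cor(X[, f], X[, kept, drop = FALSE]))
      r[is.na(r)] <- 0  # zero-variance columns correlate with nothing
      if (any(abs(r) > corr_threshold)) {
        report$disposition[report$feature == f] <- "removed_correlated"
        next
      }
    }
    kept <- c(kept, f)
  }
  drop <- report$feature[report$disposition != "kept"]
  list(data = data[, setdiff(names(data), drop), drop = FALSE], report = report)
}

#' Log-transform skewed features
#'
#' Features whose absolute adjusted Fisher-Pearson sample skewness exceeds
#' the threshold are replaced by their natural log; features that are not
#' strictly positive are shifted by `1 - min(x)` before the log. The
#' transform and shift are recorded in the report.
#'
#' @inheritParams filter_noninformative
#' @param skew_threshold absolute skewness cutoff.
#' @return `list(data, report)`.
#' @export
log_transform_skewed <- function(data, skew_threshold = 2.0,
                                 features = feature_columns(data)) {
  report <- new_qc_report(features, "kept")
  for (f in features) {
    x <- data[[f]]
    if (anyNA(x)) {
      digicomp_error("log_transform_skewed requires a complete matrix",
                     "digicomp_input_error")
    }
    sk <- e1071::skewness(x, type = 2)
    if (is.na(sk) || abs(sk) <= skew_threshold) next
    shift <- if (min(x) > 0) 0 else 1 - min(x)
    data[[f]] <- log(x + shift)
    report$transform[report$feature == f] <- "log"
    report$shift[report$feature == f] <- shift
  }
  list(data = data, report = report)
}

#' Remove per-value outliers
#'
#' Individual values whose robust z (median/MAD of the feature) exceeds
#' the cutoff are set missing; whole rows are never dropped, preserving
#' the longitudinal grid. Call [impute_mean()] afterwards to re-complete
#' the matrix. Features with zero MAD are left untouched.
#'
#' @inheritParams filter_noninformative
#' @param outlier_winsor_z robust z cutoff.
#' @return `list(data, report)` counting removed values per feature.
#' @export
remove_outlier_values <- function(data, outlier_winsor_z = 4,
                                  features = feature_columns(data)) {
  report <- new_qc_report(features, "kept")
  for (f in features) {
    x <- data[[f]]
    if (stats::mad(x, na.rm = TRUE) == 0) next
    bad <- !is.na(x) & abs(robust_z(x)) > outlier_winsor_z
    if (any(bad)) {
      data[[f]][bad] <- NA_real_
      report$n_outliers_removed[report$feature == f] <- sum(bad)
    }
  }
  list(data = data, report = report)
}

#' Run the full feature quality-control pipeline
#'
#' Applies, in fixed order: non-informative filtering, mean imputation,
#' correlation pruning, log transform of skewed features, per-value
#' outlier removal, and re-imputation. Subject-visit rows are never
#' reordered or dropped. On data that is already clean the pipeline is a
#' no-op.
#'
#' @param data longitudinal dataset (post-aggregation).
#' @param qc a [qc_config()].
#' @param features feature columns to process.
#' @return `list(data, report)`; the report assigns every input feature
#'   exactly one disposition (`kept`, `removed_noninformative`,
#'   `removed_missing`, `removed_extreme`, `removed_correlated`) plus the
#'   transform applied and counts of imputed cells and removed outliers.
#' @export
run_qc <- function(data, qc = qc_config(), features = feature_columns(data)) {
  s1 <- filter_noninformative(data, qc, features)
  kept1 <- s1$report$feature[s1$report$disposition == "kept"]
  s2 <- impute_mean(s1$data, kept1)
  s3 <- prune_correlated(s2$data, qc$corr_threshold, kept1)
  kept3 <- s3$report$feature[s3$report$disposition == "kept"]
  s4 <- log_transform_skewed(s3$data, qc$skew_threshold, kept3)
  s5 <- remove_outlier_values(s4$data, qc$outlier_winsor_z, kept3)
  s6 <- impute_mean(s5$data, kept3)

  report <- new_qc_report(features, "kept")
  for (step in list(s1$report, s3$report)) {
    rm_i <- step$disposition != "kept"
    report$disposition[match(step$feature[rm_i], report$feature)] <-
      step$disposition[rm_i]
  }
  m4 <- match(s4$report$feature, report$feature)
  report$transform[m4] <- s4$report$transform
  report$shift[m4] <- s4$report$shift
  report$n_imputed[match(s2$report$feature, report$feature)] <- s2$report$n_imputed
  report$n_imputed[match(s6$report$feature, report$feature)] <-
    report$n_imputed[match(s6$report$feature, report$feature)] + s6$report$n_imputed
  report$n_outliers_removed[match(s5$report$feature, report$feature)] <-
    s5$report$n_outliers_removed
  stopifnot(nrow(s6$data) == nrow(data))
  list(data = s6$data, report = report)
}
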