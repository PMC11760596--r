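# Internal helpers shared across modules.

digicomp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "digicomp_error")))
}

# Evaluate `code` under a given RNG seed without clobbering the caller's
# random stream.
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

meta_columns <- function(data) {
  fixed <- c("subject_id", "group", "visit_time", "age", "sex",
             "clinical_score", "composite", "fold")
  c(intersect(fixed, names(data)), grep("^subscale_", names(data), value = TRUE))
}

#' Identify digital feature columns of a longitudinal dataset
#'
#' Every column that is not part of the fixed subject-visit metadata
#' (`subject_id`, `group`, `visit_time`, `age`, `sex`, `clinical_score`,
#' `composite`, `fold`, or a `subscale_*` column) is treated as a digital
#' feature.
#'
#' @param data a longitudinal dataset (one row per subject-visit).
#' @return character vector of feature column names.
#' @export
feature_columns <- function(data) {
  setdiff(names(data), meta_columns(data))
}

# Subject-level fold assignment, stratified by group. Returns a named
# integer vector mapping subject_id -> fold.
make_subject_folds <- function(data, n_folds, seed) {
  if (n_folds < 2) {
    digicomp_error("n_folds must be >= 2", "digicomp_config_error")
  }
  subj <- data[!duplicated(data$subject_id), c("subject_id", "group")]
  fold <- integer(nrow(subj))
  names(fold) <- subj$subject_id
  local_seed(seed, {
    for (g in unique(subj$group)) {
      idx <- which(subj$group == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Numeric design columns for a set of covariates; factors are expanded to
# treatment-coded dummies (e.g. sex -> sexM). `factor_levels` pins the
# level sets (so a subset of rows missing a level still yields the same
# columns as the data the model was trained on).
encode_covariates <- function(data, covariates, factor_levels = NULL) {
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  cols <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.null(x)) {
      digicomp_error(sprintf("covariate column '%s' not found", cv),
                     "digicomp_input_error")
    }
    if (is.numeric(x)) {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- cv
      m
    } else {
      lv <- factor_levels[[cv]]
      if (is.null(lv)) lv <- levels(factor(x))
      if (length(lv) < 2) {
        # constant factor carries no information beyond the intercept
        return(matrix(numeric(0), nrow = length(x), ncol = 0))
      }
      f <- factor(x, levels = lv)
      mm <- matrix(0, length(x), length(lv) - 1)
      for (j in seq_along(lv)[-1]) mm[, j - 1] <- as.numeric(f == lv[j])
      colnames(mm) <- paste0(cv, lv[-1])
      mm
    }
  })
  do.call(cbind, cols)
}

# Level sets of the non-numeric covariates in `data`.
covariate_levels <- function(data, covariates) {
  lv <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x)) NULL else levels(factor(x))
  })
  names(lv) <- covariates
  lv[!vapply(lv, is.null, logical(1))]
}

# Mean absolute deviation about the mean (the aggregation "mad", distinct
# from stats::mad which is a median absolute deviation).
mean_abs_dev <- function(x) mean(abs(x - mean(x)))

# Robust z-scores via median/MAD scaling. A zero MAD yields +/-Inf for any
# value off the median (and 0 at the median).
robust_z <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, na.rm = TRUE)
  if (is.na(s)) s <- 0
  if (s == 0) {
    ifelse(x == med, 0, Inf * sign(x - med))
  } else {
    (x - med) / s
  }
}
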