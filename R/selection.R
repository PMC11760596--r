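# Feature ranking, cross-validated choice of the feature count, and
# merging of the progression and classification feature sets.

# Design matrix for GEE/PGEE fits on a longitudinal dataset: intercept,
# covariate columns (unpenalized), then feature columns (penalized).
build_design <- function(data, features, covariates, factor_levels = NULL) {
  Xc <- encode_covariates(data, covariates, factor_levels)
  Xf <- as.matrix(data[, features, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, Xc, Xf)
  list(X = X, penalized = ncol(X) - length(features) + seq_along(features))
}

endpoint_data <- function(data, endpoint, positive_group = "de_novo_pd",
                          negative_group = "hc") {
  if (endpoint == "classification") {
    sub <- data[data$group %in% c(positive_group, negative_group), , drop = FALSE]
    if (!nrow(sub)) {
      digicomp_error("classification endpoint groups not present in data",
                     "digicomp_input_error")
    }
    list(data = sub, y = as.numeric(sub$group == positive_group),
         family = "binomial", corstr = "independence")
  } else {
    list(data = data, y = data$clinical_score,
         family = "gaussian", corstr = "exchangeable")
  }
}

#' Penalized-GEE feature selection for one endpoint
#'
#' Fits a SCAD-penalized GEE of the endpoint on the candidate features
#' plus unpenalized covariates. The progression endpoint regresses the
#' clinical score on all rows (gaussian, exchangeable working
#' correlation); the classification endpoint regresses the de novo PD vs
#' HC indicator on the corresponding subset (binomial-logit, independence
#' working correlation). When `lambda` is `NULL` it is chosen by
#' cluster-level cross-validation via [tune_lambda()].
#'
#' @param data longitudinal dataset.
#' @param features candidate feature columns.
#' @param endpoint `"progression"` or `"classification"`.
#' @param covariates unpenalized adjustment covariates.
#' @param lambda SCAD penalty level, or `NULL` to tune.
#' @param lambda_grid optional grid for tuning.
#' @param n_folds,seed cross-validation settings for tuning.
#' @param ... further arguments to [fit_pgee()].
#' @return a `pgee_fit` with the endpoint recorded in `$endpoint`.
#' @export
pgee_select <- function(data, features, endpoint = c("progression", "classification"),
                        covariates = "age", lambda = NULL, lambda_grid = NULL,
                        n_folds = 5, seed = 1, ...) {
  endpoint <- match.arg(endpoint)
  ep <- endpoint_data(data, endpoint)
  des <- build_design(ep$data, features, covariates)
  if (is.null(lambda)) {
    lambda <- as.numeric(tune_lambda(des$X, ep$y, ep$data$subject_id,
                                     family = ep$family, corstr = ep$corstr,
                                     penalized = des$penalized,
                                     lambda_grid = lambda_grid,
                                     n_folds = n_folds, seed = seed, ...))
  }
  fit <- fit_pgee(des$X, ep$y, ep$data$subject_id, family = ep$family,
                  corstr = ep$corstr, lambda = lambda,
                  penalized = des$penalized, ...)
  fit$endpoint <- endpoint
  fit
}

#' Rank features by penalized-GEE estimate magnitude
#'
#' Descending absolute standardized PGEE estimate over the penalized
#' features; coefficients at zero (below the fit's `zero_cutoff`) are
#' excluded, and exact ties are broken by feature name, ascending.
#'
#' @param pgee_fit a `pgee_fit` from [fit_pgee()] or [pgee_select()].
#' @return an object of class `feature_ranking`: a data.frame with
#'   columns `feature`, `estimate` in rank order.
#' @export
rank_features <- function(pgee_fit) {
  est <- pgee_fit$coefficients[pgee_fit$penalized]
  est <- est[abs(est) > pgee_fit$zero_cutoff]
  ord <- order(-abs(est), names(est))
  out <- data.frame(feature = names(est)[ord], estimate = unname(est)[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("feature_ranking", "data.frame"),
            endpoint = pgee_fit$endpoint)
}

fold_metric <- function(y, pred, family) {
  if (family == "gaussian") {
    sqrt(mean((y - pred)^2))
  } else {
    mann_whitney_auc(pred[y == 1], pred[y == 0])
  }
}

#' Choose the number of top features by subject-level cross-validation
#'
#' Per fold: a penalized GEE is fit on the training subjects and its
#' feature ranking extracted; then for each candidate count `k`, an
#' unpenalized GEE on the top-`k` features (plus covariates) is fit on
#' the training subjects and scored on the held-out subjects - RMSE for
#' the continuous progression endpoint, AUC for the binary classification
#' endpoint. The chosen `P` optimizes the mean curve (smallest RMSE or
#' largest AUC), with ties broken toward the smaller count. Folds are
#' split by subject and stratified by group, so no subject contributes to
#' both training and testing in any fold. The top-`k` refits use
#' `lambda = 0` so the metric reflects the feature set rather than
#' shrinkage.
#'
#' @inheritParams pgee_select
#' @param candidate_features candidate feature columns.
#' @param k_max largest feature count considered (truncated with a
#'   warning if it exceeds the number of ranked features in every fold).
#' @param n_folds number of subject-level folds.
#' @param seed RNG seed controlling folds (and lambda tuning if needed).
#' @return an object of class `cv_curve`: list with `folds` (per-fold
#'   per-k metric), `mean_curve`, `chosen_p`, `endpoint`, `metric`.
#' @export
choose_feature_count <- function(data, candidate_features,
                                 endpoint = c("progression", "classification"),
                                 covariates = "age", k_max = 20, n_folds = 10,
                                 seed = 1, lambda = NULL, lambda_grid = NULL,
                                 ...) {
  endpoint <- match.arg(endpoint)
  if (n_folds < 2) digicomp_error("n_folds must be >= 2", "digicomp_config_error")
  ep <- endpoint_data(data, endpoint)
  dat <- ep$data
  if (k_max > length(candidate_features)) {
    warning(sprintf("k_max truncated from %d to %d available features",
                    k_max, length(candidate_features)))
    k_max <- length(candidate_features)
  }
  if (is.null(lambda)) {
    des_all <- build_design(dat, candidate_features, covariates)
    lambda <- as.numeric(tune_lambda(des_all$X, ep$y, dat$subject_id,
                                     family = ep$family, corstr = ep$corstr,
                                     penalized = des_all$penalized,
                                     lambda_grid = lambda_grid, seed = seed))
  }
  fold <- make_subject_folds(dat, n_folds, seed)
  lv <- covariate_levels(dat, covariates)
  metric_name <- if (endpoint == "progression") "rmse" else "auc"
  res <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold[dat$subject_id] == k
    stopifnot(!any(unique(dat$subject_id[test]) %in% unique(dat$subject_id[!test])))
    if (!any(test) || all(test)) next
    train <- dat[!test, , drop = FALSE]
    des <- build_design(train, candidate_features, covariates, lv)
    pfit <- tryCatch(
      fit_pgee(des$X, ep$y[!test], train$subject_id, family = ep$family,
               corstr = ep$corstr, lambda = lambda,
               penalized = des$penalized, ...),
      error = function(e) NULL)
    if (is.null(pfit)) next
    pfit$endpoint <- endpoint
    rk <- rank_features(pfit)
    if (!nrow(rk)) next
    ks <- seq_len(min(k_max, nrow(rk)))
    vals <- rep(NA_real_, k_max)
    for (kk in ks) {
      feats <- rk$feature[seq_len(kk)]
      dtr <- build_design(train, feats, covariates, lv)
      dte <- build_design(dat[test, , drop = FALSE], feats, covariates, lv)
      gfit <- tryCatch(
        fit_gee(dtr$X, ep$y[!test], train$subject_id, family = ep$family,
                corstr = ep$corstr),
        error = function(e) NULL)
      if (is.null(gfit)) next
      pred <- predict(gfit, dte$X)
      vals[kk] <- fold_metric(ep$y[test], pred, ep$family)
    }
    res[[k]] <- data.frame(fold = k, k = seq_len(k_max), metric = vals)
  }
  folds_df <- do.call(rbind, res)
  if (is.null(folds_df) || all(is.na(folds_df$metric))) {
    digicomp_error("cross-validation produced no usable folds",
                   "digicomp_model_error")
  }
  # only k values scored in every contributing fold are comparable:
  # averaging a large k over the lone folds that ranked that many
  # features is an apples-to-oranges comparison
  n_used <- length(unique(folds_df$fold))
  n_by_k <- tapply(is.finite(folds_df$metric), folds_df$k, sum)
  mean_curve <- tapply(folds_df$metric, folds_df$k, mean, na.rm = TRUE)
  mean_curve <- data.frame(k = as.integer(names(mean_curve)),
                           metric = as.numeric(mean_curve))
  ok <- is.finite(mean_curve$metric) & (as.integer(n_by_k) == n_used)
  if (!any(ok)) ok <- is.finite(mean_curve$metric)
  mean_curve$comparable <- ok
  opt <- if (endpoint == "progression") {
    min(mean_curve$metric[ok])
  } else {
    max(mean_curve$metric[ok])
  }
  cand <- mean_curve$k[ok & abs(mean_curve$metric - opt) < 1e-12]
  chosen <- min(cand)
  structure(list(folds = folds_df, mean_curve = mean_curve,
                 chosen_p = chosen, endpoint = endpoint,
                 metric = metric_name, lambda = lambda, seed = seed),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("Feature-count CV (%s endpoint, %s): chosen P = %d\n",
              x$endpoint, x$metric, x$chosen_p))
  print(x$mean_curve)
  invisible(x)
}

#' Merge progression and classification feature sets
#'
#' Union of the two name lists, preserving first occurrence order
#' (progression features first); duplicates count once.
#'
#' @param progression_set,classification_set character vectors of feature
#'   names.
#' @return character vector of unique feature names.
#' @export
merge_feature_sets <- function(progression_set, classification_set) {
  out <- unique(c(progression_set, classification_set))
  if (!length(out)) {
    digicomp_error("merged feature set is empty; no composite possible",
                   "digicomp_empty_panel_error")
  }
  out
}
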