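# Composite digital measure construction and evaluation.
#
# The composite is a gaussian GEE of the clinical anchor score on the
# standardized final feature set plus covariates (exchangeable working
# correlation); its linear predictor is the composite score for a
# subject-visit row. Evaluation covers longitudinal progression (the
# screening LMM refit with the composite as response), effect sizes on
# subject-level slopes, between/within-subject coefficients of
# variation, and de novo PD vs HC classification.

#' Fit the final composite digital measure
#'
#' @param data longitudinal dataset containing the clinical score, the
#'   final features, and the covariates.
#' @param final_features merged final feature set.
#' @param covariates adjustment covariates included in the model.
#' @param corstr working correlation of the GEE.
#' @return an object of class `composite_model`: GEE coefficients on the
#'   training standardization scale plus the per-feature mean/SD needed
#'   to score new rows.
#' @export
fit_composite <- function(data, final_features, covariates = "age",
                          corstr = "exchangeable") {
  missing_f <- setdiff(final_features, names(data))
  if (length(missing_f)) {
    digicomp_error(paste0("final features not present in data: ",
                          paste(missing_f, collapse = ", ")),
                   "digicomp_input_error")
  }
  ctr <- vapply(final_features, function(f) mean(data[[f]]), numeric(1))
  scl <- vapply(final_features, function(f) stats::sd(data[[f]]), numeric(1))
  if (any(!is.finite(scl)) || any(scl == 0)) {
    digicomp_error(paste0("zero-variance final feature(s): ",
                          paste(final_features[scl == 0], collapse = ", ")),
                   "digicomp_model_error")
  }
  std <- data
  for (f in final_features) std[[f]] <- (std[[f]] - ctr[[f]]) / scl[[f]]
  lv <- covariate_levels(data, covariates)
  des <- build_design(std, final_features, covariates, lv)
  fit <- fit_gee(des$X, std$clinical_score, std$subject_id,
                 family = "gaussian", corstr = corstr)
  structure(list(
    features = final_features, covariates = covariates,
    factor_levels = lv,
    coefficients = fit$coefficients, robust_cov = fit$robust_cov,
    feature_center = ctr, feature_scale = scl,
    corstr = fit$corstr, alpha = fit$alpha,
    converged = fit$converged
  ), class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("Composite digital measure: %d features + covariates (%s)\n",
              length(x$features), paste(x$covariates, collapse = ", ")))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score subject-visit rows with a composite model
#'
#' Returns the model's linear predictor with the stored training
#' standardization applied to the features. With
#' `include_covariates = FALSE`, covariate terms are dropped (the
#' intercept is kept), giving a covariate-free composite.
#'
#' @param model a `composite_model`.
#' @param rows data.frame containing the model's features (and covariates
#'   unless excluded).
#' @param include_covariates include covariate terms in the score.
#' @return numeric vector of composite scores, one per row.
#' @export
score_composite <- function(model, rows, include_covariates = TRUE) {
  missing_f <- setdiff(model$features, names(rows))
  if (length(missing_f)) {
    digicomp_error(paste0("rows are missing model features: ",
                          paste(missing_f, collapse = ", ")),
                   "digicomp_input_error")
  }
  if (any(model$feature_scale == 0)) {
    digicomp_error("stored feature scale of 0; model cannot score",
                   "digicomp_model_error")
  }
  std <- rows
  for (f in model$features) {
    std[[f]] <- (std[[f]] - model$feature_center[[f]]) / model$feature_scale[[f]]
  }
  covs <- if (include_covariates) model$covariates else character(0)
  des <- build_design(std, model$features, covs, model$factor_levels)
  beta <- model$coefficients[colnames(des$X)]
  if (anyNA(beta)) {
    digicomp_error("rows lack columns required by the model",
                   "digicomp_input_error")
  }
  drop(des$X %*% beta)
}

#' Cross-validated composite scores
#'
#' Each subject's composite scores are produced by the model trained
#' without that subject (subject-level folds, stratified by group). The
#' per-group root mean squared error of the held-out scores against the
#' clinical score is attached as attribute `"rmse_by_group"`.
#'
#' @inheritParams fit_composite
#' @param n_folds number of subject-level folds (default 10).
#' @param seed RNG seed for the folds.
#' @return `data` with added columns `composite` (held-out score) and
#'   `fold`.
#' @export
crossvalidated_scores <- function(data, final_features, covariates = "age",
                                  n_folds = 10, seed = 1,
                                  corstr = "exchangeable") {
  fold <- make_subject_folds(data, n_folds, seed)
  out <- data
  out$composite <- NA_real_
  out$fold <- unname(fold[data$subject_id])
  for (k in sort(unique(out$fold))) {
    test <- out$fold == k
    train <- data[!test, , drop = FALSE]
    if (length(unique(train$group)) < length(unique(data$group))) {
      warning(sprintf("fold %d training set is missing a group; proceeding", k))
    }
    model <- fit_composite(train, final_features, covariates, corstr)
    out$composite[test] <- score_composite(model, data[test, , drop = FALSE])
  }
  rmse <- function(i) sqrt(mean((out$clinical_score[i] - out$composite[i])^2))
  groups <- unique(out$group)
  by_group <- vapply(groups, function(g) rmse(out$group == g), numeric(1))
  names(by_group) <- groups
  pd <- out$group != "hc"
  attr(out, "rmse_by_group") <- by_group
  attr(out, "rmse_overall") <- rmse(rep(TRUE, nrow(out)))
  attr(out, "rmse_pd") <- if (any(pd)) rmse(pd) else NA_real_
  out
}

#' Progression evaluation of the composite measure
#'
#' Refits the univariate screening LMM with the composite score as the
#' response (covariate-adjusted) and extracts the omnibus group-by-visit
#' p-value, the HC slope p-value, and the per-PD-group differential
#' slope p-values.
#'
#' @param scored dataset with a `composite` column (e.g. from
#'   [crossvalidated_scores()]).
#' @param covariates adjustment covariates for the evaluation LMM.
#' @return list with `group_by_visit_p`, `hc_slope_p`, `diff_slope_p`
#'   (named per PD group), `group_slopes`, and the underlying `lmm_fit`.
#' @export
evaluate_progression <- function(scored, covariates = "age") {
  fit <- fit_progression_lmm(scored, "composite", covariates)
  list(group_by_visit_p = fit$omnibus_interaction_p,
       hc_slope_p = unname(fit$hc_slope[["p"]]),
       diff_slope_p = vapply(fit$diff_slopes, function(x) x[["p"]], numeric(1)),
       group_slopes = fit$group_slopes,
       fit = fit)
}

#' Effect size of the progression slope between a PD group and HC
#'
#' Cohen's d on subject-level ordinary-least-squares slopes of the score
#' on visit time: `d = (mean slope in pd_group - mean slope in HC) /
#' pooled SD`, with a 95% CI from the standard normal approximation
#' `d +/- 1.96 * SE(d)`. Subjects with fewer than two visits are excluded
#' with a warning.
#'
#' @param scored dataset with the score column.
#' @param pd_group disease group to compare against HC.
#' @param hc_group reference group label.
#' @param score_col column holding the score.
#' @return named vector `c(d, ci_low, ci_high)`.
#' @export
effect_size_slope <- function(scored, pd_group, hc_group = "hc",
                              score_col = "composite") {
  subject_slopes <- function(g) {
    sub <- scored[scored$group == g, , drop = FALSE]
    sl <- vapply(split(sub, sub$subject_id), function(d) {
      if (length(unique(d$visit_time)) < 2) return(NA_real_)
      stats::coef(stats::lm(d[[score_col]] ~ d$visit_time))[2]
    }, numeric(1))
    if (anyNA(sl)) {
      warning("subject(s) with < 2 visits excluded from effect size")
      sl <- sl[!is.na(sl)]
    }
    sl
  }
  s1 <- subject_slopes(pd_group)
  s0 <- subject_slopes(hc_group)
  n1 <- length(s1); n0 <- length(s0)
  sp <- sqrt(((n1 - 1) * stats::var(s1) + (n0 - 1) * stats::var(s0)) /
               (n1 + n0 - 2))
  d <- (mean(s1) - mean(s0)) / sp
  se <- sqrt((n1 + n0) / (n1 * n0) + d^2 / (2 * (n1 + n0 - 2)))
  c(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se)
}

#' Between- and within-subject coefficients of variation
#'
#' One-way random-effects decomposition of the score by subject
#' (ANOVA method of moments): `between_cov = sqrt(sigma2_between) / grand
#' mean`, `within_cov = sqrt(sigma2_within) / grand mean`. The grand mean
#' must be positive; scores are never re-centered silently.
#'
#' @inheritParams effect_size_slope
#' @return named vector `c(between_cov, within_cov)`.
#' @export
coefficient_of_variation <- function(scored, score_col = "composite") {
  y <- scored[[score_col]]
  gm <- mean(y)
  if (gm <= 0) {
    digicomp_error(
      "grand mean of the score is not positive; shift the score to a positive scale before computing CoVs",
      "digicomp_model_error")
  }
  subj <- factor(scored$subject_id)
  fit <- stats::aov(y ~ subj)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  ni <- table(subj)
  N <- sum(ni)
  a <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2w <- msw
  s2b <- max(0, (msb - msw) / n0)
  c(between_cov = sqrt(s2b) / gm, within_cov = sqrt(s2w) / gm)
}

# Mann-Whitney AUC: probability a positive score exceeds a negative one,
# ties counting one half.
mann_whitney_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classify disease vs control from composite scores
#'
#' AUC by the Mann-Whitney formulation over pooled subject-visit scores;
#' the decision threshold maximizes the Youden index J = sensitivity +
#' specificity - 1 over observed score values (a row is called positive
#' when its score is at or above the threshold), with ties broken toward
#' the lower threshold. Confusion counts are reported at that threshold.
#'
#' @inheritParams effect_size_slope
#' @param positive_group,negative_group group labels to classify.
#' @return list with `auc`, `threshold`, `confusion` (tp/fp/tn/fn),
#'   `misclassified`.
#' @export
classify_groups <- function(scored, positive_group = "de_novo_pd",
                            negative_group = "hc", score_col = "composite") {
  pos <- scored[[score_col]][scored$group == positive_group]
  neg <- scored[[score_col]][scored$group == negative_group]
  if (!length(pos) || !length(neg)) {
    digicomp_error("both classification groups must be present",
                   "digicomp_input_error")
  }
  auc <- mann_whitney_auc(pos, neg)
  cand <- sort(unique(c(pos, neg)))
  j <- vapply(cand, function(th) {
    mean(pos >= th) + mean(neg < th) - 1
  }, numeric(1))
  th <- cand[which(j >= max(j) - 1e-12)[1]]
  tp <- sum(pos >= th); fn <- sum(pos < th)
  fp <- sum(neg >= th); tn <- sum(neg < th)
  list(auc = auc, threshold = th,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       misclassified = fp + fn)
}

#' Full evaluation report for a composite digital measure
#'
#' Combines the progression block, per-PD-group effect sizes,
#' coefficients of variation, cross-validated RMSEs (if present as
#' attributes on `scored`), and classification performance.
#'
#' @param scored output of [crossvalidated_scores()] (or any dataset with
#'   a `composite` column).
#' @param covariates covariates for the evaluation LMM.
#' @param positive_group,negative_group classification groups.
#' @return an object of class `evaluation_report` (a list).
#' @export
evaluate_composite <- function(scored, covariates = "age",
                               positive_group = "de_novo_pd",
                               negative_group = "hc") {
  prog <- evaluate_progression(scored, covariates)
  pd_groups <- names(prog$diff_slope_p)
  eff <- lapply(pd_groups, function(g) effect_size_slope(scored, g))
  names(eff) <- pd_groups
  cov_ok <- tryCatch(coefficient_of_variation(scored), error = function(e) {
    warning(conditionMessage(e))
    c(between_cov = NA_real_, within_cov = NA_real_)
  })
  cls <- classify_groups(scored, positive_group, negative_group)
  structure(list(
    group_by_visit_p = prog$group_by_visit_p,
    hc_slope_p = prog$hc_slope_p,
    diff_slope_p = prog$diff_slope_p,
    effect_sizes = eff,
    between_cov = unname(cov_ok["between_cov"]),
    within_cov = unname(cov_ok["within_cov"]),
    rmse_by_group = attr(scored, "rmse_by_group"),
    rmse_pd = attr(scored, "rmse_pd"),
    auc = cls$auc, threshold = cls$threshold,
    confusion = cls$confusion, misclassified = cls$misclassified
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Composite digital measure evaluation\n")
  cat(sprintf("  group-by-visit p = %.3g; HC slope p = %.3g\n",
              x$group_by_visit_p, x$hc_slope_p))
  for (g in names(x$diff_slope_p)) {
    e <- x$effect_sizes[[g]]
    cat(sprintf("  %s vs HC: slope p = %.3g, effect size %.2f (%.2f, %.2f)\n",
                g, x$diff_slope_p[[g]], e["d"], e["ci_low"], e["ci_high"]))
  }
  cat(sprintf("  CoV between/within = %.3f / %.3f\n", x$between_cov, x$within_cov))
  if (!is.null(x$rmse_by_group)) {
    cat("  CV RMSE by group:",
        paste(sprintf("%s = %.2f", names(x$rmse_by_group), x$rmse_by_group),
              collapse = ", "), "\n")
  }
  cat(sprintf("  AUC (de novo PD vs HC) = %.3f at threshold %.3f (%d misclassified)\n",
              x$auc, x$threshold, x$misclassified))
  invisible(x)
}
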