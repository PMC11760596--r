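# Linear mixed-effects progression screening and association testing.
#
# Screening model, per digital feature:
#   feature ~ covariates + group + visit + group:visit + covariate:visit
#             + (visit | subject)
# with HC as the reference group, REML estimation, and Wald (normal
# approximation) p-values. Numeric covariates are centered before fitting
# so the visit main effect is the HC slope at average covariate values.
# Visit enters as continuous time in months.
#
# Convergence fallback ladder for the random effects: unstructured
# intercept+slope -> diagonal (uncorrelated) -> intercept only; a model
# that is still singular or non-converged after the ladder is flagged.

#' Screening thresholds
#'
#' A feature passes univariate progression screening when its trend is
#' flat in healthy controls (HC slope p-value above `alpha_hc_flat`) and
#' it progresses in the PD groups (group-by-visit interaction p-value
#' below `alpha_progression`, or some PD-vs-HC differential slope p-value
#' below `alpha_progression`). The defaults (0.05 and 0.1) are the
#' deliberately relaxed criteria the framework recommends for screening;
#' no multiplicity correction is applied at this stage.
#'
#' @param alpha_hc_flat HC flatness level.
#' @param alpha_progression progression level.
#' @return an object of class `screening_thresholds`.
#' @export
screening_thresholds <- function(alpha_hc_flat = 0.05, alpha_progression = 0.1) {
  if (alpha_hc_flat <= 0 || alpha_hc_flat >= 1 ||
      alpha_progression <= 0 || alpha_progression >= 1) {
    digicomp_error("thresholds must be in (0, 1)", "digicomp_config_error")
  }
  structure(list(alpha_hc_flat = alpha_hc_flat,
                 alpha_progression = alpha_progression),
            class = "screening_thresholds")
}

wald_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# Fit an lmer model walking down the random-effects ladder; returns the
# first fit with no convergence warnings and no singularity, else the
# last attempted fit flagged as non-converged.
fit_lmm_ladder <- function(fixed, data,
                           ladder = c("(visit_time | subject_id)",
                                      "(visit_time || subject_id)",
                                      "(1 | subject_id)")) {
  last <- NULL
  for (re in ladder) {
    form <- stats::as.formula(paste(fixed, "+", re))
    warns <- character(0)
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(form, data = data, REML = TRUE),
               error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    if (inherits(fit, "error")) next
    singular <- lme4::isSingular(fit, tol = 1e-4)
    ok <- !length(warns) && !singular
    last <- list(fit = fit, random = re, converged = ok, singular = singular)
    if (ok) return(last)
  }
  if (is.null(last)) {
    digicomp_error("mixed model could not be fitted", "digicomp_model_error")
  }
  last
}

check_longitudinal <- function(data, feature = NULL) {
  need <- c("subject_id", "group", "visit_time")
  if (!all(need %in% names(data))) {
    digicomp_error("data must have subject_id, group and visit_time columns",
                   "digicomp_input_error")
  }
  if (length(unique(data$visit_time)) < 2) {
    digicomp_error("need at least 2 distinct visit times to estimate slopes",
                   "digicomp_model_error")
  }
  nv <- table(data$subject_id)
  if (all(nv < 2)) {
    digicomp_error("every subject has a single visit; slopes are inestimable",
                   "digicomp_model_error")
  }
  if (!is.null(feature) && is.null(data[[feature]])) {
    digicomp_error(sprintf("feature '%s' not found", feature),
                   "digicomp_input_error")
  }
  invisible(NULL)
}

prep_model_frame <- function(data, response, covariates, reference = "hc") {
  df <- data
  levs <- unique(df$group)
  if (reference %in% levs) levs <- c(reference, setdiff(levs, reference))
  df$group <- factor(df$group, levels = levs)
  for (cv in covariates) {
    if (is.null(df[[cv]])) {
      digicomp_error(sprintf("covariate '%s' not found", cv), "digicomp_input_error")
    }
    if (is.numeric(df[[cv]])) df[[cv]] <- df[[cv]] - mean(df[[cv]], na.rm = TRUE)
    else df[[cv]] <- factor(df[[cv]])
  }
  df$.y <- df[[response]]
  df
}

#' Fit the univariate progression screening model for one feature
#'
#' @param data longitudinal dataset with `subject_id`, `group`,
#'   `visit_time` (months) and the feature column; `"hc"` must be present
#'   as (and is used for) the reference group.
#' @param feature feature column name (the model response).
#' @param covariates covariate columns entering as main effects and
#'   covariate-by-visit interactions; numeric covariates are centered.
#' @return an object of class `lmm_fit` with the fixed-effect table
#'   (estimate, SE, Wald z, p), variance components, the omnibus
#'   group-by-visit Wald chi-square p-value, and derived contrasts:
#'   the HC slope and, per PD group, the absolute slope and the
#'   differential slope versus HC.
#' @export
fit_progression_lmm <- function(data, feature, covariates = "age") {
  check_longitudinal(data, feature)
  df <- prep_model_frame(data, feature, covariates)
  cov_main <- paste(covariates, collapse = " + ")
  cov_int <- paste(sprintf("%s:visit_time", covariates), collapse = " + ")
  fixed <- paste(".y ~ group + visit_time + group:visit_time",
                 if (length(covariates)) paste("+", cov_main, "+", cov_int) else "")
  lad <- fit_lmm_ladder(fixed, df)
  fit <- lad$fit

  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  coefs <- data.frame(term = names(fe), estimate = unname(fe), se = unname(se),
                      z = unname(fe / se), p = unname(wald_p(fe, se)),
                      stringsAsFactors = FALSE)

  pd_groups <- setdiff(levels(df$group), "hc")
  int_terms <- paste0("group", pd_groups, ":visit_time")
  int_terms <- int_terms[int_terms %in% names(fe)]

  # omnibus group-by-visit Wald chi-square over all interaction terms
  omnibus_p <- NA_real_
  if (length(int_terms)) {
    b <- fe[int_terms]
    Vb <- V[int_terms, int_terms, drop = FALSE]
    stat <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
    omnibus_p <- stats::pchisq(stat, df = length(int_terms), lower.tail = FALSE)
  }

  hc_slope <- c(estimate = unname(fe["visit_time"]),
                se = unname(se["visit_time"]),
                p = unname(wald_p(fe["visit_time"], se["visit_time"])))

  slope_contrast <- function(term) {
    est <- fe["visit_time"] + fe[term]
    v <- V["visit_time", "visit_time"] + V[term, term] +
      2 * V["visit_time", term]
    c(estimate = unname(est), se = sqrt(v), p = unname(wald_p(est, sqrt(v))))
  }
  group_slopes <- lapply(int_terms, slope_contrast)
  names(group_slopes) <- sub("^group", "", sub(":visit_time$", "", int_terms))
  diff_slopes <- lapply(int_terms, function(term) {
    c(estimate = unname(fe[term]), se = unname(se[term]),
      p = unname(wald_p(fe[term], se[term])))
  })
  names(diff_slopes) <- names(group_slopes)

  vc <- lme4::VarCorr(fit)
  sub_vc <- vc[["subject_id"]]
  var_int <- if (!is.null(sub_vc)) unname(sub_vc["(Intercept)", "(Intercept)"]) else NA_real_
  var_slope <- if (!is.null(sub_vc) && "visit_time" %in% rownames(sub_vc)) {
    unname(sub_vc["visit_time", "visit_time"])
  } else if (!is.null(vc[["subject_id.1"]])) {
    unname(vc[["subject_id.1"]][1, 1])
  } else NA_real_
  cov_is <- if (!is.null(sub_vc) && "visit_time" %in% rownames(sub_vc)) {
    unname(sub_vc["(Intercept)", "visit_time"])
  } else NA_real_

  structure(list(
    feature = feature, coefficients = coefs, vcov = V,
    var_intercept = var_int, var_slope = var_slope,
    cov_intercept_slope = cov_is, sigma2 = stats::sigma(fit)^2,
    logLik = as.numeric(stats::logLik(fit)),
    converged = lad$converged, random_structure = lad$random,
    hc_slope = hc_slope, group_slopes = group_slopes,
    diff_slopes = diff_slopes, omnibus_interaction_p = omnibus_p,
    pd_groups = names(diff_slopes), model = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Progression LMM for feature:", x$feature, "\n")
  cat("  random effects:", x$random_structure,
      if (!x$converged) "(non-converged/singular)" else "", "\n")
  cat(sprintf("  HC slope: %.4g (p = %.3g)\n", x$hc_slope["estimate"],
              x$hc_slope["p"]))
  cat(sprintf("  group-by-visit omnibus p = %.3g\n", x$omnibus_interaction_p))
  invisible(x)
}

#' Apply the screening criteria to a fitted progression model
#'
#' Pure function of the fit's p-values: pass if and only if the HC slope
#' p-value exceeds `alpha_hc_flat` and either the omnibus group-by-visit
#' p-value or the smallest PD-vs-HC differential slope p-value is below
#' `alpha_progression`. A non-converged fit fails automatically.
#'
#' @param fit an `lmm_fit` from [fit_progression_lmm()].
#' @param thresholds a [screening_thresholds()].
#' @return a one-row data.frame: feature, `p_hc_slope`, `p_interaction`,
#'   `p_diff_<group>` columns, `pass`, `failure_reason`.
#' @export
screen_feature <- function(fit, thresholds = screening_thresholds()) {
  p_diff <- vapply(fit$diff_slopes, function(x) x[["p"]], numeric(1))
  out <- data.frame(feature = fit$feature,
                    p_hc_slope = fit$hc_slope[["p"]],
                    p_interaction = fit$omnibus_interaction_p,
                    stringsAsFactors = FALSE)
  for (g in names(p_diff)) out[[paste0("p_diff_", g)]] <- p_diff[[g]]
  if (!fit$converged) {
    out$pass <- FALSE
    out$failure_reason <- "non_convergence"
    return(out)
  }
  hc_flat <- out$p_hc_slope > thresholds$alpha_hc_flat
  progresses <- (is.finite(out$p_interaction) &&
                   out$p_interaction < thresholds$alpha_progression) ||
    (length(p_diff) && min(p_diff) < thresholds$alpha_progression)
  out$pass <- hc_flat && progresses
  out$failure_reason <- if (out$pass) NA_character_
    else if (!hc_flat) "hc_not_flat" else "no_progression"
  out
}

#' Screen a panel of features for longitudinal progression
#'
#' Fits the screening model to every feature and applies the pass
#' criteria. Per-feature fitting errors are logged in the result (as an
#' automatic fail), not fatal.
#'
#' @inheritParams fit_progression_lmm
#' @param features feature columns to screen.
#' @param thresholds a [screening_thresholds()].
#' @return a data.frame with one row per feature (columns as in
#'   [screen_feature()]); see [screening_pvalues_long()] for a tidy
#'   p-value table suitable for heatmaps.
#' @export
screen_panel <- function(data, features = feature_columns(data),
                         covariates = "age",
                         thresholds = screening_thresholds()) {
  if (!length(features)) {
    return(data.frame(feature = character(0), pass = logical(0)))
  }
  rows <- lapply(features, function(f) {
    res <- tryCatch(
      screen_feature(fit_progression_lmm(data, f, covariates), thresholds),
      error = function(e) {
        data.frame(feature = f, p_hc_slope = NA_real_, p_interaction = NA_real_,
                   pass = FALSE,
                   failure_reason = paste0("error: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
    res
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format screening p-value table
#'
#' One row per (feature, statistic) pair, convenient for rendering
#' -log10(p) heatmaps of the screening results.
#'
#' @param results output of [screen_panel()].
#' @return data.frame with columns feature, statistic, p_value, pass.
#' @export
screening_pvalues_long <- function(results) {
  pcols <- grep("^p_", names(results), value = TRUE)
  out <- do.call(rbind, lapply(pcols, function(cl) {
    data.frame(feature = results$feature,
               statistic = sub("^p_", "", cl),
               p_value = results[[cl]],
               pass = results$pass,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Univariate association between the clinical score and one feature
#'
#' Mixed model of the clinical outcome on the feature plus covariates,
#' with a random intercept per subject; returns the feature coefficient's
#' Wald test.
#'
#' @inheritParams fit_progression_lmm
#' @param outcome clinical outcome column.
#' @return list with `estimate`, `se`, `p`, and `converged`.
#' @export
association_test <- function(data, feature, outcome = "clinical_score",
                             covariates = "age") {
  if (is.null(data[[feature]])) {
    digicomp_error(sprintf("feature '%s' not found", feature), "digicomp_input_error")
  }
  if (stats::var(data[[feature]], na.rm = TRUE) == 0) {
    digicomp_error(sprintf("feature '%s' is constant", feature),
                   "digicomp_model_error")
  }
  df <- prep_model_frame(data, outcome, covariates)
  df$.x <- df[[feature]]
  fixed <- paste(".y ~ .x",
                 if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "")
  lad <- fit_lmm_ladder(fixed, df, ladder = "(1 | subject_id)")
  fe <- lme4::fixef(lad$fit)
  # a perfect (zero-residual) fit can make the covariance unavailable;
  # report the coefficient with a degenerate SE rather than failing
  V <- suppressWarnings(tryCatch(as.matrix(stats::vcov(lad$fit)),
                                 error = function(e) NULL))
  se_x <- if (is.null(V) || !is.finite(V[".x", ".x"])) 0 else sqrt(V[".x", ".x"])
  list(estimate = unname(fe[".x"]), se = se_x,
       p = unname(wald_p(fe[".x"], se_x)), converged = lad$converged)
}

#' Select covariates by their interaction with visit time
#'
#' For each candidate covariate, fits the clinical outcome on
#' `covariate + visit + covariate:visit` with random intercept and slope,
#' restricted to the pooled PD subset (all non-reference groups), and
#' selects covariates whose covariate-by-visit interaction p-value is
#' below `alpha` (factor covariates use an omnibus Wald chi-square over
#' their interaction terms).
#'
#' @param data longitudinal dataset.
#' @param candidates candidate covariate columns.
#' @param outcome clinical outcome column.
#' @param alpha selection level.
#' @param reference the control group label excluded from the pooled
#'   disease subset.
#' @return character vector of selected covariates, with the per-candidate
#'   interaction p-values attached as attribute `"p_values"`.
#' @export
select_covariates <- function(data, candidates = c("age", "sex"),
                              outcome = "clinical_score", alpha = 0.05,
                              reference = "hc") {
  if (!length(candidates)) return(character(0))
  pd <- data[data$group != reference, , drop = FALSE]
  if (!nrow(pd)) {
    digicomp_error("pooled disease subset is empty", "digicomp_input_error")
  }
  pvals <- vapply(candidates, function(cv) {
    df <- prep_model_frame(pd, outcome, cv)
    fixed <- sprintf(".y ~ %s + visit_time + %s:visit_time", cv, cv)
    lad <- tryCatch(fit_lmm_ladder(fixed, df), error = function(e) NULL)
    if (is.null(lad)) return(NA_real_)
    fe <- lme4::fixef(lad$fit)
    V <- as.matrix(stats::vcov(lad$fit))
    terms <- grep(":visit_time$|^visit_time:", names(fe), value = TRUE)
    if (!length(terms)) return(NA_real_)
    b <- fe[terms]
    Vb <- V[terms, terms, drop = FALSE]
    stat <- drop(t(b) %*% solve(Vb, b))
    stats::pchisq(stat, df = length(terms), lower.tail = FALSE)
  }, numeric(1))
  sel <- candidates[!is.na(pvals) & pvals < alpha]
  attr(sel, "p_values") <- pvals
  sel
}
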