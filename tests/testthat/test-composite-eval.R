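# Composite construction, scoring, cross-validation, and the evaluation
# battery (progression, effect sizes, CoV, classification).

test_that("a perfect single-feature anchor is fit exactly", {
  d <- generate_cohort(clean_config(n_per_group = 5, n_features = 4, seed = 61))
  d$clinical_score <- d$feat01
  model <- fit_composite(d, c("feat01", "feat02"), covariates = character(0))
  # standardized scale: the feat01 coefficient is its SD, others vanish
  expect_equal(unname(model$coefficients["feat01"]),
               stats::sd(d$feat01), tolerance = 1e-6)
  expect_lt(abs(model$coefficients[["feat02"]]), 1e-6)
  sc <- score_composite(model, d)
  expect_equal(sc, d$clinical_score, tolerance = 1e-6)
})

test_that("collinear final features are rejected with names", {
  d <- generate_cohort(clean_config(n_per_group = 4, n_features = 4, seed = 67))
  d$copy_of_01 <- d$feat01
  expect_error(fit_composite(d, c("feat01", "copy_of_01")), "copy_of_01")
  expect_error(fit_composite(d, c("feat01", "nope")),
               class = "digicomp_input_error")
})

test_that("scoring matches the GEE linear predictor and handles flags", {
  d <- generate_cohort(clean_config(n_per_group = 5, n_features = 4, seed = 71))
  model <- fit_composite(d, c("feat01", "feat03"), covariates = "age")
  # intercept-only model scores a constant
  m0 <- model
  m0$coefficients[] <- 0
  m0$coefficients["(Intercept)"] <- 4.2
  expect_equal(score_composite(m0, d), rep(4.2, nrow(d)))
  # refitting on identical data reproduces coefficients (determinism)
  model2 <- fit_composite(d, c("feat01", "feat03"), covariates = "age")
  expect_identical(model$coefficients, model2$coefficients)
  # covariate-free scoring drops the covariate term only
  s_full <- score_composite(model, d)
  s_nocov <- score_composite(model, d, include_covariates = FALSE)
  expect_equal(s_full - s_nocov,
               model$coefficients[["age"]] * d$age, tolerance = 1e-10)
  expect_error(score_composite(model, d[setdiff(names(d), "feat03")]),
               class = "digicomp_input_error")
})

test_that("affine feature transforms with matching standardization score identically", {
  d <- generate_cohort(clean_config(n_per_group = 5, n_features = 4, seed = 73))
  model <- fit_composite(d, "feat02", covariates = character(0))
  d2 <- d
  d2$feat02 <- 3 * d$feat02 + 7
  model2 <- model
  model2$feature_center["feat02"] <- 3 * model$feature_center["feat02"] + 7
  model2$feature_scale["feat02"] <- 3 * model$feature_scale["feat02"]
  expect_equal(score_composite(model2, d2), score_composite(model, d),
               tolerance = 1e-10)
})

test_that("cross-validated scores are held-out, reproducible, and audited", {
  d <- generate_cohort(clean_config(n_per_group = 5, n_features = 6,
                                    anchor_noise_sd = 3, seed = 79))
  sc1 <- crossvalidated_scores(d, sprintf("feat%02d", 1:5), "age",
                               n_folds = 5, seed = 4)
  sc2 <- crossvalidated_scores(d, sprintf("feat%02d", 1:5), "age",
                               n_folds = 5, seed = 4)
  expect_identical(sc1$composite, sc2$composite)
  expect_false(anyNA(sc1$composite))
  # RMSE recomputed independently from the emitted predictions
  for (g in unique(sc1$group)) {
    i <- sc1$group == g
    expect_equal(unname(attr(sc1, "rmse_by_group")[g]),
                 sqrt(mean((sc1$clinical_score[i] - sc1$composite[i])^2)),
                 tolerance = 1e-10)
  }
  # noiseless anchor driven by a single feature: held-out RMSE ~ 0
  d0 <- generate_cohort(noiseless_config(n_per_group = 5, n_features = 3))
  d0$clinical_score <- d0$feat01
  sc0 <- crossvalidated_scores(d0, "feat01", character(0), n_folds = 5, seed = 1)
  expect_lt(attr(sc0, "rmse_overall"), 1e-6)
})

test_that("effect sizes behave under null, shift and scale", {
  mk <- function(s1, s0) {
    # two visits at t = 0, 1 so the per-subject OLS slope is the difference
    subj <- sprintf("s%02d", seq_along(c(s1, s0)))
    grp <- rep(c("de_novo_pd", "hc"), c(length(s1), length(s0)))
    data.frame(subject_id = rep(subj, each = 2), group = rep(grp, each = 2),
               visit_time = rep(0:1, length(subj)),
               composite = as.vector(rbind(0, c(s1, s0))))
  }
  set.seed(83)
  same <- mk(rnorm(10), rnorm(10))
  e0 <- effect_size_slope(same, "de_novo_pd")
  expect_lt(e0[["ci_low"]], 0)
  expect_gt(e0[["ci_high"]], 0)
  # doubling all scores leaves d unchanged
  doubled <- same
  doubled$composite <- 2 * doubled$composite
  expect_equal(effect_size_slope(doubled, "de_novo_pd")[["d"]], e0[["d"]],
               tolerance = 1e-12)
  # slopes N(1,1) vs N(0,1), n = 10 + 10: the CI covers d = 1 most of the time
  hits <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    e <- effect_size_slope(mk(rnorm(10, 1), rnorm(10, 0)), "de_novo_pd")
    hits <- hits + (e[["ci_low"]] <= 1 && 1 <= e[["ci_high"]])
  }
  expect_gte(hits / n_sim, 0.9)
  # subjects with a single visit are excluded with a warning
  onev <- rbind(same, data.frame(subject_id = "s99", group = "de_novo_pd",
                                 visit_time = 0, composite = 5))
  expect_warning(effect_size_slope(onev, "de_novo_pd"), "excluded")
})

test_that("coefficients of variation match a hand-built ANOVA decomposition", {
  # every subject constant at distinct values: within = 0
  d1 <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                   composite = rep(c(1, 2, 3), each = 3))
  cv1 <- coefficient_of_variation(d1)
  expect_equal(unname(cv1["within_cov"]), 0)
  expect_gt(cv1[["between_cov"]], 0)
  # all subjects identical: both components 0
  d2 <- data.frame(subject_id = rep(c("a", "b"), each = 3), composite = 5)
  expect_equal(unname(coefficient_of_variation(d2)), c(0, 0))
  # 3 subjects x 3 visits: match the one-way ANOVA method of moments
  y <- c(10, 12, 11, 20, 19, 21, 15, 14, 16)
  d3 <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3), composite = y)
  cv3 <- coefficient_of_variation(d3)
  gm <- mean(y)
  sub_means <- tapply(y, d3$subject_id, mean)
  msb <- 3 * sum((sub_means - gm)^2) / 2
  msw <- sum((y - rep(sub_means, each = 3))^2) / 6
  expect_equal(unname(cv3["within_cov"]), sqrt(msw) / gm, tolerance = 1e-12)
  expect_equal(unname(cv3["between_cov"]), sqrt((msb - msw) / 3) / gm,
               tolerance = 1e-12)
  # non-positive grand mean is an error, not a silent re-centering
  d4 <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                   composite = c(-1, -2, -3, -4))
  expect_error(coefficient_of_variation(d4), class = "digicomp_model_error")
})

test_that("AUC matches a brute-force concordant-pair count", {
  sc <- data.frame(
    group = rep(c("de_novo_pd", "hc"), each = 5),
    composite = c(3.1, 2.5, 4.0, 1.2, 2.8, 1.0, 2.5, 0.7, 1.9, 2.2))
  res <- classify_groups(sc)
  pos <- sc$composite[sc$group == "de_novo_pd"]
  neg <- sc$composite[sc$group == "hc"]
  brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(res$auc, brute, tolerance = 1e-12)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = sc$group == "de_novo_pd", predictor = sc$composite,
    quiet = TRUE, direction = "<")))
  expect_equal(res$auc, proc_auc, tolerance = 1e-12)
})

test_that("classification handles separation, null data and transforms", {
  sep <- data.frame(group = rep(c("de_novo_pd", "hc"), each = 20),
                    composite = c(rnorm(20, 10), rnorm(20, 0)))
  res <- classify_groups(sep)
  expect_equal(res$auc, 1)
  expect_equal(res$misclassified, 0)
  # labels independent of scores: AUC near 1/2
  set.seed(89)
  null <- data.frame(group = sample(rep(c("de_novo_pd", "hc"), each = 500)),
                     composite = rnorm(1000))
  expect_lt(abs(classify_groups(null)$auc - 0.5), 0.05)
  # AUC invariant under strictly increasing transforms
  t1 <- classify_groups(sep)
  sep2 <- sep
  sep2$composite <- exp(sep$composite / 3)
  expect_equal(classify_groups(sep2)$auc, t1$auc, tolerance = 1e-12)
  expect_error(classify_groups(sep[sep$group == "hc", ]),
               class = "digicomp_input_error")
})

test_that("the Youden threshold maximizes J with ties toward the lower value", {
  sc <- data.frame(group = rep(c("de_novo_pd", "hc"), each = 3),
                   composite = c(5, 6, 7, 1, 2, 3))
  res <- classify_groups(sc)
  # every threshold in (3, 5] separates perfectly; observed candidates: 5
  expect_equal(res$threshold, 5)
  expect_equal(unname(res$confusion), c(3L, 0L, 3L, 0L))
})

test_that("group-label permutation yields uniform-ish omnibus p-values", {
  d <- generate_cohort(clean_config(n_per_group = 5, n_features = 3, seed = 97))
  d$composite <- d$feat01
  subj <- unique(d[c("subject_id", "group")])
  set.seed(101)
  rej <- 0
  n_perm <- 30
  for (i in seq_len(n_perm)) {
    perm <- setNames(sample(subj$group), subj$subject_id)
    dp <- d
    dp$group <- unname(perm[dp$subject_id])
    p <- tryCatch(
      evaluate_progression(dp, covariates = character(0))$group_by_visit_p,
      error = function(e) NA_real_)
    rej <- rej + isTRUE(p < 0.05)
  }
  expect_lte(rej / n_perm, 0.2)
})

test_that("evaluate_composite assembles a coherent report", {
  d <- generate_cohort(clean_config(n_per_group = 8, n_features = 6,
                                    anchor_noise_sd = 3, seed = 103))
  sc <- crossvalidated_scores(d, sprintf("feat%02d", 1:5), "age",
                              n_folds = 5, seed = 6)
  rep <- evaluate_composite(sc)
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(all(vapply(rep$effect_sizes, function(e)
    e[["ci_low"]] <= e[["d"]] && e[["d"]] <= e[["ci_high"]], logical(1))))
  expect_gte(rep$between_cov, 0)
  expect_gte(rep$within_cov, 0)
  expect_named(rep$diff_slope_p)
  expect_output(print(rep), "AUC")
})
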