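# GEE and penalized GEE: classical oracles, working-correlation moment
# estimators, SCAD arithmetic, penalization behavior, and lambda tuning.

test_that("gaussian independence GEE reproduces ordinary least squares", {
  set.seed(1)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(40 * 4), 40, 4,
                                       dimnames = list(NULL, letters[1:4])))
  y <- drop(X %*% c(1, 2, -1, 0, 0.5)) + rnorm(40)
  id <- rep(1:10, each = 4)
  fit <- fit_gee(X, y, id, "gaussian", "independence")
  ols <- stats::coef(stats::lm(y ~ X - 1))
  expect_lt(max(abs(fit$coefficients - ols)), 1e-8)
})

test_that("size-1-cluster logistic GEE reproduces IRLS logistic regression", {
  set.seed(2)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(120 * 3), 120, 3,
                                       dimnames = list(NULL, letters[1:3])))
  y <- stats::rbinom(120, 1, stats::plogis(drop(X %*% c(-0.3, 1, -1.2, 0.4))))
  fit <- fit_gee(X, y, seq_len(120), "binomial", "independence")
  glm_fit <- stats::glm.fit(X, y, family = stats::binomial())
  expect_lt(max(abs(fit$coefficients - glm_fit$coefficients)), 1e-6)
})

test_that("noiseless responses are recovered exactly", {
  set.seed(3)
  X <- cbind(1, matrix(rnorm(60 * 2), 60, 2))
  beta <- c(2, -1, 0.5)
  fit <- fit_gee(X, drop(X %*% beta), rep(1:15, each = 4),
                 "gaussian", "exchangeable")
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
})

test_that("the fast gaussian path agrees with the generic cluster loop", {
  set.seed(4)
  X <- cbind(`(Intercept)` = 1, matrix(rnorm(200 * 5), 200, 5))
  id <- rep(1:40, each = 5)
  y <- drop(X %*% c(1, 0.5, -0.5, 0, 1, 0)) +
    rep(rnorm(40), each = 5) + rnorm(200)
  for (cs in c("independence", "exchangeable")) {
    fa <- digicomp:::gee_engine(X, y, id, "gaussian", cs, 1e-8, 200,
                                use_fast = TRUE)
    sl <- digicomp:::gee_engine(X, y, id, "gaussian", cs, 1e-8, 200,
                                use_fast = FALSE)
    expect_equal(fa$coefficients, sl$coefficients, tolerance = 1e-10)
    expect_equal(fa$robust_cov, sl$robust_cov, tolerance = 1e-8)
    expect_equal(fa$alpha, sl$alpha, tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with named columns", {
  X <- cbind(`(Intercept)` = 1, a = 1:10, twice_a = 2 * (1:10))
  expect_error(fit_gee(X, rnorm(10), rep(1:5, 2), "gaussian", "independence"),
               "twice_a")
})

test_that("working correlation moment estimators behave as specified", {
  set.seed(5)
  # exactly uncorrelated residuals
  r0 <- lapply(1:300, function(i) rnorm(4))
  expect_lt(abs(estimate_working_correlation(r0, "exchangeable")$alpha), 0.05)
  # exchangeable rho = 0.5, 200 clusters of size 4: within 0.07
  r5 <- lapply(1:200, function(i) {
    f <- rnorm(1)
    sqrt(0.5) * f + sqrt(0.5) * rnorm(4)
  })
  expect_lt(abs(estimate_working_correlation(r5, "exchangeable")$alpha - 0.5), 0.07)
  # a single perfectly correlated cluster is clipped below 0.99
  r1 <- list(rep(2, 6))
  est <- estimate_working_correlation(r1, "exchangeable")
  expect_lt(est$alpha, 0.99 + 1e-12)
  expect_gte(est$alpha, -0.99)
  # ar1 moment estimator recovers a known autocorrelation
  ra <- lapply(1:400, function(i) {
    x <- numeric(6)
    x[1] <- rnorm(1)
    for (t in 2:6) x[t] <- 0.6 * x[t - 1] + rnorm(1, 0, sqrt(1 - 0.36))
    x
  })
  expect_lt(abs(estimate_working_correlation(ra, "ar1")$alpha - 0.6), 0.07)
  # all clusters of size 1: independence with a warning
  expect_warning(
    wc <- estimate_working_correlation(as.list(rnorm(10)), "exchangeable"),
    "independence")
  expect_equal(wc$kind, "independence")
})

test_that("SCAD derivative matches hand arithmetic on all three segments", {
  expect_equal(scad_derivative(0.5, 1), 1)
  expect_equal(scad_derivative(2, 1, 3.7), (3.7 - 2) / 2.7)
  expect_equal(scad_derivative(2, 1, 3.7), 0.6296296, tolerance = 1e-7)
  expect_equal(scad_derivative(5, 1, 3.7), 0)
  # continuity at the segment boundaries
  expect_equal(scad_derivative(1 + 1e-10, 1), 1, tolerance = 1e-6)
  expect_equal(scad_derivative(3.7 - 1e-10, 1), 0, tolerance = 1e-6)
  expect_error(scad_derivative(1, 1, a = 2), class = "digicomp_config_error")
  expect_error(scad_derivative(-1, 1), class = "digicomp_input_error")
})

test_that("lambda = 0 PGEE equals the unpenalized GEE", {
  d <- make_pgee_data(1, n_clusters = 40, n_features = 8)
  pen <- 2:9
  pfit <- fit_pgee(d$X, d$y, d$id, "gaussian", "exchangeable",
                   lambda = 0, penalized = pen)
  Xs <- d$X
  Xs[, pen] <- scale(Xs[, pen])
  gfit <- fit_gee(Xs, d$y, d$id, "gaussian", "exchangeable")
  expect_lt(max(abs(pfit$coefficients - gfit$coefficients)), 1e-6)
  # and raw-scale coefficients reproduce the unstandardized GEE
  graw <- fit_gee(d$X, d$y, d$id, "gaussian", "exchangeable")
  expect_lt(max(abs(pfit$coefficients_raw - graw$coefficients)), 1e-5)
})

test_that("an overwhelming penalty empties the support", {
  d <- make_pgee_data(2, n_clusters = 40, n_features = 8)
  fit <- fit_pgee(d$X, d$y, d$id, "gaussian", "exchangeable",
                  lambda = 50, penalized = 2:9)
  expect_length(fit$support, 0)
})

test_that("GEE coefficients are equivariant under column scaling", {
  set.seed(6)
  X <- cbind(`(Intercept)` = 1, a = rnorm(80), b = rnorm(80))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(80)
  id <- rep(1:20, each = 4)
  f1 <- fit_gee(X, y, id, "gaussian", "exchangeable")
  X2 <- X
  X2[, "b"] <- X[, "b"] * 10
  f2 <- fit_gee(X2, y, id, "gaussian", "exchangeable")
  expect_equal(f2$coefficients[["b"]], f1$coefficients[["b"]] / 10,
               tolerance = 1e-8)
})

test_that("sandwich intervals achieve near-nominal coverage", {
  # heteroscedastic clustered data, independence working correlation
  beta1 <- 0.7
  hits <- 0
  n_sim <- 500
  set.seed(8)
  for (i in seq_len(n_sim)) {
    id <- rep(1:25, each = 3)
    x <- rnorm(75)
    u <- rep(rnorm(25, 0, 0.8), each = 3)
    y <- 1 + beta1 * x + u + rnorm(75, 0, 0.5 + 0.5 * abs(x))
    fit <- fit_gee(cbind(1, x = x), y, id, "gaussian", "independence")
    se <- sqrt(fit$robust_cov["x", "x"])
    hits <- hits + (abs(fit$coefficients[["x"]] - beta1) < 1.96 * se)
  }
  expect_gte(hits / n_sim, 0.90)
  expect_lte(hits / n_sim, 0.98)
})

test_that("a singleton lambda grid is returned as-is", {
  d <- make_pgee_data(3, n_clusters = 20, n_features = 5)
  expect_equal(as.numeric(tune_lambda(d$X, d$y, d$id, "gaussian", "exchangeable",
                                      penalized = 2:6, lambda_grid = 0.3)), 0.3)
})

test_that("pure-noise responses drive lambda to the sparse end of the grid", {
  n_hit <- 0
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    set.seed(400 + s)
    X <- cbind(`(Intercept)` = 1, matrix(rnorm(80 * 10), 80, 10))
    y <- rnorm(80)
    id <- rep(1:20, each = 4)
    grid <- exp(seq(log(0.5), log(0.01), length.out = 8))
    lam <- as.numeric(tune_lambda(X, y, id, "gaussian", "exchangeable",
                                  penalized = 2:11, lambda_grid = grid,
                                  n_folds = 4, seed = s))
    n_hit <- n_hit + (lam %in% grid[1:3])
  }
  expect_gte(n_hit / n_rep, 0.8)
})

test_that("tuned lambda keeps strong signals in the support", {
  n_hit <- 0
  n_rep <- 15
  for (s in seq_len(n_rep)) {
    d <- make_pgee_data(500 + s, n_clusters = 50, n_features = 20, n_signal = 3)
    lam <- as.numeric(tune_lambda(d$X, d$y, d$id, "gaussian", "exchangeable",
                                  penalized = 2:21, n_folds = 4, seed = s))
    fit <- fit_pgee(d$X, d$y, d$id, "gaussian", "exchangeable",
                    lambda = lam, penalized = 2:21)
    n_hit <- n_hit + all(d$true_support %in% fit$support)
  }
  expect_gte(n_hit / n_rep, 0.9)
})

test_that("mean support size is non-increasing in lambda", {
  grid <- exp(seq(log(1), log(0.02), length.out = 6))
  sizes <- matrix(0, 20, length(grid))
  for (s in 1:20) {
    d <- make_pgee_data(600 + s, n_clusters = 40, n_features = 15, n_signal = 3)
    for (li in seq_along(grid)) {
      fit <- fit_pgee(d$X, d$y, d$id, "gaussian", "exchangeable",
                      lambda = grid[li], penalized = 2:16)
      sizes[s, li] <- length(fit$support)
    }
  }
  m <- colMeans(sizes)  # grid is decreasing, so means must be non-decreasing
  expect_true(all(diff(m) >= -0.2))
})
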