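# Generalized estimating equations and SCAD-penalized GEE.
#
# The GEE solver uses Fisher scoring on the estimating function
#   U(beta) = sum_i D_i' V_i^{-1} (y_i - mu_i),
# alternating coefficient updates with moment re-estimation of the
# working correlation, and returns both the naive (model-based) and the
# robust sandwich covariance. The penalized variant augments each Newton
# step with a local quadratic approximation of the SCAD penalty:
#   beta <- beta + [H + n E]^{-1} [U - n E beta],
# E = diag(q_lambda(|beta_j|) / (eps + |beta_j|)) on penalized columns,
# which performs simultaneous estimation and variable selection for
# high-dimensional longitudinal covariates.

# Every design column needs a unique, non-empty name (support sets and
# CV refits subset by name).
ensure_colnames <- function(X) {
  cn <- colnames(X)
  if (is.null(cn)) cn <- rep("", ncol(X))
  blank <- !nzchar(cn)
  cn[blank] <- paste0("x", which(blank))
  colnames(X) <- make.unique(cn)
  X
}

gee_family <- function(family) {
  switch(family,
    gaussian = list(
      linkinv = function(eta) eta,
      variance = function(mu) rep(1, length(mu)),
      mu_eta = function(eta) rep(1, length(eta)),
      initialize = function(y) y,
      estimate_phi = TRUE
    ),
    binomial = list(
      linkinv = function(eta) stats::plogis(eta),
      variance = function(mu) pmax(mu * (1 - mu), 1e-10),
      mu_eta = function(eta) {
        mu <- stats::plogis(eta)
        pmax(mu * (1 - mu), 1e-10)
      },
      initialize = function(y) (y + 0.5) / 2,
      estimate_phi = FALSE
    ),
    digicomp_error(sprintf("unsupported family '%s'", family),
                   "digicomp_config_error")
  )
}

#' Moment estimate of the working correlation
#'
#' Given Pearson residuals grouped by cluster, estimates the exchangeable
#' correlation as the average within-cluster cross-product over the
#' dispersion, or the AR(1) parameter from the lag-1 cross-products.
#' Estimates are clipped to (-0.99, 0.99); exchangeable estimates are
#' additionally kept above `-1/(max cluster size - 1)` so the implied
#' matrix stays positive definite.
#'
#' @param residuals list of per-cluster Pearson residual vectors.
#' @param kind one of `"independence"`, `"exchangeable"`, `"ar1"`.
#' @param n_params number of mean-model parameters, used as a degrees-of-
#'   freedom correction.
#' @return an object of class `working_correlation` with fields `kind`,
#'   `alpha`, and `cluster_sizes`. If all clusters have size 1 and a
#'   correlated structure was requested, independence is returned with a
#'   warning.
#' @export
estimate_working_correlation <- function(residuals,
                                         kind = c("independence",
                                                  "exchangeable", "ar1"),
                                         n_params = 0) {
  kind <- match.arg(kind)
  sizes <- lengths(residuals)
  make <- function(kind, alpha = NA_real_) {
    structure(list(kind = kind, alpha = alpha, cluster_sizes = sizes),
              class = "working_correlation")
  }
  if (kind == "independence") return(make("independence"))
  if (all(sizes == 1)) {
    warning("all clusters have size 1; falling back to independence")
    return(make("independence"))
  }
  r2 <- sum(unlist(residuals)^2)
  N <- sum(sizes)
  phi <- r2 / max(N - n_params, 1)
  if (kind == "exchangeable") {
    num <- sum(vapply(residuals, function(r) (sum(r)^2 - sum(r^2)) / 2, numeric(1)))
    npair <- sum(sizes * (sizes - 1) / 2)
    denom <- max(npair - n_params, 1) * phi
    alpha <- num / denom
    lower <- max(-0.99, -1 / (max(sizes) - 1) + 1e-3)
    alpha <- min(max(alpha, lower), 0.99)
  } else {
    num <- sum(vapply(residuals, function(r) {
      if (length(r) < 2) 0 else sum(r[-length(r)] * r[-1])
    }, numeric(1)))
    nlag <- sum(pmax(sizes - 1, 0))
    alpha <- num / (max(nlag - n_params, 1) * phi)
    alpha <- min(max(alpha, -0.99), 0.99)
  }
  make(kind, alpha)
}

corr_matrix <- function(kind, alpha, n) {
  if (n == 1 || kind == "independence") return(diag(n))
  if (kind == "exchangeable") {
    m <- matrix(alpha, n, n)
    diag(m) <- 1
    m
  } else {
    alpha^abs(outer(seq_len(n), seq_len(n), "-"))
  }
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    digicomp_error(paste0("design matrix is rank deficient; collinear columns: ",
                          paste(bad, collapse = ", ")),
                   "digicomp_model_error")
  }
  invisible(NULL)
}

# Closed-form inverse of the exchangeable correlation matrix,
# R^{-1} = a I + b J, as coefficients (a, b) for cluster size n.
exch_inv_coef <- function(alpha, n) {
  if (n == 1 || is.na(alpha)) return(c(a = 1, b = 0))
  a <- 1 / (1 - alpha)
  b <- -alpha / ((1 - alpha) * (1 + (n - 1) * alpha))
  c(a = a, b = b)
}

# Fast accumulation of H, U and the sandwich meat for the gaussian
# identity-link case with independence/exchangeable correlation, using
# R^{-1} = a I + b J: no per-cluster loops, so high-dimensional penalty
# tuning stays cheap. `pre` caches X'X and within-cluster column sums per
# cluster-size class.
gauss_exch_precompute <- function(X, id) {
  fid <- factor(id, levels = unique(id))
  sizes <- as.integer(table(fid)[levels(fid)])
  S <- rowsum(X, fid, reorder = FALSE)          # n_clusters x p
  classes <- sort(unique(sizes))
  by_class <- lapply(classes, function(n) {
    cl <- which(sizes == n)
    rows <- which(as.integer(fid) %in% cl)
    list(n = n, clusters = cl, rows = rows,
         XtX = crossprod(X[rows, , drop = FALSE]),
         S = S[cl, , drop = FALSE])
  })
  list(fid = fid, sizes = sizes, S = S, by_class = by_class)
}

gauss_exch_accumulate <- function(X, r, pre, alpha, phi) {
  p <- ncol(X)
  H <- matrix(0, p, p)
  U <- numeric(p)
  rs <- rowsum(r, pre$fid, reorder = FALSE)     # per-cluster residual sums
  G <- matrix(0, length(pre$sizes), p)          # per-cluster score rows
  for (cls in pre$by_class) {
    ab <- exch_inv_coef(alpha, cls$n)
    Xr <- crossprod(X[cls$rows, , drop = FALSE], r[cls$rows])
    H <- H + (ab["a"] * cls$XtX + ab["b"] * crossprod(cls$S)) / phi
    U <- U + (ab["a"] * Xr + ab["b"] * crossprod(cls$S, rs[cls$clusters])) / phi
    Xri <- rowsum(X[cls$rows, , drop = FALSE] * r[cls$rows], pre$fid[cls$rows],
                  reorder = FALSE)
    G[cls$clusters, ] <- (ab["a"] * Xri +
                            ab["b"] * cls$S * rs[cls$clusters]) / phi
  }
  list(H = H, U = drop(U), M = crossprod(G))
}

# Core Fisher-scoring loop shared by fit_gee and fit_pgee. `penalty_E`
# is NULL (unpenalized) or a function(beta) returning the diagonal of the
# local-quadratic penalty matrix.
gee_engine <- function(X, y, id, family, corstr, tol, max_iter,
                       penalty_E = NULL, beta0 = NULL, use_fast = TRUE) {
  fam <- gee_family(family)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cl <- split(seq_along(id), factor(id, levels = unique(id)))
  n_clusters <- length(cl)
  p <- ncol(X)
  fast <- use_fast && family == "gaussian" &&
    corstr %in% c("independence", "exchangeable")
  pre <- if (fast) gauss_exch_precompute(X, id) else NULL

  beta <- if (!is.null(beta0)) beta0 else {
    init <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y,
        family = if (family == "gaussian") stats::gaussian() else stats::binomial()
      )$coefficients),
      error = function(e) NULL)
    if (is.null(init) || anyNA(init)) rep(0, p) else init
  }

  alpha <- NA_real_
  phi <- 1
  iter <- 0L
  converged <- FALSE
  first_step <- NA_real_
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    v <- fam$variance(mu)
    pearson <- (y - mu) / sqrt(v)
    if (fam$estimate_phi) {
      phi <- sum(pearson^2) / max(length(y) - p, 1)
      if (phi <= 0 || !is.finite(phi)) phi <- 1e-8
    }
    wc <- suppressWarnings(
      estimate_working_correlation(lapply(cl, function(i) pearson[i]),
                                   corstr, n_params = p))
    alpha <- wc$alpha
    if (fast) {
      acc <- gauss_exch_accumulate(X, y - mu, pre,
                                   if (wc$kind == "independence") NA else alpha,
                                   phi)
      H <- acc$H
      U <- acc$U
    } else {
      Rcache <- list()
      H <- matrix(0, p, p)
      U <- numeric(p)
      for (i in cl) {
        ni <- length(i)
        key <- as.character(ni)
        if (is.null(Rcache[[key]])) {
          Rcache[[key]] <- solve(corr_matrix(wc$kind, alpha, ni))
        }
        Rinv <- Rcache[[key]]
        Ahalf <- sqrt(v[i])
        # V^{-1} = A^{-1/2} R^{-1} A^{-1/2} / phi
        Vinv <- (Rinv / tcrossprod(Ahalf)) / phi
        D <- X[i, , drop = FALSE] * fam$mu_eta(eta[i])
        WD <- Vinv %*% D
        H <- H + crossprod(D, WD)
        U <- U + drop(crossprod(WD, y[i] - mu[i]))
      }
    }
    if (!is.null(penalty_E)) {
      Ediag <- penalty_E(beta)
      delta <- tryCatch(
        solve(H + n_clusters * diag(Ediag, p), U - n_clusters * Ediag * beta),
        error = function(e) NULL)
    } else {
      delta <- tryCatch(solve(H, U), error = function(e) NULL)
    }
    if (is.null(delta)) {
      digicomp_error("singular Fisher information in GEE update",
                     "digicomp_model_error")
    }
    step <- max(abs(delta))
    if (iter == 1L) first_step <- max(step, 1e-8)
    if (!is.finite(step) || (iter > 3L && step > 10 * first_step)) {
      digicomp_error(sprintf(
        "GEE iteration diverged at iteration %d (step %.3g, initial %.3g)",
        iter, step, first_step), "digicomp_divergence_error")
    }
    beta <- beta + delta
    if (step < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  # final quantities at the converged beta
  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  v <- fam$variance(mu)
  pearson <- (y - mu) / sqrt(v)
  if (fam$estimate_phi) phi <- sum(pearson^2) / max(length(y) - p, 1)
  wc <- suppressWarnings(
    estimate_working_correlation(lapply(cl, function(i) pearson[i]),
                                 corstr, n_params = p))
  if (fast) {
    acc <- gauss_exch_accumulate(X, y - mu, pre,
                                 if (wc$kind == "independence") NA else wc$alpha,
                                 phi)
    H <- acc$H
    M <- acc$M
  } else {
    H <- matrix(0, p, p)
    M <- matrix(0, p, p)
    Rcache <- list()
    for (i in cl) {
      ni <- length(i)
      key <- as.character(ni)
      if (is.null(Rcache[[key]])) {
        Rcache[[key]] <- solve(corr_matrix(wc$kind, wc$alpha, ni))
      }
      Ahalf <- sqrt(v[i])
      Vinv <- (Rcache[[key]] / tcrossprod(Ahalf)) / phi
      D <- X[i, , drop = FALSE] * fam$mu_eta(eta[i])
      WD <- Vinv %*% D
      H <- H + crossprod(D, WD)
      g <- drop(crossprod(WD, y[i] - mu[i]))
      M <- M + tcrossprod(g)
    }
  }
  Hinv <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  robust <- Hinv %*% M %*% Hinv
  names(beta) <- colnames(X)
  dimnames(robust) <- dimnames(Hinv) <- list(colnames(X), colnames(X))

  list(coefficients = beta, naive_cov = Hinv, robust_cov = robust,
       family = family, corstr = wc$kind, alpha = wc$alpha, phi = phi,
       iterations = iter, converged = converged,
       n_clusters = n_clusters, cluster_sizes = lengths(cl),
       fitted = mu, linear_predictors = eta)
}

#' Fit a generalized estimating equations model
#'
#' Marginal regression for clustered/longitudinal responses. Solves the
#' GEE score equations by Fisher scoring, re-estimating the working
#' correlation by the method of moments at each iteration, and reports
#' both the naive and the robust (sandwich) covariance.
#'
#' @param X design matrix, including the intercept column.
#' @param y response vector (numeric; 0/1 for `family = "binomial"`).
#' @param id cluster (subject) identifier, one per row of `X`.
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit).
#' @param corstr working correlation: `"independence"`, `"exchangeable"`,
#'   or `"ar1"`.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   update.
#' @param max_iter iteration cap; a fit stopping at the cap is returned
#'   with `converged = FALSE`.
#' @return an object of class `gee_fit`.
#' @export
fit_gee <- function(X, y, id, family = c("gaussian", "binomial"),
                    corstr = c("independence", "exchangeable", "ar1"),
                    tol = 1e-8, max_iter = 200) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  X <- ensure_colnames(as.matrix(X))
  check_full_rank(X)
  if (length(y) != nrow(X) || length(id) != nrow(X)) {
    digicomp_error("X, y and id must have matching lengths", "digicomp_input_error")
  }
  out <- gee_engine(X, y, id, family, corstr, tol, max_iter)
  structure(out, class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s, %s working correlation", x$family, x$corstr))
  if (!is.na(x$alpha)) cat(sprintf(", alpha = %.3f", x$alpha))
  cat(sprintf("), %d clusters, %d iterations%s\n", x$n_clusters, x$iterations,
              if (x$converged) "" else " [not converged]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a GEE or penalized GEE fit
#'
#' @param object a `gee_fit` or `pgee_fit`.
#' @param newX design matrix matching the fit's columns (raw scale for
#'   `pgee_fit`; standardization is applied internally).
#' @param type `"response"` (mean scale) or `"link"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gee_fit <- function(object, newX, type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(as.matrix(newX) %*% object$coefficients)
  if (type == "link") eta else gee_family(object$family)$linkinv(eta)
}

#' SCAD penalty derivative
#'
#' The three-segment derivative of the smoothly clipped absolute
#' deviation penalty: `lambda` for magnitudes up to `lambda`, the linear
#' taper `max(a * lambda - theta, 0) / (a - 1)` beyond, reaching zero at
#' `a * lambda`. Continuous in `theta`; nearly unbiased for large
#' coefficients while sparse at zero.
#'
#' @param theta coefficient magnitude(s), >= 0.
#' @param lambda penalty level, >= 0.
#' @param a shape parameter, > 2 (conventional default 3.7).
#' @return vector of derivative values, same length as `theta`.
#' @export
scad_derivative <- function(theta, lambda, a = 3.7) {
  if (a <= 2) digicomp_error("SCAD shape parameter a must be > 2",
                             "digicomp_config_error")
  if (any(theta < 0) || lambda < 0) {
    digicomp_error("theta and lambda must be non-negative", "digicomp_input_error")
  }
  ifelse(theta <= lambda, lambda, pmax(a * lambda - theta, 0) / (a - 1))
}

#' Fit a SCAD-penalized GEE
#'
#' Adds a SCAD penalty to the GEE estimating function and solves it by a
#' local quadratic approximation: each Fisher-scoring step becomes
#' `beta <- beta + [H + n E]^{-1} [U - n E beta]` with
#' `E = diag(q_lambda(|beta_j|) / (eps_ridge + |beta_j|))` on penalized
#' columns and zero elsewhere, re-estimating the working correlation each
#' sweep. Penalized columns are standardized internally (training
#' mean/SD) and coefficients are reported on both scales; the support is
#' the set of penalized columns whose standardized coefficient magnitude
#' exceeds `zero_cutoff`.
#'
#' @inheritParams fit_gee
#' @param lambda penalty level (>= 0); `lambda = 0` reproduces the
#'   unpenalized GEE fit.
#' @param a SCAD shape parameter.
#' @param penalized index (integer or logical) of the penalized columns
#'   of `X`; the intercept and covariates must be excluded.
#' @param eps_ridge denominator stabilizer of the local quadratic
#'   approximation.
#' @param zero_cutoff standardized-scale magnitude below which a
#'   penalized coefficient is reported as zero.
#' @param standardize standardize penalized columns internally (default).
#' @return an object of class `pgee_fit` (inherits `gee_fit`), with
#'   standardized-scale coefficients in `$coefficients`, raw-scale
#'   coefficients in `$coefficients_raw`, and the selected support in
#'   `$support`.
#' @export
fit_pgee <- function(X, y, id, family = c("gaussian", "binomial"),
                     corstr = c("independence", "exchangeable", "ar1"),
                     lambda, a = 3.7, penalized,
                     eps_ridge = 1e-6, zero_cutoff = 1e-3,
                     tol = 1e-6, max_iter = 200, standardize = TRUE) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  if (lambda < 0) digicomp_error("lambda must be >= 0", "digicomp_config_error")
  if (a <= 2) digicomp_error("SCAD shape parameter a must be > 2",
                             "digicomp_config_error")
  X <- ensure_colnames(as.matrix(X))
  p <- ncol(X)
  pen <- logical(p)
  pen[penalized] <- TRUE

  ctr <- rep(0, p)
  scl <- rep(1, p)
  Xs <- X
  if (standardize) {
    for (j in which(pen)) {
      ctr[j] <- mean(X[, j])
      scl[j] <- stats::sd(X[, j])
      if (!is.finite(scl[j]) || scl[j] == 0) {
        digicomp_error(sprintf("penalized column '%s' has zero variance",
                               colnames(X)[j]), "digicomp_model_error")
      }
      Xs[, j] <- (X[, j] - ctr[j]) / scl[j]
    }
  }

  # ridge initializer: keeps penalized coefficients away from exact zero so
  # the local quadratic approximation can move them
  beta0 <- pgee_init(Xs, y, family)

  penalty_E <- function(beta) {
    th <- abs(beta)
    E <- numeric(p)
    E[pen] <- scad_derivative(th[pen], lambda, a) / (eps_ridge + th[pen])
    E
  }
  out <- gee_engine(Xs, y, id, family, corstr, tol, max_iter,
                    penalty_E = penalty_E, beta0 = beta0)

  beta_std <- out$coefficients
  beta_raw <- beta_std / scl
  icpt <- which(!pen & apply(X, 2, function(cc) all(cc == cc[1])))
  if (length(icpt)) {
    beta_raw[icpt[1]] <- beta_raw[icpt[1]] -
      sum((beta_std * ctr / scl)[pen]) / X[1, icpt[1]]
  }
  support <- colnames(X)[pen & abs(beta_std) > zero_cutoff]

  out$coefficients_raw <- beta_raw
  out$lambda <- lambda
  out$a <- a
  out$eps_ridge <- eps_ridge
  out$zero_cutoff <- zero_cutoff
  out$penalized <- colnames(X)[pen]
  out$support <- support
  out$center <- ctr
  out$scale <- scl
  class(out) <- c("pgee_fit", "gee_fit")
  out
}

pgee_init <- function(Xs, y, family) {
  p <- ncol(Xs)
  if (family == "gaussian") {
    drop(solve(crossprod(Xs) + 0.1 * diag(p), crossprod(Xs, y)))
  } else {
    beta <- rep(0, p)
    for (k in 1:8) {
      eta <- drop(Xs %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (y - mu) / w
      beta <- drop(solve(crossprod(Xs, Xs * w) + 0.1 * diag(p),
                         crossprod(Xs, w * z)))
    }
    beta
  }
}

#' @export
print.pgee_fit <- function(x, ...) {
  cat(sprintf("Penalized GEE (SCAD, lambda = %.4g, a = %.2f), %s/%s\n",
              x$lambda, x$a, x$family, x$corstr))
  cat(sprintf("  %d penalized columns, support size %d%s\n",
              length(x$penalized), length(x$support),
              if (x$converged) "" else " [not converged]"))
  if (length(x$support)) {
    est <- x$coefficients[x$support]
    print(round(est[order(-abs(est))], 4))
  }
  invisible(x)
}

#' Predict from a penalized GEE fit
#'
#' @inheritParams predict.gee_fit
#' @export
predict.pgee_fit <- function(object, newX, type = c("response", "link"), ...) {
  type <- match.arg(type)
  newX <- as.matrix(newX)
  Xs <- sweep(sweep(newX, 2, object$center, "-"), 2, object$scale, "/")
  eta <- drop(Xs %*% object$coefficients)
  if (type == "link") eta else gee_family(object$family)$linkinv(eta)
}

#' Serialize a GEE or penalized-GEE fit to JSON
#'
#' Writes the coefficients, working-correlation estimate, convergence
#' record and (for penalized fits) the penalty settings and support.
#'
#' @param fit a `gee_fit` or `pgee_fit`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(family = fit$family, corstr = fit$corstr, alpha = fit$alpha,
              phi = fit$phi, iterations = fit$iterations,
              converged = fit$converged, n_clusters = fit$n_clusters,
              coefficients = as.list(fit$coefficients))
  if (inherits(fit, "pgee_fit")) {
    out$lambda <- fit$lambda
    out$a <- fit$a
    out$zero_cutoff <- fit$zero_cutoff
    out$support <- fit$support
    out$coefficients_raw <- as.list(fit$coefficients_raw)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Default penalty grid for [tune_lambda()]
#'
#' Log-spaced grid from the largest marginal score
#' `max_j |x_j' (y - mean(y))| / n` down to 2% of it.
#'
#' @inheritParams fit_pgee
#' @param length_out number of grid points.
#' @return decreasing numeric vector of lambda values.
#' @export
default_lambda_grid <- function(X, y, penalized, length_out = 15) {
  X <- as.matrix(X)
  pen <- logical(ncol(X))
  pen[penalized] <- TRUE
  Xs <- scale(X[, pen, drop = FALSE])
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(Xs, yc))) / nrow(X)
  lmax <- max(lmax, 1e-4)
  exp(seq(log(lmax), log(lmax * 0.02), length.out = length_out))
}

#' Choose the SCAD penalty level by cluster-level cross-validation
#'
#' Folds partition clusters (never rows), so held-out prediction is for
#' unseen subjects. Each candidate penalty is scored by the features it
#' selects, not by its shrunken coefficients: the penalized fit on the
#' training clusters determines the support, an unpenalized GEE is refit
#' on that support, and the refit predicts the held-out clusters. (SCAD
#' estimates in the penalty range that zeroes noise features are
#' taper-biased, so scoring the shrunken fit would systematically favor
#' under-penalization.) The loss is the mean squared error for the
#' gaussian family and the binomial deviance for the binomial family.
#' Under
#' `rule = "1se"` (the default) the selected penalty is the largest one
#' whose mean loss is within one standard error of the minimizer - the
#' standard parsimony rule for penalized cross-validation, which breaks
#' the near-ties that plain loss minimization resolves haphazardly;
#' `rule = "min"` takes the strict minimizer (exact ties toward the
#' larger penalty).
#'
#' @inheritParams fit_pgee
#' @param lambda_grid candidate penalty levels; default
#'   [default_lambda_grid()].
#' @param n_folds number of cluster-level folds.
#' @param seed RNG seed for the fold assignment.
#' @param rule `"1se"` or `"min"` (see Details).
#' @return the selected lambda, with the per-lambda mean loss curve
#'   attached as attribute `"curve"`.
#' @export
tune_lambda <- function(X, y, id, family = c("gaussian", "binomial"),
                        corstr = c("independence", "exchangeable", "ar1"),
                        penalized, lambda_grid = NULL, n_folds = 5,
                        seed = 1, rule = c("1se", "min"), ...) {
  rule <- match.arg(rule)
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  X <- ensure_colnames(as.matrix(X))
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y, penalized)
  if (!length(lambda_grid)) {
    digicomp_error("lambda_grid must be non-empty", "digicomp_config_error")
  }
  if (length(lambda_grid) == 1) {
    return(structure(lambda_grid, curve = NULL))
  }
  ids <- unique(id)
  fold <- local_seed(seed, {
    rep_len(seq_len(n_folds), length(ids))[sample.int(length(ids))]
  })
  names(fold) <- ids
  loss <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (k in seq_len(n_folds)) {
    test <- id %in% ids[fold == k]
    if (!any(test) || all(test)) next
    for (li in seq_along(lambda_grid)) {
      fit <- tryCatch(
        fit_pgee(X[!test, , drop = FALSE], y[!test], id[!test],
                 family = family, corstr = corstr,
                 lambda = lambda_grid[li], penalized = penalized, ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      keep <- union(setdiff(colnames(X), fit$penalized), fit$support)
      refit <- tryCatch(
        fit_gee(X[!test, keep, drop = FALSE], y[!test], id[!test],
                family = family, corstr = corstr),
        error = function(e) NULL)
      if (is.null(refit)) next
      mu <- predict(refit, X[test, keep, drop = FALSE])
      loss[k, li] <- if (family == "gaussian") {
        mean((y[test] - mu)^2)
      } else {
        mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
        -2 * mean(y[test] * log(mu) + (1 - y[test]) * log(1 - mu))
      }
    }
  }
  mean_loss <- colMeans(loss, na.rm = TRUE)
  if (all(!is.finite(mean_loss))) {
    digicomp_error("no lambda produced a valid cross-validated fit",
                   "digicomp_model_error")
  }
  best_i <- which.min(replace(mean_loss, !is.finite(mean_loss), Inf))
  margin <- if (rule == "1se") {
    se <- stats::sd(loss[, best_i], na.rm = TRUE) /
      sqrt(sum(is.finite(loss[, best_i])))
    if (is.finite(se)) se else 0
  } else {
    1e-12
  }
  cand <- which(is.finite(mean_loss) & mean_loss <= mean_loss[best_i] + margin)
  sel <- lambda_grid[cand[which.max(lambda_grid[cand])]]
  structure(sel, curve = data.frame(lambda = lambda_grid, loss = mean_loss))
}
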