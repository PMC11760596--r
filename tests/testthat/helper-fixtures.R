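# Shared fixtures, built in code at test time.

# A quiet cohort configuration with no skewed features, no missingness and
# no outliers: convenient for model-recovery tests.
clean_config <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(skewed_feature_index = integer(0), missing_rate = 0,
         outlier_rate = 0, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# Fully deterministic configuration: every noise source switched off, so
# each feature is exactly linear in visit time within subject.
noiseless_config <- function(..., seed = 1) {
  args <- utils::modifyList(
    list(random_intercept_sd = 0, random_slope_sd = 0, residual_sd = 0,
         anchor_noise_sd = 0, seed = seed),
    list(...))
  do.call(clean_config, args)
}

# Clustered gaussian regression data with exchangeable errors and a sparse
# true coefficient vector; the standard PGEE test bed.
make_pgee_data <- function(seed, n_clusters = 100, cluster_size = 4,
                           n_features = 50, n_signal = 5, beta_signal = 0.8,
                           rho = 0.3) {
  set.seed(seed)
  N <- n_clusters * cluster_size
  X <- matrix(rnorm(N * n_features), N, n_features)
  colnames(X) <- sprintf("f%02d", seq_len(n_features))
  beta <- c(rep(beta_signal, n_signal), rep(0, n_features - n_signal))
  id <- rep(seq_len(n_clusters), each = cluster_size)
  eps <- unlist(lapply(seq_len(n_clusters), function(i) {
    f <- rnorm(1)
    sqrt(rho) * f + sqrt(1 - rho) * rnorm(cluster_size)
  }))
  list(X = cbind(`(Intercept)` = 1, X), y = drop(X %*% beta) + eps, id = id,
       true_support = colnames(X)[seq_len(n_signal)])
}

# Balanced longitudinal toy data from a random-intercept-only generative
# model (compound-symmetric covariance), for GLS-oracle checks.
make_cs_data <- function(seed, n_subj = 6, visits = 0:4, tau = 1.5, sigma = 1) {
  set.seed(seed)
  groups <- rep(c("hc", "de_novo_pd"), each = n_subj / 2)
  rows <- lapply(seq_len(n_subj), function(j) {
    b0 <- rnorm(1, 0, tau)
    slope <- if (groups[j] == "hc") 0 else 0.5
    data.frame(subject_id = sprintf("s%02d", j), group = groups[j],
               visit_time = visits, age = 0,
               y = 1 + b0 + slope * visits + rnorm(length(visits), 0, sigma))
  })
  do.call(rbind, rows)
}
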