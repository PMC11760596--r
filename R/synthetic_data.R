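# Synthetic longitudinal cohort generator.
#
# Emulates a four-group observational study (three Parkinson's disease
# stages plus healthy controls) with clinic visits every 3 months for
# 2 years, a panel of digital features with group-specific progression
# slopes, subject-level random intercepts/slopes, block-correlated
# residuals, optional skewness, missingness and outliers, and a clinical
# anchor score driven by the latent (noise-free) feature signals.

default_groups <- c("de_novo_pd", "mild_moderate_pd", "advanced_pd", "hc")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the framework was developed for:
#' four groups of 10 subjects (de novo PD, mild-to-moderate PD on therapy,
#' advanced PD, healthy controls) seen once every 3 months for 2 years
#' (visits at 0, 3, ..., 24 months), a 20-feature digital panel in which
#' the first five features carry true progression (de novo and advanced PD
#' progress; mild-to-moderate PD on therapy and HC are flat), and an
#' MDS-UPDRS-III-like continuous clinical anchor score driven by the
#' noise-free progressive feature signals. Age and sex distributions match
#' the published baseline demographics of that design (group mean ages
#' 66.2/61.6/71.2/65.6 years, male proportions 0.5/0.9/0.5/0.3).
#'
#' @param n_per_group subjects per group.
#' @param groups ordered group labels; `"hc"` is the reference group.
#' @param visit_times visit times in months, strictly increasing.
#' @param n_features number of digital features.
#' @param progressive_feature_index indices of features carrying true
#'   progression (and, by default, the baseline group separation).
#' @param group_slopes `length(groups) x n_features` matrix of per-month
#'   fixed slopes; default gives progressive features slope 0.15 in de novo
#'   PD and 0.10 in advanced PD, zero elsewhere.
#' @param group_baselines `length(groups) x n_features` matrix of feature
#'   means at time 0; default separates groups on the progressive features
#'   (de novo 1.0, mild-to-moderate 1.5, advanced 2.5, HC 0).
#' @param random_intercept_sd,random_slope_sd,residual_sd noise scales of
#'   the per-subject-per-feature random intercept, random slope, and the
#'   visit-level residual.
#' @param feature_corr target pairwise correlation of residuals within a
#'   correlation block (induced through a shared Gaussian latent factor).
#' @param corr_block_size number of consecutive features per block.
#' @param skewed_feature_index features generated on the log scale (their
#'   stored values are `exp(skew_strength * linear value)`); default is the
#'   last two features.
#' @param skew_strength multiplier applied before exponentiation.
#' @param missing_rate probability that a feature cell is missing (MCAR).
#' @param outlier_rate,outlier_scale probability that an observed cell is
#'   shifted by `+/- outlier_scale * residual_sd`.
#' @param anchor_weights weights mapping the noise-free feature signals to
#'   the clinical anchor score; default weight 1 on each progressive
#'   feature.
#' @param anchor_noise_sd,anchor_offset anchor measurement noise SD and
#'   additive offset placing the score in a 0-80-like range.
#' @param anchor_round round the anchor to an integer (the clinical scale
#'   is integer-valued; the framework treats it as continuous, so the
#'   default is `FALSE`).
#' @param age_mean,age_sd,male_prop per-group age Normal parameters and
#'   male proportion, in the order of `groups`.
#' @param epoch_sd dispersion of epoch-level draws around the subject-visit
#'   feature value (used by [generate_epoch_table()]).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [generate_epoch_table()]
#' @export
cohort_config <- function(n_per_group = 10,
                          groups = default_groups,
                          visit_times = seq(0, 24, by = 3),
                          n_features = 20,
                          progressive_feature_index = NULL,
                          group_slopes = NULL,
                          group_baselines = NULL,
                          random_intercept_sd = 1,
                          random_slope_sd = 0.02,
                          residual_sd = 1,
                          feature_corr = 0.3,
                          corr_block_size = 5,
                          skewed_feature_index = NULL,
                          skew_strength = 1,
                          missing_rate = 0.05,
                          outlier_rate = 0.002,
                          outlier_scale = 5,
                          anchor_weights = NULL,
                          anchor_noise_sd = 5,
                          anchor_offset = 20,
                          anchor_round = FALSE,
                          age_mean = c(66.2, 61.6, 71.2, 65.6),
                          age_sd = c(6.46, 10.76, 4.78, 6.98),
                          male_prop = c(0.5, 0.9, 0.5, 0.3),
                          epoch_sd = 1,
                          seed = 1) {
  G <- length(groups)
  K <- n_features
  visit_times <- as.numeric(visit_times)

  if (is.null(progressive_feature_index)) {
    progressive_feature_index <- seq_len(min(5, K))
  }
  if (length(progressive_feature_index) &&
      !all(progressive_feature_index %in% seq_len(K))) {
    digicomp_error("progressive_feature_index must be a subset of 1..n_features",
                   "digicomp_config_error")
  }
  if (is.null(skewed_feature_index)) {
    skewed_feature_index <-
      if (K >= 2) setdiff((K - 1):K, progressive_feature_index) else integer(0)
  }
  if (is.null(group_slopes)) {
    group_slopes <- matrix(0, G, K, dimnames = list(groups, NULL))
    if ("de_novo_pd" %in% groups) {
      group_slopes["de_novo_pd", progressive_feature_index] <- 0.15
    }
    if ("advanced_pd" %in% groups) {
      group_slopes["advanced_pd", progressive_feature_index] <- 0.10
    }
  }
  if (is.null(group_baselines)) {
    group_baselines <- matrix(0, G, K, dimnames = list(groups, NULL))
    base <- c(de_novo_pd = 1.0, mild_moderate_pd = 1.5, advanced_pd = 2.5, hc = 0)
    for (g in intersect(groups, names(base))) {
      group_baselines[g, progressive_feature_index] <- base[[g]]
    }
  }
  if (is.null(anchor_weights)) {
    anchor_weights <- numeric(K)
    anchor_weights[progressive_feature_index] <- 1
  }
  if (is.null(rownames(group_slopes))) rownames(group_slopes) <- groups
  if (is.null(rownames(group_baselines))) rownames(group_baselines) <- groups

  cfg <- structure(list(
    n_per_group = n_per_group, groups = groups, visit_times = visit_times,
    n_features = K, progressive_feature_index = progressive_feature_index,
    group_slopes = group_slopes, group_baselines = group_baselines,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd, residual_sd = residual_sd,
    feature_corr = feature_corr, corr_block_size = corr_block_size,
    skewed_feature_index = skewed_feature_index,
    skew_strength = skew_strength,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    outlier_scale = outlier_scale, anchor_weights = anchor_weights,
    anchor_noise_sd = anchor_noise_sd, anchor_offset = anchor_offset,
    anchor_round = anchor_round,
    age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
    epoch_sd = epoch_sd, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  bad <- function(msg) digicomp_error(msg, "digicomp_config_error")
  with(cfg, {
    if (n_per_group < 1) bad("n_per_group must be >= 1")
    if (!length(groups) || anyDuplicated(groups)) bad("groups must be unique labels")
    if (length(visit_times) < 1 || is.unsorted(visit_times, strictly = TRUE)) {
      bad("visit_times must be strictly increasing")
    }
    if (n_features < 1) bad("n_features must be >= 1")
    if (length(progressive_feature_index) &&
        !all(progressive_feature_index %in% seq_len(n_features))) {
      bad("progressive_feature_index must be a subset of 1..n_features")
    }
    if (length(skewed_feature_index) &&
        !all(skewed_feature_index %in% seq_len(n_features))) {
      bad("skewed_feature_index must be a subset of 1..n_features")
    }
    sds <- c(random_intercept_sd, random_slope_sd, residual_sd,
             anchor_noise_sd, epoch_sd)
    if (any(sds < 0)) bad("all SDs must be >= 0")
    if (missing_rate < 0 || missing_rate >= 1) bad("missing_rate must be in [0, 1)")
    if (outlier_rate < 0 || outlier_rate >= 1) bad("outlier_rate must be in [0, 1)")
    if (feature_corr < 0 || feature_corr >= 1) bad("feature_corr must be in [0, 1)")
    if (corr_block_size < 1) bad("corr_block_size must be >= 1")
    if (!all(dim(group_slopes) == c(length(groups), n_features))) {
      bad("group_slopes must be a groups x features matrix")
    }
    if (!all(dim(group_baselines) == c(length(groups), n_features))) {
      bad("group_baselines must be a groups x features matrix")
    }
    if (length(anchor_weights) != n_features) {
      bad("anchor_weights must have one weight per feature")
    }
    if (length(age_mean) != length(groups) || length(age_sd) != length(groups) ||
        length(male_prop) != length(groups)) {
      bad("age_mean, age_sd and male_prop must have one entry per group")
    }
    invisible(NULL)
  })
}

feature_names_for <- function(cfg) sprintf("feat%02d", seq_len(cfg$n_features))

#' Generate a synthetic longitudinal cohort
#'
#' Subject `j` in group `g` has latent feature trajectory
#' `mu_gk + b0_jk + (s_gk + b1_jk) * t` with `b0 ~ N(0, sigma_int^2)` and
#' `b1 ~ N(0, sigma_slope^2)`; the observed value adds a residual whose
#' within-block correlation `feature_corr` is induced by a shared Gaussian
#' latent factor per block and visit. Skew-listed features are
#' exponentiated, then missing cells and outliers are injected at the
#' configured rates. The clinical anchor score is
#' `anchor_offset + sum_k w_k * latent_k(t) + N(0, anchor_noise_sd^2)`,
#' i.e. it is driven by the noise-free (pre-skew) feature signals.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with one row per subject-visit: `subject_id`,
#'   `group`, `visit_time` (months), `age`, `sex`, `clinical_score`, and
#'   one column per feature (`feat01`, ...). Identical `(config, seed)`
#'   yield bitwise-identical output.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    digicomp_error("config must be a cohort_config", "digicomp_config_error")
  }
  validate_cohort_config(config)
  cfg <- config
  tt <- cfg$visit_times
  V <- length(tt)
  K <- cfg$n_features
  fnames <- feature_names_for(cfg)
  block_of <- ceiling(seq_len(K) / cfg$corr_block_size)
  n_blocks <- max(block_of)
  rho <- cfg$feature_corr

  local_seed(cfg$seed, {
    rows <- vector("list", length(cfg$groups) * cfg$n_per_group)
    sub_i <- 0L
    for (gi in seq_along(cfg$groups)) {
      g <- cfg$groups[gi]
      mu <- cfg$group_baselines[g, ]
      sl <- cfg$group_slopes[g, ]
      for (j in seq_len(cfg$n_per_group)) {
        sub_i <- sub_i + 1L
        sid <- sprintf("sub%03d", sub_i)
        age <- stats::rnorm(1, cfg$age_mean[gi], cfg$age_sd[gi])
        sex <- if (stats::runif(1) < cfg$male_prop[gi]) "M" else "F"
        b0 <- stats::rnorm(K, 0, cfg$random_intercept_sd)
        b1 <- stats::rnorm(K, 0, cfg$random_slope_sd)
        # latent (noise-free) trajectory, V x K
        latent <- matrix(mu + b0, V, K, byrow = TRUE) +
          outer(tt, sl + b1)
        fac <- matrix(stats::rnorm(V * n_blocks), V, n_blocks)
        z <- matrix(stats::rnorm(V * K), V, K)
        eps <- cfg$residual_sd *
          (sqrt(rho) * fac[, block_of, drop = FALSE] + sqrt(1 - rho) * z)
        y <- latent + eps
        if (length(cfg$skewed_feature_index)) {
          y[, cfg$skewed_feature_index] <-
            exp(cfg$skew_strength * y[, cfg$skewed_feature_index])
        }
        anchor <- cfg$anchor_offset + drop(latent %*% cfg$anchor_weights) +
          stats::rnorm(V, 0, cfg$anchor_noise_sd)
        if (cfg$anchor_round) anchor <- round(anchor)
        if (cfg$missing_rate > 0) {
          y[matrix(stats::runif(V * K) < cfg$missing_rate, V, K)] <- NA_real_
        }
        if (cfg$outlier_rate > 0) {
          hit <- matrix(stats::runif(V * K) < cfg$outlier_rate, V, K) & !is.na(y)
          sgn <- matrix(sign(stats::runif(V * K) - 0.5), V, K)
          y[hit] <- y[hit] + sgn[hit] * cfg$outlier_scale * cfg$residual_sd
        }
        df <- data.frame(subject_id = sid, group = g, visit_time = tt,
                         age = age, sex = sex, clinical_score = anchor,
                         stringsAsFactors = FALSE)
        df[fnames] <- as.data.frame(y)
        rows[[sub_i]] <- df
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate an epoch-level feature table
#'
#' Expands the cohort of `config` to epoch level: for every
#' subject-visit-task, each feature contributes `epochs_per_task`
#' independent draws `N(value, epoch_sd^2)` around the subject-visit
#' feature value. Features are assigned to the three tasks (walk, sway,
#' tug) in round-robin order. Aggregating the epochs with the mean
#' recovers the subject-visit value up to sampling error.
#'
#' @param config a [cohort_config()].
#' @param epochs_per_task number of epochs per subject-visit-task (>= 1).
#' @return a long `data.frame` with columns `subject_id`, `visit_time`,
#'   `task`, `feature_name`, `epoch_index`, `value`. Missing cohort cells
#'   yield missing epochs.
#' @export
generate_epoch_table <- function(config = cohort_config(), epochs_per_task = 10) {
  if (epochs_per_task < 1) {
    digicomp_error("epochs_per_task must be >= 1", "digicomp_config_error")
  }
  cohort <- generate_cohort(config)
  fnames <- feature_names_for(config)
  tasks <- rep_len(c("walk", "sway", "tug"), length(fnames))
  E <- as.integer(epochs_per_task)
  n <- nrow(cohort)
  local_seed(config$seed + 1000003L, {
    per_feat <- lapply(seq_along(fnames), function(k) {
      target <- rep(cohort[[fnames[k]]], each = E)
      data.frame(
        subject_id = rep(cohort$subject_id, each = E),
        visit_time = rep(cohort$visit_time, each = E),
        task = tasks[k],
        feature_name = fnames[k],
        epoch_index = rep.int(seq_len(E), n),
        value = target + stats::rnorm(n * E, 0, config$epoch_sd),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, per_feat)
    rownames(out) <- NULL
    out
  })
}

#' Read or write longitudinal tables as CSV
#'
#' Plain UTF-8 CSV with a header row and ISO decimal point; the
#' interchange format between pipeline stages.
#'
#' @param data a data.frame.
#' @param path file path.
#' @return `read_longitudinal_csv` returns a data.frame;
#'   `write_longitudinal_csv` returns `path` invisibly.
#' @export
write_longitudinal_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_longitudinal_csv
#' @export
read_longitudinal_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Serialize a cohort configuration to YAML or JSON
#'
#' @param config a [cohort_config()].
#' @param path destination ending in `.yaml`, `.yml`, or `.json`.
#' @return `path`, invisibly; `read_cohort_config` returns the config.
#' @export
write_cohort_config <- function(config, path) {
  lst <- unclass(config)
  lst$group_slopes <- as.data.frame(lst$group_slopes)
  lst$group_baselines <- as.data.frame(lst$group_baselines)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lst$group_slopes <- as.matrix(as.data.frame(lst$group_slopes))
  lst$group_baselines <- as.matrix(as.data.frame(lst$group_baselines))
  rownames(lst$group_slopes) <- lst$groups
  rownames(lst$group_baselines) <- lst$groups
  do.call(cohort_config, lst)
}
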