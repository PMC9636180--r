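#' Dataset-simulation strategy for the stability ensemble
#'
#' Two resampling modes are provided because the moment-preserving
#' description admits two readings:
#' `per_participant_moments` redraws each participant's whole feature vector
#' i.i.d. from `N(mu_p, sigma_p^2)`, where `mu_p`/`sigma_p^2` are the mean
#' and variance of that participant's observed features (the literal
#' reading: features become exchangeable within a participant);
#' `per_feature_jitter` redraws each value from a normal centred on the
#' observed value with sd `noise_scale` times the feature's within-group sd
#' (feature-level signal is preserved up to noise).
#'
#' @param mode `"per_participant_moments"` or `"per_feature_jitter"`.
#' @param noise_scale Positive noise multiplier (jitter mode only).
#' @return A list of class `simulation_strategy`.
#' @export
simulation_strategy <- function(mode = c("per_participant_moments",
                                         "per_feature_jitter"),
                                noise_scale = 0.5) {
  mode <- match.arg(mode)
  if (mode == "per_feature_jitter" && (!is.numeric(noise_scale) || noise_scale <= 0)) {
    stop("`noise_scale` must be > 0 for per_feature_jitter", call. = FALSE)
  }
  structure(list(mode = mode, noise_scale = noise_scale),
            class = "simulation_strategy")
}

#' Stability-ensemble configuration
#'
#' @param iterations Number of simulated datasets / elastic-net fits (study
#'   convention: 300).
#' @param alpha_grid Elastic-net mixing values searched by cross-validation.
#' @param k_folds Cross-validation folds.
#' @param score_threshold Feature-score cut for the selection indicator
#'   (strictly greater than; study convention: 80 on the 0-100 scale).
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(iterations = 300, alpha_grid = seq(0.1, 0.9, by = 0.2),
                            k_folds = 5, score_threshold = 80, seed = 1) {
  assert_count(iterations, "iterations", 1L)
  assert_count(k_folds, "k_folds", 2L)
  stopifnot(score_threshold > 0, score_threshold < 100,
            all(alpha_grid > 0 & alpha_grid <= 1))
  structure(list(iterations = as.integer(iterations), alpha_grid = alpha_grid,
                 k_folds = as.integer(k_folds), score_threshold = score_threshold,
                 seed = as.integer(seed)), class = "ensemble_config")
}

#' Simulate one moment-preserving replicate of a feature table
#'
#' Same shape, participants and labels as the baseline; values are redrawn
#' according to the [simulation_strategy()]. Frequency features (identified
#' via the table's `feature_info` attribute or the `feature_kind` argument)
#' are clipped to \[0, 100\]; zero-variance draws return the mean exactly.
#'
#' @param baseline Wide feature tibble (metadata + feature columns).
#' @param strategy A [simulation_strategy()].
#' @param seed Integer seed for this replicate.
#' @param feature_cols Feature columns; autodetected by default.
#' @param feature_kind Optional named character vector (feature ->
#'   `"frequency"`/`"msi"`).
#' @param group_col Grouping column used by the jitter mode's within-group sd.
#' @return A tibble of the same shape as `baseline`.
#' @export
simulate_dataset <- function(baseline, strategy = simulation_strategy(), seed = 1,
                             feature_cols = NULL, feature_kind = NULL,
                             group_col = "group") {
  meta <- c("participant_id", "group", "batch", "timepoint")
  feature_cols <- feature_cols %||% setdiff(
    names(baseline)[vapply(baseline, is.numeric, logical(1))], meta)
  if (nrow(baseline) < 2L || length(feature_cols) < 2L) {
    stop("baseline needs >= 2 participants and >= 2 features", call. = FALSE)
  }
  if (is.null(feature_kind)) {
    fi <- attr(baseline, "feature_info")
    if (!is.null(fi)) feature_kind <- setNames(fi$kind, fi$feature)
  }
  x <- as.matrix(baseline[feature_cols])
  n <- nrow(x); p <- ncol(x)
  sim <- withr::with_seed(seed, {
    if (strategy$mode == "per_participant_moments") {
      mu <- rowMeans(x)
      sdev <- apply(x, 1, sd)
      matrix(rnorm(n * p, mean = rep(mu, p), sd = rep(sdev, p)), n, p)
    } else {
      g <- baseline[[group_col]]
      sds <- apply(x, 2, function(col) stats::ave(col, g, FUN = sd))
      x + matrix(rnorm(n * p), n, p) * strategy$noise_scale * sds
    }
  })
  colnames(sim) <- feature_cols
  if (!is.null(feature_kind)) {
    fr <- feature_cols[feature_kind[feature_cols] %in% "frequency"]
    sim[, fr] <- pmin(pmax(sim[, fr, drop = FALSE], 0), 100)
  }
  out <- baseline
  out[feature_cols] <- tibble::as_tibble(sim)
  out
}

# Rank-formula AUC of scores for a binary outcome (positive = TRUE).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated elastic-net fit with 0-100 feature scores
#'
#' Regularized logistic regression over a grid of L1/L2 mixing values; the
#' penalty strength and mixing are chosen jointly by k-fold cross-validated
#' binomial deviance. Feature scores are max-scaled absolute coefficients at
#' the selected model (`|beta| / max|beta| * 100`; an all-zero model scores
#' every feature 0). AUC, and sensitivity/specificity at probability 0.5,
#' are computed from out-of-fold (pre-validated) predictions; the second
#' factor level is the positive class.
#'
#' @param data Matrix/tibble of features (rows = participants).
#' @param labels Two-level factor outcome.
#' @param config An [ensemble_config()] (alpha grid and fold count are used).
#' @return An `enet_fit` list: `scores` (named, 0-100), `auc`,
#'   `sensitivity`, `specificity`, `alpha`, `lambda`.
#' @export
fit_elastic_net <- function(data, labels, config = ensemble_config()) {
  x <- as.matrix(data)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (min(table(y)) < config$k_folds) {
    stop("each class needs >= k_folds members", call. = FALSE)
  }
  # balanced fold assignment within class (consumes the caller-seeded RNG)
  foldid <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    foldid[idx] <- sample(rep_len(seq_len(config$k_folds), length(idx)))
  }
  best <- NULL
  for (a in config$alpha_grid) {
    cvf <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                             foldid = foldid, keep = TRUE,
                             type.measure = "deviance", standardize = TRUE)
    i <- which.min(cvf$cvm)
    if (is.null(best) || cvf$cvm[i] < best$cvm) {
      best <- list(cvm = cvf$cvm[i], fit = cvf, index = i, alpha = a)
    }
  }
  beta <- as.numeric(coef(best$fit, s = best$fit$lambda[best$index]))[-1]
  # scores on the standardized scale so they are comparable across features
  # with different units (glmnet reports coefficients on the original scale)
  beta_std <- abs(beta) * apply(x, 2, sd)
  scores <- if (max(beta_std) == 0) {
    rep(0, length(beta_std))
  } else {
    beta_std / max(beta_std) * 100
  }
  names(scores) <- colnames(x)
  link <- best$fit$fit.preval[, best$index]
  prob <- 1 / (1 + exp(-link))
  pos <- y == levels(y)[2]
  pred_pos <- prob > 0.5
  structure(list(
    scores = scores,
    auc = auc_rank(prob, pos),
    sensitivity = sum(pred_pos & pos) / sum(pos),
    specificity = sum(!pred_pos & !pos) / sum(!pos),
    alpha = best$alpha, lambda = best$fit$lambda[best$index]
  ), class = "enet_fit")
}

#' Selection indicator for a feature score
#'
#' 1 when the 0-100 score strictly exceeds the threshold (80 by default),
#' else 0.
#'
#' @param score Numeric score(s) in \[0, 100\].
#' @param threshold Strict cut point.
#' @return Integer 0/1 vector.
#' @export
delta_indicator <- function(score, threshold = 80) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  as.integer(score > threshold)
}

#' Cumulative importance across ensemble iterations
#'
#' Per feature, the percentage of iterations in which the selection
#' indicator was 1: `100 * sum(delta) / iterations`.
#'
#' @param delta Iterations x features 0/1 matrix.
#' @return Named numeric vector in \[0, 100\].
#' @export
cumulative_importance <- function(delta) {
  delta <- as.matrix(delta)
  if (!length(delta)) stop("empty delta matrix", call. = FALSE)
  if (!all(delta %in% c(0, 1))) stop("delta must be 0/1", call. = FALSE)
  100 * colSums(delta) / nrow(delta)
}

#' Run the simulation ensemble for stability selection
#'
#' Repeats simulate -> fit -> score -> select for `config$iterations`
#' replicates (per-iteration seeds derived deterministically from the master
#' seed), and aggregates the cumulative-importance vector and ensemble
#' performance (AUC, sensitivity, specificity). Failed iterations are
#' recorded and excluded from all denominators; more than 10% failures
#' aborts the run.
#'
#' @param baseline Wide feature tibble with a `group` column.
#' @param strategy A [simulation_strategy()].
#' @param config An [ensemble_config()].
#' @param group_col Name of the outcome column.
#' @param feature_cols Feature columns; autodetected by default.
#' @return A `stab_ensemble`: scores and delta matrices, `importance`
#'   tibble, `performance` tibble, failure log.
#' @export
run_ensemble <- function(baseline, strategy = simulation_strategy(),
                         config = ensemble_config(), group_col = "group",
                         feature_cols = NULL) {
  meta <- c("participant_id", "group", "batch", "timepoint")
  feature_cols <- feature_cols %||% setdiff(
    names(baseline)[vapply(baseline, is.numeric, logical(1))], meta)
  labels <- factor(baseline[[group_col]])
  seeds <- derive_seeds(config$seed, config$iterations, "ensemble")
  fits <- vector("list", config$iterations)
  failures <- character()
  for (i in seq_len(config$iterations)) {
    fits[[i]] <- tryCatch(
      withr::with_seed(seeds[i], {
        sim <- simulate_dataset(baseline, strategy, seed = seeds[i],
                                feature_cols = feature_cols,
                                group_col = group_col)
        fit_elastic_net(sim[feature_cols], labels, config)
      }),
      error = function(e) {
        failures <<- c(failures, sprintf("iteration %d: %s", i,
                                         conditionMessage(e)))
        NULL
      })
    if (length(failures) > 0.1 * config$iterations) {
      stop("more than 10% of ensemble iterations failed:\n",
           paste(head(failures, 5), collapse = "\n"), call. = FALSE)
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  scores <- do.call(rbind, lapply(fits, `[[`, "scores"))
  delta <- matrix(delta_indicator(scores, config$score_threshold),
                  nrow = nrow(scores), dimnames = dimnames(scores))
  ci <- cumulative_importance(delta)
  perf <- tibble::tibble(
    iteration = which(ok),
    auc = vapply(fits, `[[`, numeric(1), "auc"),
    sensitivity = vapply(fits, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(fits, `[[`, numeric(1), "specificity"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha")
  )
  structure(list(
    scores = scores, delta = delta,
    importance = tibble::tibble(feature = names(ci),
                                cumulative_importance = unname(ci),
                                mean_score = colMeans(scores)) |>
      dplyr::arrange(dplyr::desc(.data$cumulative_importance),
                     dplyr::desc(.data$mean_score)),
    performance = perf,
    failures = failures, config = config, strategy = strategy
  ), class = "stab_ensemble")
}

#' @export
print.stab_ensemble <- function(x, ...) {
  cat("Stability-selection ensemble:", nrow(x$scores), "iterations,",
      ncol(x$scores), "features\n")
  cat(sprintf("mean AUC %.3f | mean sensitivity %.3f | mean specificity %.3f\n",
              mean(x$performance$auc), mean(x$performance$sensitivity),
              mean(x$performance$specificity)))
  cat("top features by cumulative importance:\n")
  print(head(x$importance, 5))
  invisible(x)
}
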