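#' Cohort generator configuration
#'
#' Describes a two-arm immunophenotyping cohort to simulate: arm sizes
#' (sustained unresponsiveness `SU` vs desensitized `DS`), batch structure,
#' visit timepoints, and the feature-level ground truth to inject. Defaults
#' mirror a 51-participant avoidance cohort (21 SU vs 30 DS) profiled on 123
#' cytometry-derived features.
#'
#' @param n_su,n_ds Number of participants per outcome arm (each >= 2).
#' @param n_batches Number of acquisition batches participants are spread over.
#' @param timepoints Character vector of visit labels (e.g. `"BL"`, `"wk104"`).
#' @param seed Integer master seed; mandatory for reproducibility.
#' @param n_features Number of participant-level features (frequencies + MSIs).
#' @param n_informative Number of features carrying a true group effect.
#' @param effect_size Standardized mean difference injected per informative
#'   feature on the latent (logit/log) scale.
#' @param batch_sd Standard deviation of additive batch intercepts on the
#'   latent scale (0 disables batch effects).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_su = 21, n_ds = 30, n_batches = 3,
                          timepoints = "BL", seed = 1,
                          n_features = 123, n_informative = 5,
                          effect_size = 1.2, batch_sd = 0.25) {
  assert_count(n_su, "n_su", 2L); assert_count(n_ds, "n_ds", 2L)
  assert_count(n_batches, "n_batches", 1L)
  assert_count(n_features, "n_features", 1L)
  assert_count(n_informative, "n_informative", 0L)
  if (n_informative > n_features) {
    stop("`n_informative` cannot exceed `n_features`", call. = FALSE)
  }
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("`effect_size` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(batch_sd) || batch_sd < 0) {
    stop("`batch_sd` must be >= 0", call. = FALSE)
  }
  assert_count(seed, "seed", 0L)
  structure(list(
    n_su = as.integer(n_su), n_ds = as.integer(n_ds),
    n_batches = as.integer(n_batches),
    timepoints = as.character(timepoints), seed = as.integer(seed),
    n_features = as.integer(n_features),
    n_informative = as.integer(n_informative),
    effect_size = effect_size, batch_sd = batch_sd
  ), class = "cohort_config")
}

default_serology_vars <- c("peanut_sIgE", "arah2_sIgE", "igg4_ige_ratio")

#' Generate a synthetic cohort with known ground truth
#'
#' Creates one row per participant per timepoint (stable participant id, arm,
#' batch) and attaches a `truth` attribute recording the injected effects:
#' which features are informative (and with what signed latent effect), which
#' serology variables are rank-coupled to which features, and each
#' participant's true immune-subset composition used when single-cell events
#' are generated.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `participant_id`, `group`, `batch`,
#'   `timepoint`; ground truth available via [cohort_truth()].
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop("`config` must be a cohort_config", call. = FALSE)
  n <- config$n_su + config$n_ds
  ids <- sprintf("P%03d", seq_len(n))
  group <- factor(rep(c("SU", "DS"), c(config$n_su, config$n_ds)),
                  levels = c("SU", "DS"))
  seeds <- derive_seeds(config$seed, 4, "cohort")
  batch <- withr::with_seed(seeds[1], {
    sample(paste0("B", rep_len(seq_len(config$n_batches), n)))
  })
  participants <- tibble::tibble(participant_id = ids, group = group, batch = batch)
  cohort <- tidyr::expand_grid(participants,
                               timepoint = factor(config$timepoints,
                                                  levels = config$timepoints))

  feat_ids <- sprintf("feat_%03d", seq_len(config$n_features))
  kind <- rep(c("frequency", "msi"), length.out = config$n_features)
  informative <- if (config$n_informative > 0) {
    withr::with_seed(seeds[2], sample(feat_ids, config$n_informative))
  } else character()
  effects <- if (length(informative)) {
    config$effect_size * rep_len(c(1, -1), length(informative))
  } else numeric()

  links <- if (length(informative) >= 1) {
    tibble::tibble(
      feature  = informative[c(1, 1, min(2, length(informative)))],
      serology = c("peanut_sIgE", "arah2_sIgE", "igg4_ige_ratio"),
      rho      = c(0.45, 0.47, -0.45)
    )
  } else {
    tibble::tibble(feature = character(), serology = character(), rho = numeric())
  }

  base <- default_population_proportions()
  props <- withr::with_seed(seeds[3], {
    purrr::map_dfr(seq_len(n), function(i) {
      lp <- log(base) + rnorm(length(base), 0, 0.15)
      # outcome-linked composition shifts: DS carries more naive CD8,
      # SU more effector-memory CD8
      if (group[i] == "DS") lp["naive_cd8"] <- lp["naive_cd8"] + 0.5
      if (group[i] == "SU") lp["em_cd8"] <- lp["em_cd8"] + 0.4
      p <- exp(lp) / sum(exp(lp))
      tibble::tibble(participant_id = ids[i],
                     population = names(base), proportion = unname(p))
    })
  })

  truth <- structure(list(
    informative_features = tibble::tibble(feature = informative, effect = effects),
    serology_links = links,
    population_proportions = props,
    feature_info = tibble::tibble(feature = feat_ids, kind = kind),
    config = config
  ), class = "synthetic_truth")
  attr(cohort, "truth") <- truth
  cohort
}

#' Ground truth of a synthetic cohort
#' @param x An object carrying a `truth` attribute (from [generate_cohort()]
#'   or [generate_feature_table()]).
#' @return The `synthetic_truth` list.
#' @export
cohort_truth <- function(x) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("no `truth` attribute found", call. = FALSE)
  tr
}

#' Participant-level feature table with injected group effects
#'
#' Frequencies are generated on the logit scale and mapped to \[0, 100\];
#' marker expressions (MSI) on the log scale, so values are >= 0. Informative
#' features are shifted between arms by `effect_size` residual standard
#' deviations on the latent scale; batch intercepts (sd `batch_sd`) and a
#' participant random intercept are added on the same scale.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param config The [cohort_config()] used to build the cohort.
#' @param truth Ground truth; defaults to the cohort's own.
#' @return A wide tibble (metadata columns + one column per feature), with
#'   `truth` and `feature_info` attributes.
#' @export
generate_feature_table <- function(cohort, config, truth = cohort_truth(cohort)) {
  info <- truth$feature_info
  n_feat <- nrow(info)
  seeds <- derive_seeds(config$seed, 5, "features")
  participants <- unique(cohort$participant_id)
  batches <- sort(unique(cohort$batch))

  base_mu <- withr::with_seed(seeds[1], {
    ifelse(info$kind == "frequency", runif(n_feat, -1.8, -0.5), runif(n_feat, 0.5, 2))
  })
  batch_fx <- withr::with_seed(seeds[2], {
    matrix(rnorm(n_feat * length(batches), 0, config$batch_sd),
           nrow = length(batches), dimnames = list(batches, info$feature))
  })
  part_fx <- withr::with_seed(seeds[3], {
    setNames(rnorm(length(participants), 0, 0.3), participants)
  })
  # `effect_size` is the standardized mean difference on the observed feature
  # scale; the logit/log output maps attenuate a latent shift by a
  # feature-dependent amount, so the injected latent shift is calibrated per
  # feature (deterministic quadrature + root finding) to deliver it.
  sd_latent <- sqrt(1 + 0.3^2 + config$batch_sd^2)
  eff <- setNames(rep(0, n_feat), info$feature)
  if (nrow(truth$informative_features)) {
    for (i in seq_len(nrow(truth$informative_features))) {
      f <- truth$informative_features$feature[i]
      e <- truth$informative_features$effect[i]
      k <- info$kind[info$feature == f]
      eff[f] <- calibrate_latent_shift(base_mu[info$feature == f], k, e, sd_latent)
    }
  }

  noise <- withr::with_seed(seeds[4], {
    matrix(rnorm(nrow(cohort) * n_feat), nrow = nrow(cohort))
  })
  is_ds <- as.numeric(cohort$group == "DS")
  lat <- matrix(base_mu, nrow(cohort), n_feat, byrow = TRUE) +
    batch_fx[cohort$batch, , drop = FALSE] +
    matrix(part_fx[cohort$participant_id], nrow(cohort), n_feat) +
    outer(is_ds, eff) + noise

  vals <- lat
  fr <- info$kind == "frequency"
  vals[, fr] <- 100 * plogis(lat[, fr, drop = FALSE])
  vals[, !fr] <- exp(0.35 * lat[, !fr, drop = FALSE])
  colnames(vals) <- info$feature

  out <- dplyr::bind_cols(cohort, tibble::as_tibble(vals))
  attr(out, "truth") <- truth
  attr(out, "feature_info") <- info
  out
}

# Latent shift delivering a target observed-scale standardized difference.
# Quadrature over the latent normal; monotone in the shift, solved by uniroot.
calibrate_latent_shift <- function(mu, kind, effect, sd_latent) {
  if (effect == 0) return(0)
  dir <- sign(effect)
  zq <- qnorm((seq_len(400) - 0.5) / 400) * sd_latent + mu
  g <- if (kind == "frequency") {
    function(z) 100 * plogis(z)
  } else {
    function(z) exp(0.35 * z)
  }
  y0 <- g(zq); m0 <- mean(y0); v0 <- var(y0)
  fn <- function(d) {
    y1 <- g(zq + dir * d)
    dir * (mean(y1) - m0) / sqrt((var(y1) + v0) / 2) - abs(effect)
  }
  if (fn(25) < 0) {
    stop(sprintf(paste("effect_size %.2f is not attainable for a bounded/skewed",
                       "`%s` feature (pooled-sd standardized difference",
                       "saturates below it)"), abs(effect), kind), call. = FALSE)
  }
  dir * stats::uniroot(fn, c(1e-9, 25))$root
}

#' Serology table rank-coupled to designated features
#'
#' For every serology link in the cohort's ground truth the serology variable
#' is generated with a Gaussian copula on the linked feature's ranks, so the
#' realized Spearman correlation approximates the target `rho`
#' (Pearson latent correlation `2*sin(pi*rho/6)`). Unlinked variables are
#' independent log-normal draws. Values are on a log-normal IgE-like scale
#' (kU/L).
#'
#' @param cohort Cohort tibble (used for ids and for baseline filtering).
#' @param features Feature table from [generate_feature_table()].
#' @param truth Ground truth; defaults to the feature table's.
#' @param timepoint Which visit the serology is drawn at (first by default).
#' @param seed Integer seed.
#' @return A tibble: `participant_id` plus one column per serology variable.
#' @export
generate_serology <- function(cohort, features, truth = cohort_truth(features),
                              timepoint = NULL, seed = truth$config$seed) {
  links <- truth$serology_links
  if (nrow(links) && any(abs(links$rho) >= 1)) {
    stop("target |rho| must be < 1", call. = FALSE)
  }
  tp <- timepoint %||% as.character(features$timepoint[1])
  bl <- dplyr::filter(features, .data$timepoint == tp)
  n <- nrow(bl)
  vars <- unique(c(default_serology_vars, links$serology))
  seeds <- derive_seeds(seed, length(vars), "serology")
  out <- tibble::tibble(participant_id = bl$participant_id)
  for (i in seq_along(vars)) {
    v <- vars[i]
    hit <- links[links$serology == v, , drop = FALSE]
    z <- withr::with_seed(seeds[i], {
      if (nrow(hit)) {
        f <- bl[[hit$feature[1]]]
        zf <- qnorm((rank(f, ties.method = "average") - 0.5) / n)
        zf <- (zf - mean(zf)) / sd(zf)
        r <- 2 * sin(pi * hit$rho[1] / 6)
        # noise orthogonalized against the feature's normal scores in-sample,
        # so the realized latent correlation equals the target exactly and
        # the observed Spearman stays tight around it
        e <- rnorm(n)
        e <- e - zf * sum(e * zf) / sum(zf^2)
        e <- (e - mean(e)) / sd(e)
        r * zf + sqrt(1 - r^2) * e
      } else {
        rnorm(n)
      }
    })
    out[[v]] <- exp(1.5 + 1.1 * z)
  }
  out
}

#' Proportion of participants passing a food challenge
#'
#' Trial bookkeeping helper: the percentage of participants passing a
#' double-blind placebo-controlled food challenge, on the 0-100 scale.
#'
#' @param n_passed,n_total Counts of passing and eligible participants.
#' @return Percentage passing.
#' @examples
#' challenge_pass_rate(21, 51) # 41.2% sustained unresponsiveness
#' @export
challenge_pass_rate <- function(n_passed, n_total) {
  assert_count(n_passed, "n_passed", 0L); assert_count(n_total, "n_total", 1L)
  if (n_passed > n_total) stop("`n_passed` cannot exceed `n_total`", call. = FALSE)
  100 * n_passed / n_total
}
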