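#' Differential-testing specification
#'
#' @param group Name of the two-level grouping column (e.g. SU vs DS).
#' @param stratify Character vector of stratifier columns (timepoint,
#'   stimulation); each stratum is tested and FDR-adjusted separately.
#' @param batch Name of the batch column used as the random effect.
#' @param alpha_raw Raw p-value threshold for significance (0.05).
#' @param alpha_fdr Adjusted (q) threshold (0.1); a readout is significant
#'   only when both hold.
#' @param outlier An [outlier_rule()] applied per feature per stratum before
#'   fitting.
#' @param transform Optional latent transform of the response before fitting:
#'   `"none"`, `"log"` (log1p), or `"logit"` (on the 0-100 scale).
#' @return A list of class `test_spec`.
#' @export
test_spec <- function(group = "group", stratify = character(), batch = "batch",
                      alpha_raw = 0.05, alpha_fdr = 0.1,
                      outlier = outlier_rule(),
                      transform = c("none", "log", "logit")) {
  stopifnot(alpha_raw > 0, alpha_raw < 1, alpha_fdr > 0, alpha_fdr < 1)
  structure(list(group = group, stratify = stratify, batch = batch,
                 alpha_raw = alpha_raw, alpha_fdr = alpha_fdr,
                 outlier = outlier, transform = match.arg(transform)),
            class = "test_spec")
}

#' Mixed-effects likelihood-ratio test for a group effect
#'
#' Fits, by maximum likelihood, (a) an intercept-only model with a random
#' batch intercept and (b) the same model plus the group fixed effect; the
#' statistic is `2 * (logLik(b) - logLik(a))` truncated at zero, referred to
#' a chi-squared distribution with 1 df. With a single batch, or when the
#' batch variance collapses to zero (singular fit), the test degenerates to
#' the ordinary linear-model likelihood-ratio test and is flagged as such.
#'
#' @param values Numeric response.
#' @param group Two-level factor/character.
#' @param batch Batch labels.
#' @return One-row tibble: `chi2`, `p`, `singular_fallback`, `n`.
#' @export
fit_mixed_lrt <- function(values, group, batch) {
  ok <- !is.na(values) & !is.na(group) & !is.na(batch)
  v <- values[ok]; g <- factor(group[ok]); b <- factor(batch[ok])
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  if (min(table(g)) < 3L) stop("need >= 3 observations per group", call. = FALSE)
  if (var(v) == 0) {
    return(tibble::tibble(chi2 = 0, p = 1, singular_fallback = TRUE, n = length(v)))
  }
  fallback <- nlevels(b) < 2L
  chi2 <- NA_real_
  if (!fallback) {
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    fit <- tryCatch({
      m0 <- suppressMessages(lme4::lmer(v ~ 1 + (1 | b), REML = FALSE, control = ctrl))
      m1 <- suppressMessages(lme4::lmer(v ~ g + (1 | b), REML = FALSE, control = ctrl))
      list(m0 = m0, m1 = m1)
    }, error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit$m1, tol = 1e-5)) {
      fallback <- TRUE
    } else {
      chi2 <- max(0, 2 * (as.numeric(logLik(fit$m1)) - as.numeric(logLik(fit$m0))))
    }
  }
  if (fallback) {
    m0 <- lm(v ~ 1); m1 <- lm(v ~ g)
    chi2 <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  }
  tibble::tibble(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 singular_fallback = fallback, n = length(v))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving q values capped at 1; missing p values yield missing q
#' values and are excluded from the family size.
#'
#' @param p Numeric vector of raw p values in \[0, 1\].
#' @return Vector of q values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Per-feature differential analysis with batch-aware mixed models
#'
#' For every feature within every stratum: extreme outliers are removed
#' (Tukey fences, [flag_extreme_outliers()]), the mixed-effects
#' likelihood-ratio test is fitted with batch as random effect, and q values
#' are computed by Benjamini-Hochberg across all features of the stratum.
#' A readout is flagged significant when `p < alpha_raw` and
#' `q < alpha_fdr`. Features entirely missing in one group are skipped with
#' a message.
#'
#' @param features Wide tibble: metadata columns plus numeric feature
#'   columns.
#' @param spec A [test_spec()].
#' @param feature_cols Feature columns; by default every numeric column not
#'   named in the test specification's metadata.
#' @return Tibble of class `cyto_diff`: one row per feature per stratum with
#'   group summaries, `chi2`, `p`, `q`, `significant`, `n_outliers_removed`.
#' @export
differential_analysis <- function(features, spec = test_spec(), feature_cols = NULL) {
  meta <- c(spec$group, spec$batch, spec$stratify, "participant_id", "timepoint")
  feature_cols <- feature_cols %||% setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], meta)
  strata <- if (length(spec$stratify)) {
    dplyr::group_split(dplyr::group_by(features,
                                       dplyr::across(dplyr::all_of(spec$stratify))))
  } else list(features)

  res <- purrr::map_dfr(strata, function(df) {
    glev <- levels(factor(df[[spec$group]]))
    per_feature <- purrr::map_dfr(feature_cols, function(f) {
      v <- df[[f]]; g <- df[[spec$group]]; b <- df[[spec$batch]]
      present <- tapply(!is.na(v), g, any)
      if (!all(present[glev])) {
        message("feature `", f, "` missing in one group; skipped")
        return(NULL)
      }
      drop <- suppressWarnings(flag_extreme_outliers(v, spec$outlier))
      v2 <- v[!drop]; g2 <- g[!drop]; b2 <- b[!drop]
      vt <- switch(spec$transform,
                   none = v2, log = log1p(v2), logit = qlogis(pmin(pmax(
                     v2 / 100, 1e-6), 1 - 1e-6)))
      fit <- tryCatch(fit_mixed_lrt(vt, g2, b2), error = function(e) {
        message("feature `", f, "`: ", conditionMessage(e)); NULL
      })
      if (is.null(fit)) return(NULL)
      tibble::tibble(
        feature = f,
        group1 = glev[1], group2 = glev[2],
        n1 = sum(g2 == glev[1], na.rm = TRUE), n2 = sum(g2 == glev[2], na.rm = TRUE),
        mean1 = mean(v2[g2 == glev[1]], na.rm = TRUE),
        mean2 = mean(v2[g2 == glev[2]], na.rm = TRUE),
        median1 = median(v2[g2 == glev[1]], na.rm = TRUE),
        median2 = median(v2[g2 == glev[2]], na.rm = TRUE),
        chi2 = fit$chi2, p = fit$p, singular_fallback = fit$singular_fallback,
        n_outliers_removed = sum(drop)
      )
    })
    if (!nrow(per_feature)) return(per_feature)
    per_feature$q <- bh_adjust(per_feature$p)
    per_feature$significant <- per_feature$p < spec$alpha_raw &
      per_feature$q < spec$alpha_fdr
    if (length(spec$stratify)) {
      for (s in rev(spec$stratify)) {
        per_feature <- dplyr::bind_cols(
          tibble::tibble(!!s := rep(df[[s]][1], nrow(per_feature))), per_feature)
      }
    }
    per_feature
  })
  class(res) <- c("cyto_diff", class(res))
  attr(res, "spec") <- spec
  res
}

#' Rank-based two-group and paired tests
#'
#' Two-sided Wilcoxon tests: `rank_sum` (Mann-Whitney) for independent
#' groups, `signed_rank` for paired measurements. Exact p values are used
#' for small tie-free samples, a tie-corrected normal approximation
#' otherwise. All-zero paired differences yield p = 1 with a warning.
#'
#' @param x Numeric values (first group, or first paired vector).
#' @param y Second group / paired vector. Alternatively supply `group`.
#' @param group Optional two-level factor splitting `x`.
#' @param mode `"rank_sum"` or `"signed_rank"`.
#' @return One-row tibble: `statistic`, `p`, `mode`.
#' @export
rank_tests <- function(x, y = NULL, group = NULL, mode = c("rank_sum", "signed_rank")) {
  mode <- match.arg(mode)
  if (mode == "rank_sum") {
    if (!is.null(group)) {
      g <- factor(group)
      stopifnot(nlevels(g) == 2L)
      y <- x[g == levels(g)[2]]; x <- x[g == levels(g)[1]]
    }
    ht <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
  } else {
    if (is.null(y) || length(x) != length(y)) {
      stop("signed_rank needs paired vectors of equal length", call. = FALSE)
    }
    d <- x - y
    if (all(d[!is.na(d)] == 0)) {
      warning("all paired differences are zero", call. = FALSE)
      return(tibble::tibble(statistic = 0, p = 1, mode = mode))
    }
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = NULL,
                                       correct = TRUE))
  }
  tibble::tibble(statistic = unname(ht$statistic), p = ht$p.value, mode = mode)
}
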