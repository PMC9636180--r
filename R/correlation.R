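#' Spearman rank correlation with midrank ties
#'
#' Two-sided test; the p value is exact for small tie-free samples
#' (n <= 9) and uses the t approximation otherwise. Complete pairs only
#' (pairwise deletion); zero variance in either vector yields an undefined
#' coefficient, flagged in the `note` column.
#'
#' @param x,y Paired numeric vectors (>= 4 complete pairs).
#' @return One-row tibble: `rho`, `p`, `n`, `note`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          note = "zero variance"))
  }
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = n <= 9 && !ties))
  tibble::tibble(rho = unname(ht$estimate), p = ht$p.value, n = n,
                 note = NA_character_)
}

#' Correlation gate
#' @param rho_min Minimum absolute Spearman coefficient (strict).
#' @param p_max Maximum p value (strict). The screen deliberately gates on
#'   the raw p value; no multiplicity adjustment is applied.
#' @return A list of class `correlation_gate`.
#' @export
correlation_gate <- function(rho_min = 0.4, p_max = 0.001) {
  stopifnot(rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1)
  structure(list(rho_min = rho_min, p_max = p_max), class = "correlation_gate")
}

#' Screen cytometry features against serology
#'
#' Tests every (feature, serology) pair by Spearman correlation and flags
#' pairs passing the significance gate (default: `|rho| > 0.4` and
#' `p < 0.001`, on the raw p value). For passing pairs the ordinary linear
#' fit (slope, intercept) is stored for regression-line reporting; the 95%
#' pointwise confidence band is a plotting artifact (see
#' [plot_correlation()]).
#'
#' @param features Wide feature tibble with an id column.
#' @param serology Serology tibble with the same id column.
#' @param gate A [correlation_gate()].
#' @param subset Optional logical/participant-id filter applied to shared
#'   samples (e.g. one outcome arm).
#' @param feature_cols,serology_cols Columns to test; numeric non-metadata by
#'   default.
#' @param id_col Shared sample identifier.
#' @return Tibble of class `cyto_corr`: `feature`, `serology`, `n`, `rho`,
#'   `p`, `passes_screen`, `slope`, `intercept`.
#' @export
screen_serology <- function(features, serology, gate = correlation_gate(),
                            subset = NULL, feature_cols = NULL,
                            serology_cols = NULL, id_col = "participant_id") {
  meta <- c(id_col, "group", "batch", "timepoint")
  feature_cols <- feature_cols %||% setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], meta)
  serology_cols <- serology_cols %||% setdiff(
    names(serology)[vapply(serology, is.numeric, logical(1))], meta)
  shared <- intersect(features[[id_col]], serology[[id_col]])
  if (!length(shared)) stop("no shared samples between tables", call. = FALSE)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  f <- features[match(shared, features[[id_col]]), , drop = FALSE]
  s <- serology[match(shared, serology[[id_col]]), , drop = FALSE]
  grid <- tidyr::expand_grid(feature = feature_cols, serology = serology_cols)
  res <- purrr::pmap_dfr(grid, function(feature, serology) {
    ct <- spearman_cor(f[[feature]], s[[serology]])
    passes <- !is.na(ct$rho) && abs(ct$rho) > gate$rho_min && ct$p < gate$p_max
    slope <- intercept <- NA_real_
    if (passes) {
      cf <- coef(lm(s[[serology]] ~ f[[feature]]))
      intercept <- unname(cf[1]); slope <- unname(cf[2])
    }
    tibble::tibble(feature = feature, serology = serology, n = ct$n,
                   rho = ct$rho, p = ct$p, passes_screen = passes,
                   slope = slope, intercept = intercept)
  })
  class(res) <- c("cyto_corr", class(res))
  attr(res, "gate") <- gate
  res
}
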