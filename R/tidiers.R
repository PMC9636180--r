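#' Tidy a stability ensemble
#'
#' One row per feature: cumulative importance (percentage of iterations in
#' which the feature's score exceeded the selection threshold), mean score,
#' and times selected.
#'
#' @param x A `stab_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return A tibble sorted by cumulative importance.
#' @exportS3Method generics::tidy
tidy.stab_ensemble <- function(x, ...) {
  dplyr::mutate(x$importance, n_selected = as.integer(
    .data$cumulative_importance / 100 * nrow(x$delta)))
}

#' One-row summary of a stability ensemble
#' @param x A `stab_ensemble`.
#' @param ... Unused.
#' @return Tibble: iterations, failures, mean/sd AUC, mean sensitivity and
#'   specificity, number of features ever selected.
#' @exportS3Method generics::glance
glance.stab_ensemble <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$scores),
    n_failed = length(x$failures),
    mean_auc = mean(x$performance$auc, na.rm = TRUE),
    sd_auc = sd(x$performance$auc, na.rm = TRUE),
    mean_sensitivity = mean(x$performance$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$performance$specificity, na.rm = TRUE),
    n_features_selected = sum(colSums(x$delta) > 0)
  )
}

#' Tidy an elastic-net fit
#' @param x An `enet_fit` from [fit_elastic_net()].
#' @param ... Unused.
#' @return Tibble: feature, score (0-100), selected flag.
#' @exportS3Method generics::tidy
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(feature = names(x$scores), score = unname(x$scores),
                 selected = unname(x$scores) > 80)
}

#' @exportS3Method generics::glance
glance.enet_fit <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 specificity = x$specificity, alpha = x$alpha,
                 lambda = x$lambda)
}

#' Volcano-style view of differential results
#'
#' @param object A `cyto_diff` tibble from [differential_analysis()].
#' @param ... Unused.
#' @return A ggplot: group mean difference vs -log10(p), significant
#'   readouts highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.cyto_diff <- function(object, ...) {
  df <- dplyr::mutate(object, diff = .data$mean2 - .data$mean1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "group mean difference", y = expression(-log[10](p)),
                  colour = "p < 0.05 & q < 0.1") +
    ggplot2::theme_minimal()
}

#' Cumulative-importance ranking plot
#'
#' @param object A `stab_ensemble`.
#' @param top Number of top-ranked features shown.
#' @param ... Unused.
#' @return A ggplot bar chart of cumulative importance (0-100).
#' @exportS3Method ggplot2::autoplot
autoplot.stab_ensemble <- function(object, top = 20, ...) {
  df <- head(object$importance, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cumulative_importance,
    y = stats::reorder(.data$feature, .data$cumulative_importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cumulative importance (% of iterations selected)",
                  y = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Feature-serology correlation scatter with regression line
#'
#' Scatter of one screened pair with the ordinary least-squares line and its
#' 95% pointwise confidence band.
#'
#' @param features,serology The tables passed to [screen_serology()].
#' @param feature,serology_var Column names of the pair to plot.
#' @param id_col Shared sample identifier.
#' @return A ggplot.
#' @export
plot_correlation <- function(features, serology, feature, serology_var,
                             id_col = "participant_id") {
  shared <- intersect(features[[id_col]], serology[[id_col]])
  df <- tibble::tibble(
    x = features[[feature]][match(shared, features[[id_col]])],
    y = serology[[serology_var]][match(shared, serology[[id_col]])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95) +
    ggplot2::labs(x = feature, y = serology_var) +
    ggplot2::theme_minimal()
}

#' Metacluster annotation heatmap
#'
#' Tile heatmap of median marker expression per metacluster (the matrix a
#' practitioner inspects to annotate clusters).
#'
#' @param profiles The `profiles` tibble from [assign_and_profile()].
#' @return A ggplot.
#' @export
plot_cluster_heatmap <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$marker, y = factor(.data$metacluster),
    fill = .data$median_expression)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "metacluster", fill = "median\nexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
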