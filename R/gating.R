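#' Load and validate a declarative gating tree
#'
#' A gating tree is a hierarchy of marker-threshold predicates defining named
#' immune subsets. Accepted input: a YAML/JSON file path or an equivalent
#' list with a `nodes` entry; each node has `name`, `parent` (`live` is the
#' implicit root = all live cells) and a list of `predicates`, each with
#' `marker`, `relation` (`gte` = at/above threshold, `lt` = below,
#' `within` = two-sided band), and either an explicit numeric `threshold`
#' (length 2 for `within`) or a `key` naming the threshold(s) to look up at
#' gate time (length-2 key vector for bands). Grade predicates such as
#' CD25^hi or CD56^dim are expressed as `gte` against a high threshold key or
#' as a `within` band.
#'
#' @param x File path or list.
#' @param panel Optional [panel_spec()]; when given, every predicate marker
#'   must exist in the panel.
#' @return A list of class `gating_tree` with `nodes` (tibble `name`,
#'   `parent`) and `predicates` (named list).
#' @export
load_gating_tree <- function(x, panel = NULL) {
  doc <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  nodes <- doc$nodes %||% list()
  if (!length(nodes)) {
    return(structure(list(nodes = tibble::tibble(name = character(),
                                                 parent = character()),
                          predicates = list()), class = "gating_tree"))
  }
  nm <- vapply(nodes, function(n) n$name %||% stop("node without name", call. = FALSE),
               character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate population name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  if ("live" %in% nm) stop("`live` is the reserved root name", call. = FALSE)
  parent <- vapply(nodes, function(n) n$parent %||% "live", character(1))
  bad <- setdiff(parent, c("live", nm))
  if (length(bad)) {
    stop("node(s) reference missing parent: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  preds <- lapply(nodes, function(n) {
    lapply(n$predicates %||% list(), function(p) {
      rel <- match.arg(p$relation, c("gte", "lt", "within"))
      if (is.null(p$marker)) stop("predicate without marker in node `", n$name, "`",
                                  call. = FALSE)
      if (!is.null(panel) && !p$marker %in% colnames(panel$locations)) {
        stop("unknown marker `", p$marker, "` in node `", n$name, "`", call. = FALSE)
      }
      list(marker = p$marker, relation = rel,
           threshold = if (!is.null(p$threshold)) as.numeric(p$threshold),
           key = if (!is.null(p$key)) as.character(p$key))
    })
  })
  names(preds) <- nm
  tree <- structure(list(nodes = tibble::tibble(name = nm, parent = parent),
                         predicates = preds), class = "gating_tree")
  topo_order(tree)  # errors on cycles
  tree
}

topo_order <- function(tree) {
  nodes <- tree$nodes
  done <- "live"; order <- character()
  remaining <- nodes$name
  while (length(remaining)) {
    ready <- remaining[nodes$parent[match(remaining, nodes$name)] %in% done]
    if (!length(ready)) stop("gating tree contains a cycle", call. = FALSE)
    order <- c(order, ready); done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' The shipped default gating tree
#'
#' Encodes the standard PBMC subset hierarchy used throughout the package's
#' synthetic cohort: peanut-reactive CD4/CD8 T cells (CD69+CD40L+ / CD69+),
#' naive/CM/EM/TEMRA CD8 differentiation states (CD45RA x CCR7), Treg
#' (CD25hi CD127-), CD4 memory T effectors (CD45RA- CD127+ CD25lo), NKT
#' (CD56+CD3+), naive gamma-delta T cells, plasmablasts (CD27hi CD38hi
#' HLA-DR+ CD19+), memory B cells, classical/intermediate monocytes
#' (CD14+ CD16-/+), mDC1/mDC2 (CD123+/-), and CD56dim CD16+ NK cells.
#'
#' @return A `gating_tree` with 26 named populations.
#' @export
default_gating_tree <- function() {
  path <- system.file("extdata", "gating_tree.yaml", package = "cytoscreen")
  load_gating_tree(path)
}

#' Default thresholds matched to [default_panel()]
#'
#' Scalar positivity thresholds sit in the valley between the panel's
#' negative (0.3) and dim (1.8) locations; `_hi` grade thresholds between
#' the positive (2.4) and high (3.6) locations; the CD56 dim band upper edge
#' between the dim NK and bright NKT locations.
#'
#' @return Named list of thresholds consumed by [apply_gates()].
#' @export
default_thresholds <- function() {
  markers <- colnames(default_panel()$locations)
  thr <- as.list(setNames(rep(1.05, length(markers)), markers))
  thr$CD25_hi <- 3.0; thr$CD27_hi <- 3.0; thr$CD38_hi <- 3.0
  thr$CD56_hi <- 2.35
  thr
}

#' Data-driven positivity threshold for one marker
#'
#' `valley`: the density minimum between the two largest modes of a kernel
#' density estimate. `quantile`: the stated quantile (type-7 interpolation).
#' Unimodal or degenerate input with the valley method falls back to the
#' 0.99 quantile with a warning.
#'
#' @param values Transformed marker vector (>= 100 values recommended).
#' @param method `"valley"` or `"quantile"`.
#' @param q Quantile used by the quantile method (and the fallback).
#' @return A single threshold on the transformed scale.
#' @export
auto_threshold <- function(values, method = c("valley", "quantile"), q = 0.99) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 100) {
    warning("fewer than 100 values for threshold estimation", call. = FALSE)
  }
  if (method == "quantile") {
    return(unname(quantile(values, q, type = 7)))
  }
  peaks <- find_landmarks(values, max_peaks = 2)
  if (length(peaks) < 2) {
    warning("distribution not bimodal; falling back to quantile ", q, call. = FALSE)
    return(unname(quantile(values, q, type = 7)))
  }
  d <- density(values, n = 512)
  between <- d$x > peaks[1] & d$x < peaks[2]
  d$x[between][which.min(d$y[between])]
}

resolve_threshold <- function(pred, thresholds) {
  if (!is.null(pred$threshold)) return(pred$threshold)
  keys <- pred$key %||% pred$marker
  vals <- vapply(keys, function(k) {
    v <- thresholds[[k]]
    if (is.null(v)) stop("no threshold defined for `", k, "` (marker `",
                         pred$marker, "`)", call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  unname(vals)
}

#' Apply a gating tree to transformed events
#'
#' Membership is computed top-down: each node's predicate conjunction is
#' ANDed with its parent's mask, so a child population is always a subset of
#' its parent. Relations: `gte` keeps cells at/above the threshold, `lt`
#' below it, `within` keeps the half-open band `[lo, hi)`.
#'
#' @param events Transformed event tibble.
#' @param tree A `gating_tree`.
#' @param thresholds Named list of thresholds (see [default_thresholds()]).
#' @return A `population_assignment`: list with `membership` (logical cells x
#'   populations matrix, first column `live`) and `parent` (named character).
#' @export
apply_gates <- function(events, tree, thresholds = default_thresholds()) {
  ord <- topo_order(tree)
  n <- nrow(events)
  membership <- matrix(NA, n, length(ord) + 1L,
                       dimnames = list(NULL, c("live", ord)))
  membership[, "live"] <- TRUE
  parent <- c(live = NA_character_,
              setNames(tree$nodes$parent[match(ord, tree$nodes$name)], ord))
  for (nm in ord) {
    mask <- membership[, parent[[nm]]]
    for (p in tree$predicates[[nm]]) {
      x <- events[[p$marker]]
      if (is.null(x)) stop("marker `", p$marker, "` missing from events", call. = FALSE)
      thr <- resolve_threshold(p, thresholds)
      mask <- mask & switch(p$relation,
        gte = x >= thr[1],
        lt = x < thr[1],
        within = {
          if (length(thr) != 2L) stop("`within` predicate on `", p$marker,
                                      "` needs two thresholds", call. = FALSE)
          x >= thr[1] & x < thr[2]
        })
    }
    membership[, nm] <- mask
  }
  structure(list(membership = membership, parent = parent),
            class = "population_assignment")
}

#' Subset frequencies and median signal intensities
#'
#' For every gated population: frequency among its parent and among all live
#' cells (both on the 0-100 scale), and the median transformed intensity
#' (MSI) of each functional marker over member cells. Populations with zero
#' cells yield missing values (reported via a message).
#'
#' @param assignment A `population_assignment` from [apply_gates()].
#' @param events The transformed event tibble the assignment was computed on.
#' @param functional_markers Markers to summarize as MSI features.
#' @return Tidy tibble: `feature_id`, `population`, `kind`
#'   (`frequency_of_parent`, `frequency_of_live`, `msi`), `marker`, `value`.
#' @export
compute_subset_features <- function(assignment, events, functional_markers = character()) {
  m <- assignment$membership
  pops <- setdiff(colnames(m), "live")
  counts <- colSums(m)
  empty <- pops[counts[pops] == 0]
  if (length(empty)) {
    message("population(s) with 0 cells: ", paste(empty, collapse = ", "))
  }
  rows <- purrr::map_dfr(pops, function(p) {
    par <- assignment$parent[[p]]
    n_par <- counts[[par]]
    freq <- tibble::tibble(
      feature_id = paste0(p, c("|freq_parent", "|freq_live")),
      population = p,
      kind = c("frequency_of_parent", "frequency_of_live"),
      marker = NA_character_,
      value = unname(c(if (n_par > 0) 100 * counts[[p]] / n_par else NA_real_,
                       100 * counts[[p]] / counts[["live"]]))
    )
    if (length(functional_markers)) {
      msi <- tibble::tibble(
        feature_id = paste0(p, "|", functional_markers, "|msi"),
        population = p, kind = "msi", marker = functional_markers,
        value = unname(vapply(functional_markers, function(mk) {
          if (counts[[p]] == 0) return(NA_real_)
          median(events[[mk]][m[, p]])
        }, numeric(1)))
      )
      dplyr::bind_rows(freq, msi)
    } else freq
  })
  rows
}

#' Gate a list of samples and collect the manual-gating feature space
#'
#' @param samples Named list of transformed event tibbles.
#' @param tree A `gating_tree`.
#' @param thresholds Named threshold list.
#' @param functional_markers Markers summarized as MSI.
#' @return Tidy tibble with a leading `sample_id` column.
#' @export
extract_gated_features <- function(samples, tree, thresholds = default_thresholds(),
                                   functional_markers = character()) {
  purrr::imap_dfr(samples, function(ev, id) {
    asn <- apply_gates(ev, tree, thresholds)
    out <- compute_subset_features(asn, ev, functional_markers)
    dplyr::bind_cols(tibble::tibble(sample_id = id), out)
  })
}
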