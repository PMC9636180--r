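#' Train a self-organizing map on pooled lineage-marker data
#'
#' Online SOM training on a rectangular grid: each cell is presented once per
#' epoch (seeded random order), the best-matching node is found by Euclidean
#' distance, and the node and its Gaussian grid neighbourhood move towards
#' the cell. The learning rate decays linearly from `alpha[1]` to `alpha[2]`
#' and the neighbourhood radius from `max(grid)/2` down to 0.3 (at which
#' point effectively only the best-matching node updates, letting nodes
#' decouple and settle on distinct populations) over all presentation
#' steps. The codebook is initialized from a seeded sample of the data, so
#' training is fully reproducible.
#'
#' @param x Numeric matrix or tibble of transformed lineage-marker values
#'   (cells x markers); must contain at least as many cells as grid nodes
#'   and no missing values.
#' @param grid Grid dimensions `c(rows, cols)`.
#' @param epochs Passes over the data.
#' @param alpha Start and end learning rates.
#' @param seed Integer seed.
#' @return A `som_model`: codebook (nodes x markers), grid, training
#'   metadata.
#' @export
train_som <- function(x, grid = c(10, 10), epochs = 10, alpha = c(0.05, 0.01),
                      seed = 1) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("input contains missing/non-finite values",
                                           call. = FALSE)
  n_nodes <- prod(grid)
  if (nrow(x) < n_nodes) stop("need at least as many cells as grid nodes", call. = FALSE)
  grid_xy <- as.matrix(expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2])))
  steps <- epochs * nrow(x)
  alphas <- seq(alpha[1], alpha[2], length.out = steps)
  radii <- seq(max(grid) / 2, 0.3, length.out = steps)
  res <- withr::with_seed(seed, {
    codes <- x[sample.int(nrow(x), n_nodes), , drop = FALSE]
    ord <- as.integer(unlist(lapply(seq_len(epochs),
                                    function(e) sample.int(nrow(x)))))
    som_train_cpp(x, codes, ord, alphas, radii, grid_xy)
  })
  dimnames(res) <- list(paste0("node", seq_len(n_nodes)), colnames(x))
  structure(list(codebook = res, grid = grid, grid_xy = grid_xy,
                 epochs = epochs, alpha = alpha, seed = seed,
                 markers = colnames(x)), class = "som_model")
}

#' Map cells to their best-matching SOM node
#'
#' @param model A `som_model`.
#' @param x Cells x markers matrix/tibble on the training markers.
#' @return Integer vector of node indices.
#' @export
map_to_nodes <- function(model, x) {
  x <- as.matrix(x)[, model$markers, drop = FALSE]
  codes <- model$codebook
  d2 <- outer(rowSums(x^2), rowSums(codes^2), "+") - 2 * x %*% t(codes)
  max.col(-d2, ties.method = "first")
}

#' Metacluster SOM nodes to a fixed number of clusters
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) of the codebook vectors, cut at `n_meta` groups. Deterministic
#' by construction; every node is mapped, so no metacluster can be empty of
#' nodes.
#'
#' @param model A `som_model`.
#' @param n_meta Number of metaclusters (study convention: 30).
#' @return A `metaclustering`: list with `map` (node -> metacluster integer
#'   vector), `n_meta`, `linkage`.
#' @export
metacluster <- function(model, n_meta = 30) {
  assert_count(n_meta, "n_meta", 1L)
  n_nodes <- nrow(model$codebook)
  if (n_meta > n_nodes) stop("`n_meta` cannot exceed the node count", call. = FALSE)
  map <- if (n_meta == n_nodes) {
    seq_len(n_nodes)
  } else {
    hc <- hclust(dist(model$codebook), method = "average")
    unname(cutree(hc, k = n_meta))
  }
  structure(list(map = map, n_meta = as.integer(n_meta), linkage = "average"),
            class = "metaclustering")
}

#' Metacluster frequencies and marker medians per sample
#'
#' Assigns every cell to its nearest node, maps nodes to metaclusters, and
#' computes per-sample metacluster frequencies (% of live cells, summing to
#' 100) plus the pooled metacluster x marker median-expression matrix used
#' for annotation heatmaps.
#'
#' @param samples Named list of transformed event tibbles (or one tibble).
#' @param model A `som_model`.
#' @param meta A `metaclustering`.
#' @return List: `frequencies` (tibble `sample_id`, `metacluster`,
#'   `freq_pct`), `profiles` (tibble, pooled median per metacluster and
#'   marker), `assignments` (list of per-sample metacluster vectors).
#' @export
assign_and_profile <- function(samples, model, meta) {
  if (is.data.frame(samples)) samples <- list(sample1 = samples)
  if (is.null(names(samples))) names(samples) <- paste0("sample", seq_along(samples))
  assignments <- lapply(samples, function(s) {
    meta$map[map_to_nodes(model, s[, model$markers, drop = FALSE])]
  })
  levels_mc <- seq_len(meta$n_meta)
  freqs <- purrr::imap_dfr(assignments, function(a, id) {
    tab <- table(factor(a, levels = levels_mc))
    tibble::tibble(sample_id = id, metacluster = levels_mc,
                   freq_pct = 100 * as.numeric(tab) / length(a))
  })
  pooled <- dplyr::bind_rows(lapply(samples, function(s) {
    tibble::as_tibble(as.matrix(s[, model$markers, drop = FALSE]))
  }))
  pooled$metacluster <- unlist(assignments, use.names = FALSE)
  profiles <- pooled |>
    tidyr::pivot_longer(-"metacluster", names_to = "marker") |>
    dplyr::group_by(.data$metacluster, .data$marker) |>
    dplyr::summarise(median_expression = median(.data$value), .groups = "drop")
  list(frequencies = freqs, profiles = profiles, assignments = assignments)
}
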