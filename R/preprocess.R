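#' Transformation specification
#'
#' @param cofactor Positive divisor applied before the inverse hyperbolic
#'   sine variance-stabilizing transform (mass cytometry convention: 5).
#' @param excluded_markers Markers dropped from the lineage set after
#'   transformation (kept in the matrix, flagged) to limit batch effects;
#'   CD127 by default.
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(cofactor = 5, excluded_markers = "CD127") {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("`cofactor` must be a positive number", call. = FALSE)
  }
  structure(list(cofactor = cofactor,
                 excluded_markers = as.character(excluded_markers)),
            class = "transform_spec")
}

event_marker_cols <- function(events) {
  meta <- c("sample_id", "batch", "timepoint", "participant_id", "group")
  nm <- names(events)
  nm[!startsWith(nm, ".") & !nm %in% meta &
       vapply(events, is.numeric, logical(1))]
}

#' Arcsinh-transform an event matrix
#'
#' Maps every marker value `x` to `asinh(x / cofactor)`. Markers listed in
#' `spec$excluded_markers` are transformed and retained but removed from the
#' `lineage_markers` attribute consumed by clustering and alignment.
#'
#' @param events Event tibble (raw scale); non-marker metadata columns are
#'   left untouched.
#' @param spec A [transform_spec()].
#' @param markers Marker columns to transform; autodetected by default.
#' @return The transformed event tibble, with attributes `cofactor` and
#'   `lineage_markers`.
#' @export
arcsinh_transform <- function(events, spec = transform_spec(), markers = NULL) {
  markers <- markers %||% event_marker_cols(events)
  missing_ex <- setdiff(spec$excluded_markers, markers)
  if (length(missing_ex)) {
    warning("excluded marker(s) not present: ", paste(missing_ex, collapse = ", "),
            call. = FALSE)
  }
  out <- events
  out[markers] <- lapply(out[markers], function(x) asinh(x / spec$cofactor))
  attr(out, "cofactor") <- spec$cofactor
  attr(out, "lineage_markers") <- setdiff(markers, spec$excluded_markers)
  out
}

#' Density landmarks (modes) of a marker distribution
#'
#' Local maxima of a Gaussian kernel density estimate (Silverman's
#' rule-of-thumb bandwidth), retaining peaks above a prominence floor and at
#' most `max_peaks` of them (the highest), returned in ascending position.
#'
#' @param values Numeric vector on the transformed scale (>= 50 values
#'   recommended).
#' @param max_peaks Maximum number of landmarks returned.
#' @param bw Kernel bandwidth; Silverman's rule by default.
#' @param prominence Minimum peak density as a fraction of the maximum
#'   density.
#' @return Numeric vector of landmark positions, ascending.
#' @export
find_landmarks <- function(values, max_peaks = 3, bw = NULL, prominence = 0.05) {
  values <- values[is.finite(values)]
  if (!length(values)) return(numeric())
  if (length(unique(values)) == 1L) return(values[1])
  d <- density(values, bw = bw %||% stats::bw.nrd0(values), n = 512)
  y <- d$y
  i <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  i <- i[y[i] >= prominence * max(y)]
  if (!length(i)) i <- which.max(y)
  if (length(i) > max_peaks) i <- i[order(y[i], decreasing = TRUE)][seq_len(max_peaks)]
  sort(d$x[i])
}

new_warp <- function(channel, src = numeric(), tgt = numeric()) {
  stopifnot(length(src) == length(tgt))
  if (length(src) > 1 && (is.unsorted(src, strictly = TRUE) ||
                          is.unsorted(tgt, strictly = TRUE))) {
    stop("warp knots must be strictly increasing", call. = FALSE)
  }
  structure(list(channel = channel, src = src, tgt = tgt), class = "warp_fn")
}

#' Apply a monotone piecewise-linear warp
#'
#' Inside the knot range values are linearly interpolated between
#' source/target knots; beyond the outermost knots the boundary offset is
#' applied as a constant shift, so the map is strictly increasing everywhere
#' and preserves within-sample rank order exactly.
#'
#' @param warp A `warp_fn` (from [landmark_align()]).
#' @param x Numeric vector on the transformed scale.
#' @return Warped values.
#' @export
apply_warp <- function(warp, x) {
  k <- length(warp$src)
  if (k == 0L) return(x)
  if (k == 1L) return(x + (warp$tgt - warp$src))
  y <- approx(warp$src, warp$tgt, xout = x)$y
  lo <- x < warp$src[1]; hi <- x > warp$src[k]
  y[lo] <- x[lo] + (warp$tgt[1] - warp$src[1])
  y[hi] <- x[hi] + (warp$tgt[k] - warp$src[k])
  y
}

# 1-D k-means (Lloyd) with deterministic quantile initialization.
kmeans_1d <- function(x, k) {
  centers <- unname(quantile(x, probs = (seq_len(k) - 0.5) / k, type = 7))
  for (it in 1:100) {
    cl <- vapply(x, function(v) which.min(abs(v - centers)), integer(1))
    new <- vapply(seq_len(k), function(j) {
      if (any(cl == j)) mean(x[cl == j]) else centers[j]
    }, numeric(1))
    if (max(abs(new - centers)) < 1e-10) break
    centers <- new
  }
  list(centers = sort(centers), cluster = cl)
}

#' Landmark alignment of a channel across samples
#'
#' Detects density landmarks per sample, matches them across samples by 1-D
#' k-means on the pooled peak positions (k = the modal per-sample peak
#' count), sets the consensus landmark of each matched group to its mean
#' position, and warps each sample with a monotone piecewise-linear map so
#' its landmarks land on the consensus. Samples with no usable landmarks get
#' an identity warp (reported via a message).
#'
#' @param samples Named list of event tibbles sharing `channel`.
#' @param channel Marker column to align.
#' @param max_peaks Maximum landmarks per sample.
#' @return A list with `samples` (aligned tibbles) and `warps` (list of
#'   `warp_fn`), class `landmark_alignment`.
#' @export
landmark_align <- function(samples, channel, max_peaks = 3) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (is.null(names(samples))) names(samples) <- paste0("sample", seq_along(samples))
  vals <- lapply(samples, function(s) {
    if (!channel %in% names(s)) stop("channel `", channel, "` missing from a sample",
                                     call. = FALSE)
    s[[channel]]
  })
  marks <- lapply(vals, find_landmarks, max_peaks = max_peaks)
  counts <- vapply(marks, length, integer(1))
  usable <- counts > 0
  if (!any(usable)) {
    warps <- lapply(names(samples), new_warp)
    names(warps) <- names(samples)
    message("no landmarks detected on `", channel, "`; identity warps used")
    return(structure(list(samples = samples, warps = warps),
                     class = "landmark_alignment"))
  }
  tab <- table(counts[usable])
  k <- as.integer(names(tab)[which.max(tab)])
  pooled <- unlist(marks[usable], use.names = FALSE)
  km <- kmeans_1d(pooled, k)
  consensus <- km$centers

  warps <- vector("list", length(samples))
  names(warps) <- names(samples)
  out <- samples
  for (i in seq_along(samples)) {
    pk <- marks[[i]]
    if (!length(pk)) {
      warps[[i]] <- new_warp(channel)
      message("sample `", names(samples)[i], "` has no landmarks on `",
              channel, "`; identity warp")
      next
    }
    cl <- vapply(pk, function(v) which.min(abs(v - consensus)), integer(1))
    src <- tgt <- numeric()
    for (j in sort(unique(cl))) {
      cand <- pk[cl == j]
      src <- c(src, cand[which.min(abs(cand - consensus[j]))])
      tgt <- c(tgt, consensus[j])
    }
    keep <- c(TRUE, diff(src) > 1e-9) & c(TRUE, diff(tgt) > 1e-9)
    warps[[i]] <- new_warp(channel, src[keep], tgt[keep])
    out[[i]][[channel]] <- apply_warp(warps[[i]], samples[[i]][[channel]])
  }
  structure(list(samples = out, warps = warps), class = "landmark_alignment")
}

#' Uniform random subsampling of (live) cells
#'
#' @param events Event tibble.
#' @param n Target number of cells (study convention: 50,000 live cells).
#' @param seed Integer seed.
#' @param live_mask Optional logical vector marking live cells; all cells are
#'   treated as live when absent.
#' @return Event tibble with `min(n, available)` rows, sampled without
#'   replacement.
#' @export
subsample_live <- function(events, n = 50000, seed = 1, live_mask = NULL) {
  assert_count(n, "n", 1L)
  pool <- if (is.null(live_mask)) seq_len(nrow(events)) else which(live_mask)
  if (length(pool) <= n) {
    if (length(pool) < n) {
      warning(sprintf("only %d live cells available (requested %d)",
                      length(pool), n), call. = FALSE)
    }
    return(events[pool, , drop = FALSE])
  }
  idx <- withr::with_seed(seed, sample(pool, n))
  events[sort(idx), , drop = FALSE]
}

#' Extreme-outlier rule
#'
#' @param coef Fence multiplier on the interquartile range; 3.0 flags
#'   "extreme" outliers (1.5 would flag ordinary ones).
#' @param quartile_type Quantile interpolation convention (R type 7 =
#'   linear interpolation, the default of the source ecosystem).
#' @return A list of class `outlier_rule`.
#' @export
outlier_rule <- function(coef = 3, quartile_type = 7) {
  if (!is.numeric(coef) || coef < 0) stop("`coef` must be >= 0", call. = FALSE)
  structure(list(coef = coef, quartile_type = quartile_type),
            class = "outlier_rule")
}

#' Flag extreme outliers by Tukey fences
#'
#' Values below `Q1 - coef*IQR` or above `Q3 + coef*IQR` are flagged.
#' Missing values are never flagged; with fewer than 4 non-missing values
#' nothing is flagged and a warning is raised.
#'
#' @param values Numeric vector.
#' @param rule An [outlier_rule()].
#' @return Logical vector the length of `values`.
#' @export
flag_extreme_outliers <- function(values, rule = outlier_rule()) {
  out <- rep(FALSE, length(values))
  ok <- !is.na(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 non-missing values; no outliers flagged", call. = FALSE)
    return(out)
  }
  q <- quantile(values[ok], c(0.25, 0.75), type = rule$quartile_type, names = FALSE)
  iqr <- q[2] - q[1]
  out[ok] <- values[ok] < q[1] - rule$coef * iqr | values[ok] > q[2] + rule$coef * iqr
  out
}
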