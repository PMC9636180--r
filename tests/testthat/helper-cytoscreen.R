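# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# k well-separated Gaussian blobs in d dimensions as a panel_spec
blob_panel <- function(k, d = max(3, k), sep = 2.3, spread = 0.25) {
  loc <- matrix(0.3, k, d,
                dimnames = list(LETTERS[seq_len(k)], paste0("M", seq_len(d))))
  for (i in seq_len(k)) loc[i, ((i - 1) %% d) + 1] <- 0.3 + sep
  panel_spec(loc, setNames(rep("lineage", d), paste0("M", seq_len(d))),
             spread = spread)
}

blob_events <- function(k, n_cells, seed, props = NULL, d = max(3, k)) {
  props <- props %||% setNames(rep(1 / k, k), LETTERS[seq_len(k)])
  generate_events(list(participant_id = "S1", batch = "B1"),
                  blob_panel(k, d), props, n_cells = n_cells, seed = seed)
}

# transformed-scale marker matrix of a blob_events tibble
blob_matrix <- function(ev, d) {
  asinh(as.matrix(ev[paste0("M", seq_len(d))]) / 5)
}

small_feature_table <- function(seed, n_su = 20, n_ds = 26, n_features = 123,
                                n_informative = 2, effect_size = 1.5, ...) {
  cfg <- cohort_config(seed = seed, n_su = n_su, n_ds = n_ds,
                       n_features = n_features, n_informative = n_informative,
                       effect_size = effect_size, ...)
  cohort <- generate_cohort(cfg)
  generate_feature_table(cohort, cfg)
}

# brute-force Benjamini-Hochberg: q_i = min_{j >= i} p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) qs[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  out <- numeric(m)
  out[o] <- qs
  out
}

# all permutations of 1..n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}
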