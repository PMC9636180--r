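# Synthetic staining panel: per-population marker locations on the
# arcsinh-transformed scale. Levels: negative 0.3, dim/lo 1.7-1.8,
# positive 2.4-3.0, hi 3.6; population spread 0.25 so neighbouring levels
# sit >2 sd apart and threshold gates recover mixture proportions.

POS <- 2.4; NEG <- 0.3; HI <- 3.6; LO <- 1.8

default_population_profiles <- function() {
  lineage <- c("CD3", "CD4", "CD8", "CD45RA", "CCR7", "CD25", "CD127", "CD56",
               "CD16", "CD14", "HLADR", "CD19", "CD27", "CD38", "CD11c",
               "CD123", "gdTCR", "CD69", "CD40L")
  functional <- c("CD57", "IFNg", "IL4", "GzB")
  pops <- c("pr_cd4", "treg", "mem_teff_cd4", "naive_cd4",
            "pr_cd8", "naive_cd8", "cm_cd8", "em_cd8", "temra_cd8",
            "nkt", "naive_gd", "plasmablast", "memory_b",
            "classical_mono", "intermediate_mono", "mdc1", "mdc2", "nk_dim")
  loc <- matrix(NEG, length(pops), length(c(lineage, functional)),
                dimnames = list(pops, c(lineage, functional)))
  hi <- function(p, m, v) loc[p, m] <<- v
  for (p in c("pr_cd4", "treg", "mem_teff_cd4", "naive_cd4",
              "pr_cd8", "naive_cd8", "cm_cd8", "em_cd8", "temra_cd8",
              "nkt", "naive_gd")) hi(p, "CD3", POS)
  for (p in c("pr_cd4", "treg", "mem_teff_cd4", "naive_cd4")) hi(p, "CD4", POS)
  for (p in c("pr_cd8", "naive_cd8", "cm_cd8", "em_cd8", "temra_cd8")) hi(p, "CD8", POS)
  for (p in c("naive_cd4", "naive_cd8", "temra_cd8", "naive_gd")) hi(p, "CD45RA", POS)
  for (p in c("pr_cd4", "naive_cd4", "naive_cd8", "cm_cd8", "naive_gd")) hi(p, "CCR7", POS)
  hi("treg", "CD25", HI); hi("mem_teff_cd4", "CD25", LO)
  for (p in c("mem_teff_cd4", "naive_cd4")) hi(p, "CD127", POS)
  hi("nkt", "CD56", 3.0); hi("nk_dim", "CD56", 1.7)
  for (p in c("intermediate_mono", "nk_dim")) hi(p, "CD16", POS)
  for (p in c("classical_mono", "intermediate_mono")) hi(p, "CD14", POS)
  for (p in c("plasmablast", "memory_b", "classical_mono", "intermediate_mono",
              "mdc1", "mdc2")) hi(p, "HLADR", POS)
  for (p in c("plasmablast", "memory_b")) hi(p, "CD19", POS)
  hi("plasmablast", "CD27", HI); hi("memory_b", "CD27", POS)
  hi("plasmablast", "CD38", HI); hi("memory_b", "CD38", POS)
  for (p in c("classical_mono", "intermediate_mono", "mdc1", "mdc2")) hi(p, "CD11c", POS)
  hi("mdc1", "CD123", POS)
  hi("naive_gd", "gdTCR", POS)
  for (p in c("pr_cd4", "pr_cd8")) hi(p, "CD69", POS)
  hi("pr_cd4", "CD40L", POS)
  # functional markers (not gated on by the default tree)
  for (p in c("em_cd8", "temra_cd8", "nk_dim")) { hi(p, "CD57", 2.0); hi(p, "GzB", 2.2) }
  for (p in c("em_cd8", "temra_cd8", "mem_teff_cd4")) hi(p, "IFNg", 1.8)
  for (p in c("pr_cd4", "mem_teff_cd4")) hi(p, "IL4", 1.6)
  list(locations = loc,
       roles = setNames(rep(c("lineage", "functional"),
                            c(length(lineage), length(functional))),
                        c(lineage, functional)))
}

default_population_proportions <- function() {
  c(pr_cd4 = 0.03, treg = 0.04, mem_teff_cd4 = 0.08, naive_cd4 = 0.15,
    pr_cd8 = 0.02, naive_cd8 = 0.08, cm_cd8 = 0.05, em_cd8 = 0.07,
    temra_cd8 = 0.05, nkt = 0.03, naive_gd = 0.03, plasmablast = 0.02,
    memory_b = 0.06, classical_mono = 0.12, intermediate_mono = 0.05,
    mdc1 = 0.03, mdc2 = 0.04, nk_dim = 0.05)
}

#' Staining panel specification
#'
#' A panel is the bridge between the synthetic-event generator and the gating
#' tree: per-population marker locations (on the arcsinh-transformed scale),
#' marker roles (lineage vs functional), and the within-population spread.
#'
#' @param locations Numeric matrix, populations x markers, of transformed-scale
#'   means.
#' @param roles Named character vector mapping each marker to
#'   `"lineage"` or `"functional"`.
#' @param spread Within-population standard deviation on the transformed scale.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(locations, roles, spread = 0.25) {
  locations <- as.matrix(locations)
  if (anyDuplicated(colnames(locations))) stop("marker names must be unique", call. = FALSE)
  if (!all(colnames(locations) %in% names(roles))) {
    stop("every marker needs a role", call. = FALSE)
  }
  stopifnot(spread > 0)
  structure(list(locations = locations, roles = roles[colnames(locations)],
                 spread = spread), class = "panel_spec")
}

#' Default synthetic panel (19 lineage + 4 functional markers, 18 populations)
#' @return A [panel_spec()].
#' @export
default_panel <- function() {
  pr <- default_population_profiles()
  panel_spec(pr$locations, pr$roles, spread = 0.25)
}

#' Markers of a panel by role
#' @param panel A [panel_spec()].
#' @param role `"lineage"`, `"functional"` or `"all"`.
#' @return Character vector of marker names.
#' @export
panel_markers <- function(panel, role = c("all", "lineage", "functional")) {
  role <- match.arg(role)
  m <- colnames(panel$locations)
  if (role == "all") m else m[panel$roles == role]
}

#' Simulate single-cell events for one sample
#'
#' Draws `n_cells` cells from the given population mixture. Marker intensities
#' are Gaussian around the panel's per-population locations on the
#' arcsinh-transformed scale, then mapped back to the raw scale via
#' `sinh(x) * cofactor`, so that [arcsinh_transform()] recovers approximately
#' Gaussian per-population values. A per-channel batch shift (sd `batch_sd`,
#' seeded by the batch label) is added on the transformed scale. The true
#' population of every cell is kept in the `.true_population` column, which is
#' excluded from all analysis paths.
#'
#' @param participant One-row tibble (or list) with `participant_id` and
#'   `batch`.
#' @param panel A [panel_spec()].
#' @param proportions Named vector of true population fractions (must sum
#'   to 1 within 1e-6); names must be rows of the panel.
#' @param n_cells Number of cells to draw.
#' @param seed Integer seed.
#' @param batch_sd Standard deviation of the per-channel batch shift.
#' @param cofactor Arcsinh cofactor used for the raw-scale mapping.
#' @return Tibble: `sample_id`, `batch`, raw marker columns,
#'   `.true_population`.
#' @export
generate_events <- function(participant, panel = default_panel(), proportions,
                            n_cells = 5000, seed = 1, batch_sd = 0,
                            cofactor = 5) {
  assert_count(n_cells, "n_cells", 1L)
  if (is.null(names(proportions)) ||
      !all(names(proportions) %in% rownames(panel$locations))) {
    stop("`proportions` must be named by panel populations", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  markers <- colnames(panel$locations)
  batch <- as.character(participant$batch %||% "B1")
  batch_num <- suppressWarnings(as.integer(gsub("\\D", "", batch)))
  if (is.na(batch_num)) batch_num <- sum(utf8ToInt(batch))
  shift <- if (batch_sd > 0) {
    withr::with_seed(derive_seeds(batch_num, 1, "batchshift"),
                     rnorm(length(markers), 0, batch_sd))
  } else rep(0, length(markers))

  withr::with_seed(seed, {
    pop <- sample(names(proportions), n_cells, replace = TRUE, prob = proportions)
    z <- panel$locations[pop, , drop = FALSE] +
      matrix(rnorm(n_cells * length(markers), 0, panel$spread),
             n_cells, length(markers)) +
      matrix(shift, n_cells, length(markers), byrow = TRUE)
    raw <- sinh(z) * cofactor
    colnames(raw) <- markers
    out <- tibble::as_tibble(raw)
    out$sample_id <- as.character(participant$participant_id %||% "S1")
    out$batch <- batch
    out$.true_population <- pop
    dplyr::relocate(out, "sample_id", "batch")
  })
}
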