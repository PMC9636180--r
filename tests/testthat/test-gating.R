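test_that("the shipped gating tree parses and validates", {
  tree <- default_gating_tree()
  expect_s3_class(tree, "gating_tree")
  expect_gte(nrow(tree$nodes), 16)
  expect_true(all(c("pr_cd4", "pr_cd8", "naive_cd8", "em_cd8", "temra_cd8",
                    "treg", "nkt", "plasmablast", "memory_b", "classical_mono",
                    "intermediate_mono", "mdc1", "mdc2", "nk_dim",
                    "mem_teff_cd4", "naive_gd") %in% tree$nodes$name))

  empty <- load_gating_tree(list(nodes = list()))
  expect_equal(nrow(empty$nodes), 0)

  expect_error(load_gating_tree(list(nodes = list(
    list(name = "a", parent = "ghost")))), "missing parent")
  expect_error(load_gating_tree(list(nodes = list(
    list(name = "a"), list(name = "a")))), "duplicate")
  expect_error(load_gating_tree(list(nodes = list(
    list(name = "a", parent = "b"), list(name = "b", parent = "a")))),
    "cycle")
  expect_error(
    load_gating_tree(list(nodes = list(list(
      name = "a", predicates = list(list(marker = "NOPE", relation = "gte"))))),
      panel = default_panel()),
    "unknown marker")
})

test_that("auto thresholds find the valley between modes", {
  withr::with_seed(3, {
    mix <- c(rnorm(2000, 0, 0.2), rnorm(2000, 2, 0.2))
  })
  thr <- auto_threshold(mix, "valley")
  expect_gt(thr, 0.7); expect_lt(thr, 1.3)

  expect_equal(auto_threshold(1:100, "quantile", q = 0.5), 50.5)

  expect_warning(thr2 <- auto_threshold(rep(1, 200), "valley"), "quantile")
  expect_equal(thr2, 1)
})

test_that("gate masks equal hand-computed boolean masks on a toy", {
  ev <- tibble::tibble(CD3 = c(5, 5, 5, 0, 0, 5), CD4 = c(5, 5, 0, 0, 5, 0))
  tree <- load_gating_tree(list(nodes = list(
    list(name = "t", parent = "live",
         predicates = list(list(marker = "CD3", relation = "gte", threshold = 2))),
    list(name = "t_cd4", parent = "t",
         predicates = list(list(marker = "CD4", relation = "gte", threshold = 2))),
    list(name = "t_cd4neg", parent = "t",
         predicates = list(list(marker = "CD4", relation = "lt", threshold = 2))),
    list(name = "copy_of_t", parent = "t")
  )))
  asn <- apply_gates(ev, tree, thresholds = list())
  t_mask <- ev$CD3 >= 2
  expect_identical(unname(asn$membership[, "t"]), t_mask)
  expect_identical(unname(asn$membership[, "t_cd4"]), t_mask & ev$CD4 >= 2)
  expect_identical(unname(asn$membership[, "t_cd4neg"]), t_mask & ev$CD4 < 2)
  # predicate-free node inherits the parent mask unchanged
  expect_identical(asn$membership[, "copy_of_t"], asn$membership[, "t"])
  # sibling gates on one marker partition the parent
  expect_false(any(asn$membership[, "t_cd4"] & asn$membership[, "t_cd4neg"]))
  expect_identical(asn$membership[, "t_cd4"] | asn$membership[, "t_cd4neg"],
                   asn$membership[, "t"])
  expect_error(apply_gates(ev, load_gating_tree(list(nodes = list(
    list(name = "x", parent = "live",
         predicates = list(list(marker = "CD3", relation = "gte")))))),
    thresholds = list()), "CD3")
})

test_that("subset features report frequencies and MSI correctly", {
  ev <- tibble::tibble(CD3 = c(rep(5, 30), rep(0, 90)),
                       CD57 = c(1, 2, 3, rep(0, 117)))
  tree <- load_gating_tree(list(nodes = list(
    list(name = "t", parent = "live",
         predicates = list(list(marker = "CD3", relation = "gte", threshold = 2))),
    list(name = "bright", parent = "t",
         predicates = list(list(marker = "CD57", relation = "gte", threshold = 0.5)))
  )))
  asn <- apply_gates(ev, tree, list())
  sf <- compute_subset_features(asn, ev, functional_markers = "CD57")
  get <- function(p, k) sf$value[sf$population == p & sf$kind == k]
  expect_equal(get("t", "frequency_of_parent"), 25)      # 30 of 120 live
  expect_equal(get("t", "frequency_of_live"), 25)
  expect_equal(get("bright", "frequency_of_parent"), 10) # 3 of 30 T cells
  expect_equal(sf$value[sf$population == "bright" & sf$kind == "msi"], 2)

  # zero-cell population yields NA with a message
  tree2 <- load_gating_tree(list(nodes = list(
    list(name = "none", parent = "live",
         predicates = list(list(marker = "CD3", relation = "gte", threshold = 99))))))
  asn2 <- apply_gates(ev, tree2, list())
  expect_message(sf2 <- compute_subset_features(asn2, ev, "CD57"), "0 cells")
  expect_true(is.na(sf2$value[sf2$kind == "msi"]))
})

test_that("gating hierarchy invariants hold on synthetic events", {
  props <- cohort_truth(
    generate_cohort(cohort_config(seed = 2)))$population_proportions
  pr <- props[props$participant_id == "P001", ]
  ev <- generate_events(list(participant_id = "P001", batch = "B1"),
                        default_panel(), setNames(pr$proportion, pr$population),
                        n_cells = 30000, seed = 8)
  tv <- arcsinh_transform(ev)
  asn <- apply_gates(tv, default_gating_tree(), default_thresholds())
  sf <- compute_subset_features(asn, tv)
  live <- sf[sf$kind == "frequency_of_live", ]
  for (p in live$population) {
    par <- asn$parent[[p]]
    if (par != "live") {
      expect_lte(live$value[live$population == p],
                 live$value[live$population == par] + 1e-9)
    }
  }
  # exhaustive, mutually exclusive CD8 differentiation states sum to 100
  cd8 <- sf[sf$kind == "frequency_of_parent" &
              sf$population %in% c("naive_cd8", "cm_cd8", "em_cd8", "temra_cd8"), ]
  expect_equal(sum(cd8$value), 100, tolerance = 1e-9)

  # gated frequencies recover true mixture proportions (binomial error;
  # the EM gate also captures the EM-phenotype peanut-reactive CD8 cells)
  truth_frac <- setNames(pr$proportion, pr$population)
  for (p in c("naive_cd8", "temra_cd8", "nkt", "classical_mono")) {
    expected <- 100 * truth_frac[[p]]
    se <- 100 * sqrt(truth_frac[[p]] * (1 - truth_frac[[p]]) / 30000)
    expect_lt(abs(live$value[live$population == p] - expected), 4 * se + 0.25)
  }
})
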