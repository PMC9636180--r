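test_that("cohort generation respects arm sizes, batches and determinism", {
  cfg <- cohort_config(seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 51)
  expect_equal(sum(co$group == "SU"), 21)
  expect_equal(sum(co$group == "DS"), 30)
  expect_equal(length(unique(co$batch)), 3)
  expect_identical(co, generate_cohort(cfg))

  co2 <- generate_cohort(cohort_config(seed = 3, timepoints = c("BL", "wk104")))
  expect_equal(nrow(co2), 102)
  expect_equal(length(unique(co2$participant_id)), 51)

  tr0 <- cohort_truth(generate_cohort(cohort_config(seed = 1, n_informative = 0)))
  expect_equal(nrow(tr0$informative_features), 0)

  expect_error(cohort_config(n_su = 1), "n_su")
  expect_error(cohort_config(n_informative = 200, n_features = 100), "exceed")
  expect_error(cohort_config(effect_size = -1), "effect_size")
})

test_that("event generator draws the requested mixture", {
  ev <- blob_events(1, 500, seed = 2, props = c(A = 1))
  expect_true(all(ev$.true_population == "A"))
  expect_equal(nrow(ev), 500)

  ev2 <- blob_events(2, 10000, seed = 4, props = c(A = 0.7, B = 0.3))
  frac <- mean(ev2$.true_population == "A")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  expect_error(blob_events(2, 100, seed = 1, props = c(A = 0.7, B = 0.2)),
               "sum to 1")

  # same population, two batches, no batch shift: channel means agree
  pan <- blob_panel(1)
  a <- generate_events(list(participant_id = "x", batch = "B1"), pan,
                       c(A = 1), 4000, seed = 5, batch_sd = 0)
  b <- generate_events(list(participant_id = "y", batch = "B2"), pan,
                       c(A = 1), 4000, seed = 6, batch_sd = 0)
  expect_lt(max(abs(colMeans(blob_matrix(a, 3)) -
                    colMeans(blob_matrix(b, 3)))), 0.05)
})

test_that("feature table has the study shape, bounded frequencies, injected effects", {
  cfg <- cohort_config(seed = 9, n_su = 20, n_ds = 26)
  co <- generate_cohort(cfg)
  ft <- generate_feature_table(co, cfg)
  feats <- grep("^feat_", names(ft), value = TRUE)
  expect_equal(nrow(ft), 46)
  expect_equal(length(feats), 123)
  info <- attr(ft, "feature_info")
  fr <- info$feature[info$kind == "frequency"]
  expect_true(all(as.matrix(ft[fr]) >= 0 & as.matrix(ft[fr]) <= 100))
  expect_true(all(as.matrix(ft[feats]) >= 0 | info$kind == "msi"))
  expect_identical(ft, generate_feature_table(co, cfg))

  # null cohort: two-sample t statistics behave like noise
  big_t <- unlist(lapply(1:3, function(s) {
    cfg0 <- cohort_config(seed = s, effect_size = 0, batch_sd = 0)
    f0 <- generate_feature_table(generate_cohort(cfg0), cfg0)
    vapply(grep("^feat_", names(f0), value = TRUE), function(f) {
      abs(t.test(f0[[f]] ~ f0$group)$statistic)
    }, numeric(1))
  }))
  expect_gte(mean(big_t < 4), 0.99)
})

test_that("serology coupling hits its rank-correlation targets", {
  cfg <- cohort_config(seed = 21, n_su = 20, n_ds = 26)
  co <- generate_cohort(cfg)
  ft <- generate_feature_table(co, cfg)
  tr <- cohort_truth(co)

  # target rho = 0 (no links): independent serology stays weakly correlated
  tr0 <- tr
  tr0$serology_links <- tr$serology_links[0, ]
  se0 <- generate_serology(co, ft, truth = tr0, seed = 5)
  rho0 <- cor(ft[[tr$informative_features$feature[1]]], se0$peanut_sIgE,
              method = "spearman")
  expect_lt(abs(rho0), 0.3)

  # near-comonotone coupling
  tr99 <- tr
  tr99$serology_links <- tibble::tibble(
    feature = tr$informative_features$feature[1],
    serology = "peanut_sIgE", rho = 0.99)
  cfgL <- cohort_config(seed = 2, n_su = 100, n_ds = 100)
  coL <- generate_cohort(cfgL)
  ftL <- generate_feature_table(coL, cfgL)
  tr99$config <- cfgL
  seL <- generate_serology(coL, ftL, truth = tr99, seed = 3)
  expect_gt(cor(ftL[[tr99$serology_links$feature]], seL$peanut_sIgE,
                method = "spearman"), 0.9)

  # moderate target at n = 46 lands in the expected window
  se <- generate_serology(co, ft)
  obs <- mapply(function(f, v) cor(ft[[f]], se[[v]], method = "spearman"),
                tr$serology_links$feature, tr$serology_links$serology)
  expect_true(all(abs(obs - tr$serology_links$rho) < 0.15))

  trbad <- tr
  trbad$serology_links$rho[1] <- 1
  expect_error(generate_serology(co, ft, truth = trbad), "rho")
})

test_that("challenge pass rate is plain trial arithmetic", {
  expect_equal(challenge_pass_rate(21, 51), 100 * 21 / 51)
  expect_equal(challenge_pass_rate(0, 10), 0)
  expect_error(challenge_pass_rate(11, 10), "exceed")
})
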