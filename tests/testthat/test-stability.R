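test_that("moment-preserving simulation reproduces per-participant moments", {
  base <- tibble::tibble(participant_id = c("a", "b"),
                         group = factor(c("SU", "DS")),
                         f1 = c(10, 5), f2 = c(20, 5), f3 = c(30, 5))
  draws <- do.call(rbind, lapply(1:3000, function(s) {
    as.matrix(simulate_dataset(base, simulation_strategy(), seed = s)[, 3:5])
  }))
  a <- draws[seq(1, nrow(draws), by = 2), ]
  expect_equal(mean(a), 20, tolerance = 0.02)
  expect_equal(var(as.vector(a)), var(c(10, 20, 30)), tolerance = 0.05)
  # zero-variance participant: draws equal the mean exactly
  b <- draws[seq(2, nrow(draws), by = 2), ]
  expect_true(all(b == 5))
})

test_that("jitter simulation degenerates to the baseline at small noise", {
  ft <- small_feature_table(seed = 6, n_features = 20)
  feats <- grep("^feat_", names(ft), value = TRUE)
  sim <- simulate_dataset(ft, simulation_strategy("per_feature_jitter",
                                                  noise_scale = 1e-9), seed = 1)
  expect_equal(as.matrix(sim[feats]), as.matrix(ft[feats]), tolerance = 1e-6)
  expect_identical(dim(sim), dim(ft))
  expect_identical(sim$participant_id, ft$participant_id)

  # frequency features stay clipped to [0, 100]
  sim2 <- simulate_dataset(ft, simulation_strategy("per_feature_jitter",
                                                   noise_scale = 10), seed = 2)
  info <- attr(ft, "feature_info")
  fr <- intersect(info$feature[info$kind == "frequency"], feats)
  expect_true(all(as.matrix(sim2[fr]) >= 0 & as.matrix(sim2[fr]) <= 100))

  expect_error(simulate_dataset(ft[1, ], simulation_strategy(), seed = 1),
               ">= 2")
})

test_that("elastic net rewards a perfectly separating feature", {
  withr::with_seed(31, {
    n <- 51
    g <- factor(rep(c("SU", "DS"), c(21, 30)))
    x <- matrix(rnorm(n * 123), n, 123,
                dimnames = list(NULL, sprintf("f%03d", 1:123)))
    x[, 1] <- ifelse(g == "DS", 3, -3) + rnorm(n, 0, 0.1)
  })
  # univariate oracle: the feature separates the classes completely
  expect_equal(mean(x[g == "DS", 1] > max(x[g == "SU", 1])), 1)
  withr::with_seed(5, fit <- fit_elastic_net(x, g, ensemble_config()))
  expect_equal(unname(fit$scores["f001"]), 100)
  expect_gte(fit$auc, 0.95)
  expect_true(max(fit$scores) %in% c(0, 100))

  expect_error(fit_elastic_net(x, factor(rep("SU", n))), "two classes")
})

test_that("permuted labels give chance-level performance", {
  withr::with_seed(77, {
    x <- matrix(rnorm(46 * 60), 46, 60, dimnames = list(NULL, paste0("f", 1:60)))
    g <- factor(rep(c("SU", "DS"), c(20, 26)))
    aucs <- replicate(10, fit_elastic_net(x[, sample(60)], sample(g),
                                          ensemble_config())$auc)
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("selection indicator uses a strict cut at 80", {
  expect_identical(delta_indicator(c(85, 80, 0, 100, 80.0001)),
                   c(1L, 0L, 0L, 1L, 1L))
  expect_error(delta_indicator(120), "\\[0, 100\\]")
})

test_that("cumulative importance equals the selection fraction times 100", {
  expect_equal(unname(cumulative_importance(matrix(1, 300, 1))), 100)
  expect_equal(unname(cumulative_importance(matrix(rep(c(1, 0), 150), 300, 1))), 50)
  expect_equal(unname(cumulative_importance(matrix(0, 300, 2))), c(0, 0))
  expect_error(cumulative_importance(matrix(numeric(), 0, 0)), "empty")
  expect_error(cumulative_importance(matrix(2, 3, 1)), "0/1")
})

test_that("ensembles are reproducible and sane at tiny scale", {
  ft <- small_feature_table(seed = 44, n_su = 9, n_ds = 9, n_features = 15,
                            n_informative = 1, effect_size = 2)
  cfg <- ensemble_config(iterations = 5, seed = 10, k_folds = 3)
  e1 <- suppressWarnings(run_ensemble(ft, simulation_strategy("per_feature_jitter"), cfg))
  e2 <- suppressWarnings(run_ensemble(ft, simulation_strategy("per_feature_jitter"), cfg))
  expect_identical(e1$scores, e2$scores)
  expect_identical(tidy(e1)$cumulative_importance, tidy(e2)$cumulative_importance)
  expect_true(all(e1$scores >= 0 & e1$scores <= 100))
  expect_equal(unname(cumulative_importance(e1$delta)),
               unname(100 * colSums(e1$delta) / nrow(e1$delta)))

  cfg1 <- ensemble_config(iterations = 1, seed = 2, k_folds = 3)
  e3 <- suppressWarnings(run_ensemble(ft, simulation_strategy("per_feature_jitter"), cfg1))
  expect_true(all(tidy(e3)$cumulative_importance %in% c(0, 100)))

  g <- glance(e1)
  expect_equal(g$iterations, 5)
  expect_true(g$mean_auc >= 0 && g$mean_auc <= 1)
})

test_that("rank-formula AUC agrees with an independent ROC implementation", {
  withr::with_seed(55, {
    for (i in 1:20) {
      sc <- rnorm(40)
      lab <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(.4, .6))
      if (!any(lab) || all(lab)) next
      ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
        lab, sc, quiet = TRUE, direction = "<",
        levels = c(FALSE, TRUE)))))
      expect_equal(cytoscreen:::auc_rank(sc, lab), ref)
    }
  })
})
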