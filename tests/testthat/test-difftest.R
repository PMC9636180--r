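test_that("single-batch mixed LRT equals the closed-form OLS likelihood ratio", {
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      g <- sample(rep(c("a", "b"), length.out = n))
      v <- rnorm(n) + 0.5 * (g == "b")
      res <- fit_mixed_lrt(v, g, rep("B1", n))
      rss0 <- sum(lm(v ~ 1)$residuals^2)
      rss1 <- sum(lm(v ~ g)$residuals^2)
      expect_lt(abs(res$chi2 - n * log(rss0 / rss1)), 1e-6)
      expect_true(res$singular_fallback)
    }
  })
})

test_that("degenerate and invalid inputs are handled", {
  expect_equal(fit_mixed_lrt(rep(2, 12), rep(c("a", "b"), 6),
                             rep(c("B1", "B2"), each = 6))[, c("chi2", "p")],
               tibble::tibble(chi2 = 0, p = 1))
  expect_error(fit_mixed_lrt(rnorm(10), rep("a", 10), rep("B1", 10)),
               "two levels")
  expect_error(fit_mixed_lrt(rnorm(6), c("a", "a", rep("b", 4)), rep("B1", 6)),
               ">= 3")
})

test_that("null LRT attains close-to-nominal type-I error with batch effects", {
  withr::with_seed(88, {
    ps <- replicate(400, {
      b <- rep(paste0("B", 1:3), each = 10)
      g <- sample(rep(c("SU", "DS"), 15))
      v <- rnorm(30) + c(B1 = 0.4, B2 = 0, B3 = -0.4)[b]
      fit_mixed_lrt(v, g, b)$p
    })
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  q <- bh_adjust(c(0.01, NA, 0.2))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], p.adjust(c(0.01, 0.2), "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(12, {
    for (i in 1:300) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_brute(p))
      expect_true(all(q >= p - 1e-12))
      expect_false(is.unsorted(q[order(p)]))
    }
  })
})

test_that("differential analysis flags injected effects and controls the null", {
  # power: 5 informative features at effect 1.2, trial arm sizes
  hits <- vapply(1:8, function(s) {
    cfg <- cohort_config(seed = 400 + s, n_informative = 5, effect_size = 1.2)
    ft <- generate_feature_table(generate_cohort(cfg), cfg)
    res <- suppressWarnings(differential_analysis(ft))
    inf <- cohort_truth(ft)$informative_features$feature
    sum(res$significant[res$feature %in% inf])
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.8)

  # null: average number of significant features stays below the FDR budget
  n_sig <- vapply(1:3, function(s) {
    cfg <- cohort_config(seed = 500 + s, effect_size = 0)
    ft <- generate_feature_table(generate_cohort(cfg), cfg)
    sum(suppressWarnings(differential_analysis(ft))$significant)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.1 * 123)

  # single feature: q equals p, not significant at p = 0.2-ish
  cfg1 <- cohort_config(seed = 3, n_features = 2, n_informative = 0)
  ft1 <- generate_feature_table(generate_cohort(cfg1), cfg1)
  res1 <- suppressWarnings(
    differential_analysis(ft1, feature_cols = "feat_001"))
  expect_equal(res1$q, res1$p)
  expect_identical(res1$significant, res1$p < 0.05 & res1$q < 0.1)
})

test_that("rank tests reproduce exact enumeration p-values", {
  # two-group: most extreme arrangement of {1,2,3} vs {10,11,12}
  rs <- rank_tests(c(1, 2, 3), c(10, 11, 12), mode = "rank_sum")
  combos <- utils::combn(6, 3)
  all_vals <- c(1, 2, 3, 10, 11, 12)
  stats <- apply(combos, 2, function(idx) sum(rank(all_vals)[idx]))
  obs <- sum(rank(all_vals)[1:3])
  # doubled one-tail mass of the most extreme of the C(6,3)=20 arrangements
  expect_equal(rs$p, 2 * mean(stats <= obs))
  expect_equal(rs$p, 0.1)

  # paired: five strictly positive (distinct) differences -> exact
  # enumeration over the 2^5 sign patterns gives the extreme-tail p
  sr <- rank_tests(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5), mode = "signed_rank")
  expect_equal(sr$p, 2 / 2^5)

  expect_warning(z <- rank_tests(1:4, 1:4, mode = "signed_rank"), "zero")
  expect_equal(z$p, 1)

  # tie-corrected approximation path runs
  tied <- rank_tests(c(1, 1, 2, 2, 3, 8, 9), group = c(1, 1, 1, 2, 2, 2, 2) ,
                     mode = "rank_sum")
  expect_true(tied$p > 0 && tied$p <= 1)
})
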