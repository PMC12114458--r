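test_that("categorical agreement counts concordant pairs", {
  a <- rep(c("above_or_MBC", "not_MBC"), c(6, 4))
  expect_equal(categorical_agreement(a, a)$percent, 100)
  flip <- ifelse(a == "not_MBC", "above_or_MBC", "not_MBC")
  expect_equal(categorical_agreement(a, flip)$percent, 0)
  mixed <- categorical_agreement(c("above_or_MBC", "not_MBC", "not_MBC"),
                                 c("above_or_MBC", "above_or_MBC", "not_MBC"))
  expect_equal(mixed$n_concordant, 2)
  expect_equal(mixed$percent, 66.7)
  expect_error(categorical_agreement(character(0), character(0)), "no paired")
})

test_that("essential agreement works on the doubling-dilution scale", {
  expect_equal(essential_agreement(0.625, 1.25, k = 1)$n_within_k, 1)
  expect_equal(essential_agreement(0.625, 2.5, k = 1)$n_within_k, 0)
  expect_equal(essential_agreement(0.625, 2.5, k = 2)$n_within_k, 1)
  expect_equal(essential_agreement(4, 4, k = 0)$n_within_k, 1)
  # symmetry and scale invariance
  e1 <- essential_agreement(c(1, 4, 16), c(2, 4, 2))
  e2 <- essential_agreement(c(2, 4, 2), c(1, 4, 16))
  expect_equal(e1$n_within_k, e2$n_within_k)
  e3 <- essential_agreement(10 * c(1, 4, 16), 10 * c(2, 4, 2))
  expect_equal(e1$n_within_k, e3$n_within_k)
  # censored calls leave the denominator
  ec <- essential_agreement(c(1, NA, 4), c(2, 2, 4))
  expect_equal(ec$n_evaluable, 2)
  expect_equal(ec$n_censored, 1)
  expect_error(essential_agreement(-1, 2), "positive")
})

test_that("pooled percentages reproduce the panel's agreement figures", {
  tab <- fcm_agreement_counts()
  expect_equal(nrow(tab), 5)
  expect_equal(pooled_percentage(tab$exact_agree, tab$n_strains), 91.4)
  expect_equal(pooled_percentage(tab$within_1_dilution, tab$n_strains), 98.6)
  expect_equal(pooled_percentage(tab$within_2_dilution, tab$n_strains), 100.0)
  expect_equal(pooled_percentage(14, 14), 100.0)
  expect_equal(pooled_percentage(0, 14), 0.0)
  expect_equal(round_half_up(c(91.45, -2.25, 2.24), 1), c(91.5, -2.3, 2.2))
})

test_that("ROC analysis has the inverted-count orientation", {
  # separable: all killed samples have lower counts than all survivors
  sep <- roc_analysis(c(0.01, 0.02, 0.05, 0.5, 0.8, 1.0),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$sensitivity, 1.0)
  expect_equal(sep$specificity, 1.0)
  expect_true(sep$chosen_threshold > 0.05 && sep$chosen_threshold <= 0.5)
  # uninformative: identical scores
  expect_equal(roc_analysis(rep(0.2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                           FALSE))$auc, 0.5)
  expect_error(roc_analysis(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  # 8-point toy set with one tie
  scores <- c(0.02, 0.05, 0.05, 0.08, 0.3, 0.5, 0.7, 0.9)
  truth <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r <- roc_analysis(scores, truth)
  expect_equal(r$auc, auc_oracle(scores[truth], scores[!truth]))
  # exhaustive small random instances with heavy ties
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    r <- roc_analysis(scores, truth)
    expect_equal(r$auc, auc_oracle(scores[truth], scores[!truth]),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with pROC and its confusion matrix is self-consistent", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- c(stats::rbeta(30, 1, 6), stats::rbeta(30, 5, 2))
  truth <- rep(c(TRUE, FALSE), each = 30)
  r <- roc_analysis(scores, truth)
  ref <- pROC::roc(response = truth, predictor = scores, quiet = TRUE,
                   direction = ">")  # lower scores => positive
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  cm <- r$confusion
  expect_equal(r$sensitivity, cm[1, 1] / sum(cm[, 1]))
  expect_equal(r$specificity, cm[2, 2] / sum(cm[, 2]))
})

test_that("Welch statistics match the hand formula", {
  r <- welch_t(c(10, 11, 12), c(0, 1, 2))
  expect_equal(r$t, 10 * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_lt(r$p, 0.001)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  # near the equal-variance limit, Welch and pooled t agree
  set.seed(8)
  x <- stats::rnorm(200, 0.2); y <- stats::rnorm(200)
  pooled <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(welch_t(x, y)$p, pooled, tolerance = 1e-3)
  # constant but different samples
  diffc <- welch_t(c(5, 5), c(1, 1))
  expect_equal(diffc$p, 0)
})

test_that("Kruskal-Wallis matches the rank formula and is symmetric", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  r <- kruskal_wallis(g)
  expect_equal(r$H, 7.2, tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$H, r$H)
  flat <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
})
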