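roc_df <- function(x, pos) tibble::tibble(score = x,
                                          label = ifelse(pos, "case", "ctrl"))

test_that("midrank AUC matches pair enumeration, including the worked example", {
  expect_equal(auc_midrank(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  withr::with_seed(7, {
    for (rep in 1:100) {
      n <- sample(6:20, 1)
      x <- sample(1:5, n, replace = TRUE)  # heavy ties
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      expect_equal(auc_midrank(x, pos), oracle_auc(x, pos))
    }
  })
})

test_that("AUC equals the Mann-Whitney U statistic over n_pos * n_neg", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      n_pos <- sample(3:10, 1); n_neg <- sample(3:10, 1)
      x_pos <- stats::rnorm(n_pos); x_neg <- stats::rnorm(n_neg)
      u <- suppressWarnings(
        stats::wilcox.test(x_pos, x_neg)$statistic)
      expect_equal(
        auc_midrank(c(x_pos, x_neg),
                    rep(c(TRUE, FALSE), c(n_pos, n_neg))),
        unname(u) / (n_pos * n_neg))
    }
  })
})

test_that("AUC of a negated score is one minus the AUC", {
  withr::with_seed(3, {
    x <- stats::rnorm(30)
    pos <- rep(c(TRUE, FALSE), 15)
    expect_equal(auc_midrank(-x, pos), 1 - auc_midrank(x, pos))
  })
})

test_that("perfect separation yields AUC 1 and a degenerate-free bootstrap", {
  d <- roc_df(c(1, 2, 3, 11, 12, 13), c(rep(FALSE, 3), rep(TRUE, 3)))
  res <- roc_with_bootstrap(d, score, label, positive = "case",
                            n_boot = 100, seed = 1)
  expect_equal(res$auc, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  expect_equal(res$n_pos, 3)
  expect_equal(res$n_neg, 3)
})

test_that("bootstrap CI brackets the AUC and is seed-reproducible", {
  withr::with_seed(5, {
    d <- roc_df(c(stats::rnorm(20, 1), stats::rnorm(20)),
                rep(c(TRUE, FALSE), each = 20))
  })
  r1 <- roc_with_bootstrap(d, score, label, positive = "case",
                           n_boot = 300, seed = 42)
  r2 <- roc_with_bootstrap(d, score, label, positive = "case",
                           n_boot = 300, seed = 42)
  r3 <- roc_with_bootstrap(d, score, label, positive = "case",
                           n_boot = 300, seed = 43)
  expect_identical(r1$boot_auc, r2$boot_auc)
  expect_false(identical(r1$boot_auc, r3$boot_auc))
  expect_lte(r1$ci_low, r1$auc)
  expect_gte(r1$ci_high, r1$auc)
  # single-class labels are rejected
  expect_error(roc_with_bootstrap(roc_df(1:4, rep(TRUE, 4)), score, label),
               class = "imflux_validation_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    x <- stats::rnorm(40)
    pos <- rep(c(TRUE, FALSE), each = 20)
  })
  reference <- as.numeric(pROC::auc(pROC::roc(
    response = pos, predictor = x, quiet = TRUE, direction = "<")))
  expect_equal(auc_midrank(x, pos), reference)
})

test_that("identical classifiers compare with p = 1 under the add-one convention", {
  d <- tibble::tibble(a = c(1, 4, 2, 8, 3, 9), b = c(1, 4, 2, 8, 3, 9),
                      label = rep(c("case", "ctrl"), 3))
  cmp <- compare_classifiers_bootstrap(d, a, b, label, positive = "case",
                                       n_boot = 200, seed = 1)
  expect_equal(cmp$p_one_sided, 1)
  expect_equal(cmp$auc_index, cmp$auc_other)
})

test_that("a strongly better index classifier achieves a small one-sided p", {
  withr::with_seed(17, {
    n <- 20
    idx_score <- c(stats::rnorm(n, 3), stats::rnorm(n, 0))  # separates well
    other <- -idx_score                                     # anti-separates
    d <- tibble::tibble(a = idx_score, b = other,
                        label = rep(c("case", "ctrl"), each = n))
  })
  cmp <- compare_classifiers_bootstrap(d, a, b, label, positive = "case",
                                       n_boot = 2000, seed = 2)
  expect_lte(cmp$p_one_sided, 0.05)
})

test_that("classifier comparison is invariant to monotone score transforms", {
  withr::with_seed(23, {
    d <- tibble::tibble(a = stats::rnorm(30), b = stats::rnorm(30),
                        label = rep(c("case", "ctrl"), 15))
  })
  c1 <- compare_classifiers_bootstrap(d, a, b, label, positive = "case",
                                      n_boot = 200, seed = 9)
  d2 <- dplyr::mutate(d, a = exp(a), b = b^3)
  c2 <- compare_classifiers_bootstrap(d2, a, b, label, positive = "case",
                                      n_boot = 200, seed = 9)
  expect_equal(c1$p_one_sided, c2$p_one_sided)
  expect_equal(c1$d_boot, c2$d_boot)
})

test_that("tidy and glance return the documented shapes", {
  d <- roc_df(c(1, 2, 3, 2, 5, 6), c(rep(FALSE, 3), rep(TRUE, 3)))
  res <- roc_with_bootstrap(d, score, label, positive = "case",
                            n_boot = 50, seed = 4)
  g <- generics::glance(res)
  expect_equal(g$auc, res$auc)
  curve <- generics::tidy(res)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_true(all(diff(curve$tpr) >= 0))
})
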