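test_that("Cohen's kappa identities and matrix properties", {
  expect_equal(cohens_kappa(diag(c(10, 10, 10, 10))), 1)
  expect_equal(cohens_kappa(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(cohens_kappa(matrix(c(9, 1, 1, 9), 2)), 0.8)

  # diagonal confusions of any size and scale are perfect agreement
  set.seed(41)
  for (k in c(2, 3, 5, 7)) {
    expect_equal(cohens_kappa(diag(sample(3:9, k, replace = TRUE))), 1)
  }
  # rank-one confusion = statistical independence = chance agreement
  for (k in c(2, 4)) {
    r <- sample(1:6, k, replace = TRUE)
    cc <- sample(1:6, k, replace = TRUE)
    expect_equal(cohens_kappa(outer(r, cc)), 0)
  }
  expect_error(cohens_kappa(matrix(1, 2, 3)), "square")
})

test_that("agreement statistics follow their defining formulas", {
  r <- r2_rmse(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmse, 0)

  r2 <- r2_rmse(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r2$rmse, sqrt(1 / 3))

  set.seed(42)
  est <- rnorm(30, 20, 3)
  ref <- est + rnorm(30)
  r3 <- r2_rmse(est, ref)
  fit <- lm(est ~ ref)
  expect_equal(r3$r_squared,
               1 - sum(residuals(fit)^2) / sum((est - mean(est))^2))
  expect_equal(r3$rmse, sqrt(mean((est - ref)^2)))

  expect_warning(r4 <- r2_rmse(rep(2, 5), 1:5), "zero variance")
  expect_true(is.na(r4$r_squared))
  expect_error(r2_rmse(1:3, 1:4), "equal length")
})

test_that("MANOVA gate separates gross differences and survives degeneracies", {
  tab <- toy_feature_table(n_per_class = 10, k_classes = 4, sep = 10)
  expect_lt(manova_gate(tab, c("F1", "F2", "F3")), 1e-6)

  # constant column: ridge-regularized retry, with a warning
  tab2 <- tab
  tab2$F3 <- 1
  expect_warning(p2 <- manova_gate(tab2, c("F1", "F2", "F3")))
  expect_true(is.finite(p2) && p2 >= 0 && p2 <= 1)

  expect_error(manova_gate(tab[tab$species == "S1", ], "F1"), "2 classes")
})

test_that("MANOVA p-values are uniform under the null", {
  set.seed(5)
  ps <- replicate(200, {
    tab <- data.frame(tree_id = sprintf("t%02d", 1:40),
                      species = rep(c("A", "B"), each = 20),
                      F1 = rnorm(40), F2 = rnorm(40), F3 = rnorm(40))
    manova_gate(tab, c("F1", "F2", "F3"))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("LOOCV-SVM is exact on separable data and order-invariant", {
  tab <- toy_feature_table(n_per_class = 10, k_classes = 4, sep = 10)
  rep1 <- loocv_svm(tab, c("F1", "F2", "F3"))
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$kappa, 1)
  expect_equal(unname(diag(rep1$confusion)), rep(10L, 4), ignore_attr = TRUE)

  set.seed(7)
  shuffled <- tab[sample(nrow(tab)), ]
  rep2 <- loocv_svm(shuffled, c("F1", "F2", "F3"))
  expect_equal(rep2$confusion, rep1$confusion)
  expect_equal(rep2$accuracy, rep1$accuracy)
  expect_equal(rep2$predictions[sort(names(rep2$predictions))],
               rep1$predictions[sort(names(rep1$predictions))])

  # a singleton class cannot be cross-validated
  bad <- rbind(tab, data.frame(tree_id = "solo", species = "S9",
                               F1 = 0, F2 = 0, F3 = 0))
  expect_error(loocv_svm(bad, c("F1", "F2", "F3")), "S9")
})

test_that("report metrics recompute exactly from the emitted confusion", {
  set.seed(43)
  tab <- toy_feature_table(n_per_class = 12, k_classes = 3, sep = 1.2)
  rep <- loocv_svm(tab, c("F1", "F2", "F3"))
  cm <- rep$confusion
  expect_equal(rep$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(rep$recall, diag(cm) / rowSums(cm))
  expect_equal(rep$precision, diag(cm) / colSums(cm))
  expect_equal(rep$kappa, cohens_kappa(cm))
})

test_that("LOOCV accuracy approaches the Bayes rate on overlapping classes", {
  set.seed(9)
  x <- c(rnorm(50, 0, 1), rnorm(50, 1, 1))
  tab <- data.frame(tree_id = sprintf("t%03d", 1:100),
                    species = rep(c("A", "B"), each = 50), F1 = x)
  rep <- loocv_svm(tab, "F1")
  bayes <- pnorm(0.5)   # optimal rule thresholds at the midpoint
  expect_lt(abs(rep$accuracy - bayes), 0.05)
})

test_that("label shuffling collapses accuracy to chance (no leakage)", {
  set.seed(44)
  tab <- toy_feature_table(n_per_class = 10, k_classes = 4, sep = 10)
  tab$species <- sample(tab$species)
  rep <- loocv_svm(tab, c("F1", "F2", "F3"))
  expect_gte(rep$accuracy, 0.0)
  expect_lte(rep$accuracy, 0.55)   # chance = 0.25; generous binomial bound
})

test_that("subset search enumerates binomial case counts exactly", {
  tab <- toy_feature_table(n_per_class = 5, k_classes = 2, sep = 5, p = 3)

  # tiny pool: full enumeration matches the explicit listing
  res3 <- subset_search(tab, c("F1", "F2", "F3"))
  expect_equal(res3$per_size$n_cases, c(3L, 3L, 1L))
  expect_equal(sum(res3$per_size$n_cases), 7L)

  # counting-only mode reproduces choose(n, k) for the full pools
  pool13 <- paste0("P", 1:13)
  res13 <- subset_search(tab, pool13, count_only = TRUE)
  expect_equal(res13$per_size$n_cases, choose(13, 1:13))
  pool11 <- paste0("V", 1:11)
  res11 <- subset_search(tab, pool11, count_only = TRUE)
  expect_equal(res11$per_size$n_cases, choose(11, 1:11))
  expect_equal(res11$per_size$n_cases[5], 462L)

  expect_error(subset_search(tab, c("F1", "F2"), sizes = 3), "outside")
})

test_that("ties break toward smaller subsets in lexicographic order", {
  tab <- toy_feature_table(n_per_class = 5, k_classes = 2, sep = 5, p = 3)
  stub <- function(cols) 0.5          # every subset equally good
  attr(stub, "stub") <- TRUE
  res <- subset_search(tab, c("F3", "F1", "F2"), evaluator = stub)
  expect_equal(res$best_subset, "F1")  # size 1 first, then alphabetical
  expect_equal(res$best_accuracy, 0.5)
})
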