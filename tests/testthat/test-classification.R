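test_that("PCA matches a full eigendecomposition and uses a fixed sign rule", {
  X <- matrix(c(1, 2, 3, 4, 5,
                2, 1, 4, 3, 6,
                0, 2, 2, 5, 5,
                1, 1, 3, 3, 7) , 5, 4)
  pm <- pca_fit(X)
  # oracle: eigendecomposition of the sample covariance
  eg <- eigen(cov(X), symmetric = TRUE)
  expect_equal(abs(pm$loadings), abs(eg$vectors[, seq_len(ncol(pm$loadings))]),
               tolerance = 1e-10)
  expect_equal(pm$explained, pmax(eg$values, 0)[1:ncol(pm$loadings)] /
                 sum(pmax(eg$values, 0)), tolerance = 1e-10)
  # scores are the centered projections; loadings orthonormal
  expect_equal(pm$scores, sweep(X, 2, colMeans(X)) %*% pm$loadings)
  expect_equal(crossprod(pm$loadings), diag(ncol(pm$loadings)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sign rule: largest-magnitude element positive
  for (j in seq_len(ncol(pm$loadings)))
    expect_gt(pm$loadings[which.max(abs(pm$loadings[, j])), j], 0)
  # explained variances unchanged under global sign flip of the data
  expect_equal(pca_fit(-X)$explained, pm$explained)
  # collinear data: one component carries all variance
  line <- outer(1:6, c(1, -2, 0.5))
  expect_equal(suppressWarnings(pca_fit(line, 3))$explained[1], 1)
  # rank truncation warns
  expect_warning(pca_fit(X[1:3, ], 5), "rank")
  # agreement with prcomp as an independent route
  pr <- prcomp(X)
  expect_equal(abs(pm$loadings), abs(pr$rotation[, 1:ncol(pm$loadings)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("mean-spectrum PCA scores samples and preserves duplicates", {
  recs <- fx_toy_records(n_normal = 3, n_cancer = 3, noise = 0)
  # noise-free: two samples of one class have identical mean spectra
  pm <- mean_spectrum_pca(recs, n_pcs = 4)
  expect_equal(nrow(pm$scores), 6)
  expect_equal(pm$scores[1, ], pm$scores[2, ], tolerance = 1e-10)
  expect_true(all(diff(pm$explained) <= 1e-12))
  expect_lte(sum(pm$explained), 1 + 1e-12)
  expect_error(mean_spectrum_pca(recs[1:2]), "at least 3")
  # a large noiseless class effect is separable along a single PC
  sep <- pm$scores[, 1]
  labs <- vapply(recs, `[[`, "", "pathology")
  gap <- range(sep[labs == "normal"])
  expect_true(all(sep[labs == "cancer"] < gap[1]) ||
                all(sep[labs == "cancer"] > gap[2]))
})

test_that("ANOVA selection equals the squared t test and respects alpha/cap", {
  withr::with_seed(40, {
    for (rep in 1:5) {
      scores <- matrix(rnorm(40 * 6), 40, 6)
      scores[1:20, 2] <- scores[1:20, 2] + 1
      labels <- rep(c("normal", "cancer"), each = 20)
      sel <- anova_select(scores, labels, alpha = 0.05, cap = 3)
      # oracle identity: F = t^2 from the pooled two-sample t test
      for (j in 1:6) {
        tt <- t.test(scores[1:20, j], scores[21:40, j], var.equal = TRUE)
        expect_equal(sel$F[j], unname(tt$statistic^2), tolerance = 1e-10)
        expect_equal(sel$p[j], tt$p.value, tolerance = 1e-10)
      }
      expect_lte(length(sel$selected), 3)
      expect_true(all(sel$p[sel$selected] < 0.05))
    }
  })
  # zero-variance columns are excluded from selection
  scores <- cbind(rep(1, 10), rnorm(10))
  sel0 <- anova_select(scores, rep(c("a", "b"), 5))
  expect_false(1 %in% sel0$selected)
  expect_true(is.na(sel0$p[1]))
})

test_that("ANOVA selection holds its nominal type-I rate under the null", {
  # 200-rep spot check of the 1% level (the full 1000-rep simulation runs
  # in the acceptance suite)
  withr::with_seed(41, {
    n_sel <- replicate(200, {
      sc <- matrix(rnorm(20 * 30), 20, 30)
      sel <- anova_select(sc, rep(c("a", "b"), each = 10), alpha = 0.01)
      if (sel$fallback) 0L else length(sel$selected)
    })
  })
  rate <- mean(n_sel) / 30
  se <- sqrt(0.01 * 0.99 / (200 * 30))
  expect_lt(abs(rate - 0.01), 4 * se)
})

test_that("the Fisher discriminant matches its closed form and MASS::lda", {
  withr::with_seed(42, {
    X <- rbind(matrix(rnorm(100 * 2), 100, 2),
               sweep(matrix(rnorm(100 * 2), 100, 2), 2, c(-2, 0)))
  })
  labels <- rep(c("cancer", "normal"), each = 100)
  ld <- lda_fit(X, labels)
  expect_equal(abs(sum(ld$w * c(1, 0))), 1, tolerance = 1e-2)
  # orientation: cancer mean projects above normal mean
  expect_gt(sum(ld$w * colMeans(X[1:100, ])),
            sum(ld$w * colMeans(X[101:200, ])))
  # threshold is the midpoint of the projected class means
  expect_equal(ld$threshold,
               (sum(ld$w * ld$means["positive", ]) +
                  sum(ld$w * ld$means["negative", ])) / 2)
  # independent oracle: MASS::lda scaling direction
  ml <- MASS::lda(X, grouping = labels)
  cosang <- abs(sum(ld$w * ml$scaling) / sqrt(sum(ml$scaling^2)))
  expect_gt(cosang, 0.999)
  # identical class means: no separation; training AUC at chance
  withr::with_seed(43, X0 <- matrix(rnorm(80 * 3), 80, 3))
  l0 <- rep(c("cancer", "normal"), each = 40)
  ld0 <- lda_fit(X0, l0)
  sc0 <- lda_project(ld0, X0)
  expect_lt(abs(roc_and_auc(sc0, l0)$auc - 0.5), 0.25)
  expect_error(lda_fit(X0[1:41, ], l0[1:41]), "2 spectra per class")
})

test_that("sample-score aggregation implements mean, median and vote", {
  expect_equal(aggregate_sample_score(4.2), 4.2)
  expect_equal(aggregate_sample_score(c(-3, -1, 1, 3)), 0)
  expect_equal(aggregate_sample_score(c(-1, 0, 4)), 1.0)
  expect_equal(aggregate_sample_score(c(-1, 0, 4), "median"), 0)
  expect_equal(aggregate_sample_score(c(-1, 2, 4), "vote", threshold = 0),
               2 / 3 - 0.5)
  expect_error(aggregate_sample_score(numeric()), "no pixel scores")
})

test_that("ROC/AUC: perfect separation, total ties, and the rank oracle", {
  expect_equal(roc_and_auc(c(1, 2, 10, 11), c("normal", "normal", "cancer",
                                              "cancer"))$auc, 1.0)
  expect_equal(roc_and_auc(rep(1, 6), rep(c("normal", "cancer"), 3))$auc, 0.5)
  withr::with_seed(44, {
    for (i in 1:10) {
      sc <- sample(1:5, 30, replace = TRUE) # heavy ties
      lb <- sample(c("cancer", "normal"), 30, replace = TRUE,
                   prob = c(0.5, 0.5))
      if (length(unique(lb)) < 2) next
      ra <- roc_and_auc(sc, lb)
      # Mann-Whitney oracle from rank arithmetic
      n1 <- sum(lb == "cancer"); n0 <- sum(lb == "normal")
      U <- sum(rank(sc)[lb == "cancer"]) - n1 * (n1 + 1) / 2
      expect_equal(ra$auc, U / (n1 * n0), tolerance = 1e-12)
      expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
    }
  })
  expect_error(roc_and_auc(1:3, rep("cancer", 3)), "both classes")
})

test_that("confusion statistics report both conventions", {
  pred <- c(rep("cancer", 15), "normal", rep("normal", 9), "cancer")
  truth <- c(rep("cancer", 16), rep("normal", 10))
  cs <- confusion_stats(pred, truth)
  expect_equal(cs$counts, c(TP = 15, FP = 1, TN = 9, FN = 1))
  expect_equal(cs$sensitivity, 15 / 16)
  expect_equal(cs$specificity, 9 / 10)
  # swapping the positive-class convention swaps the recall pair
  cs2 <- confusion_stats(pred, truth, positive = "normal")
  expect_equal(unname(cs2$sensitivity), unname(cs$specificity))
  expect_equal(unname(cs2$specificity), unname(cs$sensitivity))
  # all correct on a 10 + 16 design
  all_right <- confusion_stats(truth, truth)
  expect_equal(unname(all_right$recall_by_class), c(1, 1))
})

test_that("LOSO yields one out-of-fold prediction per sample; separable case", {
  recs <- fx_toy_records(shift = 2, noise = 0.05)
  cv <- loso_cv(recs, n_pcs_max = 8, cap = 5)
  expect_equal(nrow(cv$per_sample), length(recs))
  expect_length(cv$folds, length(recs))
  expect_equal(cv$per_sample$sample_id,
               vapply(recs, `[[`, "", "sample_id"))
  # strongly shifted cohort: perfect out-of-fold separation
  expect_equal(cv$auc, 1.0)
  expect_equal(unname(cv$sensitivity), 1)
  expect_equal(unname(cv$specificity), 1)
  expect_error(loso_cv(recs[1:3]), "at least 2")
})

test_that("a LOSO fold's model is untouched by its held-out sample", {
  recs <- fx_toy_records(shift = 1.5, noise = 0.1, seed = 9)
  clean <- loso_cv(recs, n_pcs_max = 8, cap = 5)
  for (i in c(1, 4, 8)) {
    corrupted <- recs
    corrupted[[i]]$spectra <- corrupted[[i]]$spectra * 1e6
    dirty <- loso_cv(corrupted, n_pcs_max = 8, cap = 5)
    expect_identical(clean$folds[[i]], dirty$folds[[i]])
  }
})

test_that("label permutation sends the LOSO AUC to chance", {
  recs <- fx_toy_records(shift = 1.5, noise = 0.1, seed = 10)
  null <- permutation_null_auc(recs, n_permutations = 8, seed = 3,
                               n_pcs_max = 8, cap = 5)
  expect_length(null, 8)
  expect_lt(mean(null), 0.85)
  expect_gt(mean(null), 0.15)
})
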