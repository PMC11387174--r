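test_that("rank-based AUROC handles separation, ties and mixed cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # 3 of 4 pairs concordant, no ties
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.3), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC matches the O(n^2) pair-counting oracle exactly", {
  withr::with_seed(123, {
    for (i in 1:100) {
      n <- sample(10:200, 1)
      labels <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "positive", "negative")
      if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
      # coarse scores force plenty of ties
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
    }
  })
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    for (i in 1:10) {
      n <- sample(20:120, 1)
      labels <- rep(c("positive", "negative"), length.out = n)
      scores <- stats::rnorm(n)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = labels, predictor = scores, levels = c("negative",
                                                          "positive"),
        direction = "<", quiet = TRUE)))
      expect_equal(auroc(scores, labels), ref)
    }
  })
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(7, {
    scores <- stats::runif(60)
    labels <- rep(c("positive", "negative"), 30)
    base <- auroc(scores, labels)
    expect_equal(auroc(stats::qlogis(scores), labels), base)
    expect_equal(auroc(100 * scores + 3, labels), base)
    expect_equal(auroc(rank(scores), labels), base)
  })
})

test_that("label permutation pushes AUROC to 0.5 on average", {
  withr::with_seed(99, {
    scores <- stats::runif(200)
    labels <- rep(c("positive", "negative"), 100)
    aucs <- replicate(50, auroc(scores, sample(labels)))
    expect_gt(mean(aucs), 0.45)
    expect_lt(mean(aucs), 0.55)
  })
})

test_that("all four algorithms separate an easy 2-D problem", {
  toy <- separable_toy(n = 40)
  for (alg in c("SVM_RBF", "RF", "GLM", "GBT")) {
    model <- train_model(toy$x, toy$y, algorithm = alg,
                         hyper = if (alg == "SVM_RBF")
                           list(cost = 1, gamma = 1) else list(),
                         seed = 2)
    scores <- predict(model, toy$x)
    expect_true(all(scores >= 0 & scores <= 1))
    expect_equal(auroc(scores, toy$y), 1.0)
    expect_gt(min(scores[toy$y == "positive"]),
              max(scores[toy$y == "negative"]))
  }
})

test_that("permuted labels give near-chance test AUROC for every learner", {
  withr::with_seed(31, {
    x <- matrix(stats::rnorm(400 * 8), 400, 8)
    y <- rep(c("positive", "negative"), 200)
    tr <- sample(400, 200)
    for (alg in c("SVM_RBF", "RF", "GLM", "GBT")) {
      model <- train_model(x[tr, ], y[tr], algorithm = alg, seed = 31)
      auc <- auroc(predict(model, x[-tr, ]), y[-tr])
      expect_gte(auc, 0.35)
      expect_lte(auc, 0.65)
    }
  })
})

test_that("training is deterministic: same seed, same manifest and scores", {
  toy <- separable_toy(n = 30)
  for (alg in c("SVM_RBF", "RF", "GLM", "GBT")) {
    a <- train_model(toy$x, toy$y, algorithm = alg, seed = 8)
    b <- train_model(toy$x, toy$y, algorithm = alg, seed = 8)
    expect_identical(a$manifest, b$manifest)
    expect_identical(predict(a, toy$x), predict(b, toy$x))
  }
})

test_that("prediction is stateless and batch-size independent", {
  toy <- separable_toy(n = 30)
  model <- train_model(toy$x, toy$y, seed = 1)
  batch <- predict(model, toy$x)
  onebyone <- vapply(seq_len(nrow(toy$x)), function(i)
    predict(model, toy$x[i, , drop = FALSE]), numeric(1))
  expect_equal(batch, onebyone)
})

test_that("models reject mismatched feature layouts", {
  ds <- small_benchmark(seed = 5, n_sites = 40)
  x <- encode_windows(ds$train, c("NAC", "EIIP"))
  model <- train_model(x, ds$train$label, seed = 1)
  x_other <- encode_windows(ds$test, c("NAC", "CP"))
  expect_error(predict(model, x_other), "layout mismatch")
  x13 <- encode_windows(substr(ds$test$window, 5, 17), c("NAC", "EIIP"))
  expect_error(predict(model, x13), "mismatch")
  expect_error(train_model(matrix(1, 10, 3),
                           rep(c("positive", "negative"), 5)),
               "constant")
})

test_that("evaluation metrics recompute from the confusion counts", {
  # hand-built scores giving confusion TP=3 FP=1 TN=3 FN=1 at 0.5
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.3, 0.4)
  labels <- c("positive", "positive", "positive", "positive",
              "negative", "negative", "negative", "negative")
  rep <- m7Gsub:::eval_scores(scores, labels, threshold = 0.5)
  expect_identical(rep$confusion,
                   c(TP = 3L, FP = 1L, TN = 3L, FN = 1L))
  expect_equal(rep$sn, 0.75)
  expect_equal(rep$sp, 0.75)
  expect_equal(rep$acc, 0.75)
  expect_identical(sum(rep$confusion), rep$n)
  cc <- rep$confusion
  expect_equal(rep$sn, cc["TP"] / (cc["TP"] + cc["FN"]), ignore_attr = TRUE)
  expect_equal(rep$sp, cc["TN"] / (cc["TN"] + cc["FP"]), ignore_attr = TRUE)
  expect_equal(rep$acc, (cc["TP"] + cc["TN"]) / sum(cc), ignore_attr = TRUE)
  # perfect scores: every metric 1
  perf <- m7Gsub:::eval_scores(c(1, 1, 0, 0),
                               c("positive", "positive",
                                 "negative", "negative"))
  expect_equal(unlist(perf[c("auroc", "acc", "sn", "sp")]),
               c(auroc = 1, acc = 1, sn = 1, sp = 1))
  # single-class test set: AUROC NA with warning, the rest reported
  expect_warning(one <- m7Gsub:::eval_scores(c(0.9, 0.8),
                                             c("positive", "positive")),
                 "single-class")
  expect_true(is.na(one$auroc))
  expect_equal(one$sn, 1)
})

test_that("the RBF grid search scans the lattice and returns its argmax", {
  grid <- default_svm_grid()
  expect_identical(grid$log2_C, seq(-3L, 9L, 2L))
  expect_identical(grid$log2_gamma, seq(-15L, -3L, 2L))
  toy <- separable_toy(n = 60)
  res <- grid_search_svm(toy$x, toy$y, seed = 4)
  expect_identical(dim(res$surface), c(7L, 7L))
  expect_false(anyNA(res$surface))
  expect_equal(res$best_auroc, max(res$surface))
  expect_equal(res$surface[paste0("2^", res$best_log2_gamma),
                           paste0("2^", res$best_log2_C)],
               res$best_auroc)
  # 1x1 grid returns that cell
  one <- grid_search_svm(toy$x, toy$y,
                         grid = list(log2_C = 0L, log2_gamma = -2L),
                         seed = 4)
  expect_identical(dim(one$surface), c(1L, 1L))
  expect_equal(one$best_cost, 1)
  expect_equal(one$best_gamma, 2^-2)
})

test_that("grid-search ties resolve toward smaller cost then gamma", {
  toy <- separable_toy(n = 40)
  # on perfectly separable data many cells tie at AUROC 1
  res <- grid_search_svm(toy$x, toy$y, seed = 4)
  tied <- which(res$surface == res$best_auroc, arr.ind = TRUE)
  tied_c <- sort(unique(tied[, "col"]))
  expect_identical(paste0("2^", res$best_log2_C),
                   colnames(res$surface)[tied_c[1]])
})
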