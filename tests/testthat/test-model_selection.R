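test_that("combo enumeration yields 63 distinct canonical subsets", {
  combos <- all_encoder_combos()
  expect_length(combos, 63L)
  keys <- vapply(combos, paste, character(1), collapse = "+")
  expect_identical(anyDuplicated(keys), 0L)
  # each combo is in canonical internal order
  canon <- c("OH", "NAC", "ANF", "PKC", "CP", "EIIP")
  for (cc in combos) {
    expect_identical(cc, canon[canon %in% cc])
  }
})

test_that("the feature-combination search ranks all 63 subsets", {
  ds <- small_benchmark(seed = 13, n_sites = 50, L = 11)
  res <- search_feature_combos(ds, seed = 13)
  expect_identical(nrow(res), 63L)
  expect_identical(res$rank, 1:63)
  expect_false(is.unsorted(rev(res$auroc)))
  # argmax consistency against a brute-force re-scan
  expect_equal(res$auroc[1], max(res$auroc))
  # reproducible under the same seed
  res2 <- search_feature_combos(ds, seed = 13)
  expect_identical(res, res2)
})

test_that("a composition-driven signal ranks NAC above ANF alone", {
  # windows whose label depends only on dinucleotide composition:
  # positives are GC-dinucleotide rich, negatives AU-rich
  withr::with_seed(17, {
    make_win <- function(rich) {
      pool <- if (rich) c("G", "C", "G", "C", "A", "U") else
        c("A", "U", "A", "U", "G", "C")
      s <- sample(pool, 21, replace = TRUE)
      s[11] <- "G"
      paste(s, collapse = "")
    }
    wins <- data.frame(
      transcript_id = paste0("w", 1:120),
      position = 100L,
      window = c(vapply(1:60, function(i) make_win(TRUE), character(1)),
                 vapply(1:60, function(i) make_win(FALSE), character(1))),
      label = rep(c("positive", "negative"), each = 60),
      stringsAsFactors = FALSE)
    sp <- split_train_test(wins, seed = 17)
    ds <- structure(list(train = sp$train, test = sp$test,
                         manifest = list(regulator = "synthetic",
                                         window_length = 21L)),
                    class = "dataset_split")
    res <- search_feature_combos(ds, seed = 17)
    expect_lt(match("NAC", res$combo), match("ANF", res$combo))
  })
})

test_that("the window sweep rebuilds the dataset per length", {
  gen <- generate_synthetic(synthetic_spec(n_transcripts = 15L,
                                           transcript_length = 600L,
                                           n_positive_sites = 60L,
                                           seed = 21L))
  sw <- sweep_window_lengths(gen$transcripts, gen$sites,
                             lengths = c(11L, 21L), seed = 21L)
  expect_named(sw$reports, c("11", "21"))
  expect_identical(vapply(sw$manifests, `[[`, integer(1), "window_length"),
                   c(`11` = 11L, `21` = 21L))
  # manifests agree on everything but the window length and its windows
  m11 <- sw$manifests[["11"]]; m21 <- sw$manifests[["21"]]
  same <- c("regulator", "seed", "identity_threshold", "train_fraction")
  expect_identical(m11[same], m21[same])
  expect_true(sw$best_length %in% c(11L, 21L))
  expect_error(sweep_window_lengths(gen$transcripts, gen$sites,
                                    lengths = c(20L, 41L)), "odd")
})

test_that("centre-proximal signal keeps short windows competitive", {
  # motif within +/- 3 nt of the centre: a 9-nt window already sees all
  # of the signal, an 81-nt window mostly dilutes it
  spec <- synthetic_spec(n_transcripts = 30L, transcript_length = 900L,
                         n_positive_sites = 150L, motif = "GxAG",
                         motif_offset = 0L, noise_rate = 0, seed = 23L)
  gen <- generate_synthetic(spec)
  sw <- sweep_window_lengths(gen$transcripts, gen$sites,
                             lengths = c(21L, 81L), seed = 23L)
  expect_gte(sw$reports[["21"]]$auroc, sw$reports[["81"]]$auroc - 0.05)
})

test_that("algorithm comparison evaluates four learners on one test set", {
  ds <- small_benchmark(seed = 29, n_sites = 60, L = 11)
  reps <- compare_algorithms(ds, seed = 29,
                             grid = list(log2_C = c(-1L, 1L),
                                         log2_gamma = c(-7L, -3L)))
  expect_named(reps, c("SVM_RBF", "RF", "GLM", "GBT"))
  expect_length(attr(reps, "test_hash"), 1L)
  for (r in reps) {
    expect_s3_class(r, "eval_report")
    expect_identical(r$n, nrow(ds$test))
  }
})

test_that("cross-prediction diagonals equal each model's own evaluation", {
  specs <- list(
    A = synthetic_spec(n_transcripts = 15L, transcript_length = 500L,
                       n_positive_sites = 50L, motif = "GxAG",
                       regulator = "METTL1", seed = 31L),
    B = synthetic_spec(n_transcripts = 15L, transcript_length = 500L,
                       n_positive_sites = 50L, motif = "GxxG",
                       regulator = "WDR4", seed = 37L))
  datasets <- lapply(specs, make_benchmark, L = 21L)
  names(datasets) <- c("METTL1", "WDR4")
  fits <- lapply(datasets, fit_predictor, tune = FALSE, seed = 31L)
  models <- lapply(fits, `[[`, "model")
  cp <- cross_predict(models, datasets)
  expect_identical(dim(cp$auroc_matrix), c(2L, 2L))
  for (r in names(datasets)) {
    expect_identical(cp$auroc_matrix[r, r], fits[[r]]$report$auroc)
  }
  expect_true(all(cp$positive_rate_matrix >= 0 &
                    cp$positive_rate_matrix <= 1))
  # threshold 0 calls every positive window positive
  cp0 <- cross_predict(models, datasets, threshold = 0)
  expect_true(all(cp0$positive_rate_matrix == 1))
})

test_that("models sharing a planted motif cross-predict each other", {
  specs <- list(
    METTL1 = synthetic_spec(n_transcripts = 20L, transcript_length = 600L,
                            n_positive_sites = 80L, motif = "GxAG",
                            noise_rate = 0, regulator = "METTL1",
                            seed = 41L),
    WDR4 = synthetic_spec(n_transcripts = 20L, transcript_length = 600L,
                          n_positive_sites = 80L, motif = "GxAG",
                          noise_rate = 0, regulator = "WDR4", seed = 43L))
  datasets <- lapply(specs, make_benchmark, L = 21L)
  models <- lapply(lapply(datasets, fit_predictor, tune = FALSE,
                          seed = 41L), `[[`, "model")
  cp <- cross_predict(models, datasets)
  for (i in rownames(cp$auroc_matrix)) {
    for (j in colnames(cp$auroc_matrix)) {
      expect_gte(cp$auroc_matrix[i, j], cp$auroc_matrix[i, i] - 0.1)
    }
  }
})

test_that("cross-prediction refuses mismatched models", {
  ds <- small_benchmark(seed = 47, n_sites = 40, L = 11)
  m1 <- fit_predictor(ds, combo = c("NAC", "EIIP"), tune = FALSE)$model
  m2 <- fit_predictor(ds, combo = c("NAC", "CP"), tune = FALSE)$model
  expect_error(cross_predict(list(a = m1, b = m2), list(a = ds, b = ds)),
               "sharing")
})

test_that("model archives round-trip through save and load", {
  ds <- small_benchmark(seed = 53, n_sites = 40, L = 11)
  fit <- fit_predictor(ds, tune = FALSE, seed = 53)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit$model, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- load_model(path)
  xte <- encode_windows(ds$test, back$combo)
  expect_identical(predict(back, xte), predict(fit$model, xte))
})
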