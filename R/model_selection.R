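#' All non-empty encoder combinations
#'
#' The 63 non-empty subsets of the six encoders, each in canonical
#' internal order, enumerated smallest-first.
#'
#' @return List of 63 character vectors.
#' @export
all_encoder_combos <- function() {
  combos <- list()
  for (size in seq_along(ENCODER_ORDER)) {
    cc <- utils::combn(ENCODER_ORDER, size, simplify = FALSE)
    combos <- c(combos, lapply(cc, resolve_combo))
  }
  combos
}

#' Exhaustive feature-combination search
#'
#' Trains and evaluates one model per non-empty encoder subset (63 in
#' all) on the given train/test split, ranking by independent-test AUROC.
#' Ties are broken toward fewer encoders, then canonical order. Evaluating
#' on the held-out test partition reproduces the selection protocol the
#' reference tables use; pass `validation = "cv"` to rank by
#' cross-validated AUROC on the training partition instead, which keeps
#' the test partition untouched during selection.
#'
#' @param dataset a `dataset_split` from [build_dataset()].
#' @param algorithm learner passed to [train_model()].
#' @param hyper hyperparameters passed to [train_model()].
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @param validation `"test"` (default) or `"cv"`.
#' @param folds CV folds when `validation = "cv"`.
#' @return data.frame with columns `combo`, `n_encoders`, `auroc`,
#'   `rank`, sorted best-first.
#' @export
search_feature_combos <- function(dataset, algorithm = "SVM_RBF",
                                  hyper = list(), config = encoder_config(),
                                  seed = 1L, validation = c("test", "cv"),
                                  folds = 5L) {
  validation <- match.arg(validation)
  combos <- all_encoder_combos()
  combo_key <- vapply(combos, paste, character(1), collapse = "+")
  stopifnot(length(unique(combo_key)) == length(combos))
  aucs <- vapply(combos, function(combo) {
    xtr <- encode_windows(dataset$train, combo, config)
    if (validation == "test") {
      model <- train_model(xtr, dataset$train$label, algorithm, hyper, seed)
      xte <- encode_windows(dataset$test, combo, config)
      auroc(predict(model, xte), dataset$test$label)
    } else {
      cv_auroc(xtr, dataset$train$label, algorithm, hyper, folds, seed)
    }
  }, numeric(1))
  out <- data.frame(combo = combo_key,
                    n_encoders = lengths(combos),
                    auroc = aucs, stringsAsFactors = FALSE)
  ord <- order(-out$auroc, out$n_encoders, match(out$combo, combo_key))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# stratified k-fold CV AUROC for any learner
cv_auroc <- function(x, labels, algorithm, hyper, folds = 5L, seed = 1L) {
  y <- as_label_factor(labels)
  fold_id <- withr::with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  mean(vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    model <- train_model(x[tr, , drop = FALSE], y[tr], algorithm, hyper,
                         seed)
    auroc(predict(model, x[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1)))
}

#' Window-length sweep
#'
#' Rebuilds the dataset at each window length (windows re-extracted;
#' negative sampling, redundancy removal and the split re-run under the
#' same seed so site sets stay aligned), trains one model per length and
#' evaluates on the held-out partition.
#'
#' @param transcripts an [rna_set].
#' @param sites positive-site data.frame for one regulator.
#' @param lengths odd window lengths to test (default 21, 41, 61, 81).
#' @param combo encoder subset (default NAC+EIIP+CP).
#' @param algorithm learner (default SVM_RBF).
#' @param hyper hyperparameters for [train_model()].
#' @param seed integer seed.
#' @param ... passed to [build_dataset()] (e.g. `identity_threshold`).
#' @return List with `reports` (named list of `eval_report` per length),
#'   `manifests` (per-length dataset manifests) and `best_length`.
#' @export
sweep_window_lengths <- function(transcripts, sites,
                                 lengths = c(21L, 41L, 61L, 81L),
                                 combo = c("NAC", "EIIP", "CP"),
                                 algorithm = "SVM_RBF", hyper = list(),
                                 seed = 1L, ...) {
  if (any(lengths %% 2L == 0L)) {
    stop("window lengths must be odd, got: ",
         paste(lengths[lengths %% 2L == 0L], collapse = ", "))
  }
  reports <- list(); manifests <- list()
  for (L in lengths) {
    ds <- build_dataset(transcripts, sites, L = L, seed = seed, ...)
    xtr <- encode_windows(ds$train, combo)
    model <- train_model(xtr, ds$train$label, algorithm, hyper, seed)
    xte <- encode_windows(ds$test, combo)
    reports[[as.character(L)]] <-
      evaluate_model(model, xte, ds$test$label)
    manifests[[as.character(L)]] <- ds$manifest
  }
  aucs <- vapply(reports, `[[`, numeric(1), "auroc")
  list(reports = reports, manifests = manifests,
       best_length = lengths[which.max(aucs)])
}

#' Compare the four learning algorithms on one dataset
#'
#' Trains SVM (tuned by [grid_search_svm()] on the training partition),
#' random forest, logistic regression and gradient boosting on the
#' identical training windows and evaluates all four on the identical
#' test partition.
#'
#' @param dataset a `dataset_split`.
#' @param combo encoder subset.
#' @param seed integer seed.
#' @param grid RBF grid for the SVM (default [default_svm_grid()]).
#' @param config an [encoder_config()].
#' @param svm_validation validation scheme for the SVM grid search.
#' @param folds CV folds for the grid search.
#' @return Named list of `eval_report`s (`SVM_RBF`, `RF`, `GLM`, `GBT`)
#'   with attributes `test_hash` and `svm_hyper`.
#' @export
compare_algorithms <- function(dataset, combo = c("NAC", "EIIP", "CP"),
                               seed = 1L, grid = default_svm_grid(),
                               config = encoder_config(),
                               svm_validation = "cv", folds = 5L) {
  xtr <- encode_windows(dataset$train, combo, config)
  xte <- encode_windows(dataset$test, combo, config)
  tuned <- grid_search_svm(xtr, dataset$train$label, grid,
                           validation = svm_validation, folds = folds,
                           seed = seed)
  reports <- list()
  for (alg in ALGORITHMS) {
    hyper <- if (alg == "SVM_RBF") {
      list(cost = tuned$best_cost, gamma = tuned$best_gamma)
    } else list()
    model <- train_model(xtr, dataset$train$label, alg, hyper, seed)
    reports[[alg]] <- evaluate_model(model, xte, dataset$test$label)
  }
  attr(reports, "test_hash") <- object_hash(list(dataset$test$window,
                                                 dataset$test$label))
  attr(reports, "svm_hyper") <- list(cost = tuned$best_cost,
                                     gamma = tuned$best_gamma)
  reports
}

#' Cross-prediction between regulator models
#'
#' Applies every regulator's model to every regulator's substrate data.
#' Cell (i, j) of the AUROC matrix is model i evaluated on regulator j's
#' held-out test windows (or full window set with `on = "full"`); cell
#' (i, j) of the positive-rate matrix is the fraction of regulator j's
#' positive windows that model i calls positive at `threshold`.
#'
#' @param models named list of `m7g_model`s, one per regulator; all must
#'   share window length and encoder combination.
#' @param datasets named list of `dataset_split`s over the same regulator
#'   names.
#' @param threshold positive-call threshold (default 0.5).
#' @param on evaluate on the `"test"` partition (default) or on the
#'   `"full"` window set (train + test).
#' @param config an [encoder_config()].
#' @return List of class `cross_prediction` with square matrices
#'   `auroc_matrix` and `positive_rate_matrix` (rows = models,
#'   cols = substrate sets).
#' @export
cross_predict <- function(models, datasets, threshold = 0.5,
                          on = c("test", "full"),
                          config = encoder_config()) {
  on <- match.arg(on)
  regs <- names(models)
  stopifnot(!is.null(regs), setequal(regs, names(datasets)))
  combos <- unique(vapply(models, function(m)
    paste(m$combo, collapse = "+"), character(1)))
  Ls <- unique(vapply(models, function(m)
    as.numeric(m$window_length %||% NA_real_), numeric(1)))
  if (length(combos) > 1L || length(Ls) > 1L) {
    stop("cross_predict needs models sharing one encoder combination and ",
         "window length; got combos {", paste(combos, collapse = "; "),
         "} and L {", paste(Ls, collapse = ", "), "}")
  }
  combo <- models[[1L]]$combo
  auc_m <- rate_m <- matrix(NA_real_, length(regs), length(regs),
                            dimnames = list(model = regs, data = regs))
  for (j in regs) {
    wins <- if (on == "test") datasets[[j]]$test else
      rbind(datasets[[j]]$train, datasets[[j]]$test)
    xj <- encode_windows(wins, combo, config)
    pos <- wins$label == "positive"
    for (i in regs) {
      scores <- predict(models[[i]], xj)
      auc_m[i, j] <- auroc(scores, wins$label)
      rate_m[i, j] <- mean(scores[pos] >= threshold)
    }
  }
  structure(list(auroc_matrix = auc_m, positive_rate_matrix = rate_m,
                 threshold = threshold, on = on),
            class = "cross_prediction")
}

#' @export
print.cross_prediction <- function(x, ...) {
  cat("cross-prediction on", x$on, "windows (threshold",
      x$threshold, ")\nAUROC (rows = models, cols = substrate data):\n")
  print(round(x$auroc_matrix, 3))
  cat("positive rate on positive windows:\n")
  print(round(x$positive_rate_matrix, 3))
  invisible(x)
}

#' Fit a regulator predictor end-to-end
#'
#' Convenience wrapper: encodes the training partition, optionally tunes
#' the SVM on it by grid search, trains, and evaluates on the held-out
#' partition.
#'
#' @param dataset a `dataset_split`.
#' @param combo encoder subset (default NAC+EIIP+CP).
#' @param algorithm learner (default SVM_RBF).
#' @param tune if `TRUE` (default for SVM) run [grid_search_svm()] first.
#' @param grid RBF grid when tuning.
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @param validation grid-search validation scheme (`"cv"` or
#'   `"holdout"`).
#' @param folds CV folds for tuning.
#' @return List with `model` (an `m7g_model`), `report` (an
#'   `eval_report` on the test partition) and `tuning` (grid-search
#'   result or `NULL`).
#' @export
fit_predictor <- function(dataset, combo = c("NAC", "EIIP", "CP"),
                          algorithm = "SVM_RBF",
                          tune = identical(algorithm, "SVM_RBF"),
                          grid = default_svm_grid(),
                          config = encoder_config(), seed = 1L,
                          validation = "cv", folds = 5L) {
  xtr <- encode_windows(dataset$train, combo, config)
  tuning <- NULL
  hyper <- list()
  if (tune && algorithm == "SVM_RBF") {
    tuning <- grid_search_svm(xtr, dataset$train$label, grid,
                              validation = validation, folds = folds,
                              seed = seed)
    hyper <- list(cost = tuning$best_cost, gamma = tuning$best_gamma)
  }
  model <- train_model(xtr, dataset$train$label, algorithm, hyper, seed)
  model$manifest$regulator <- dataset$manifest$regulator
  xte <- encode_windows(dataset$test, combo, config)
  report <- evaluate_model(model, xte, dataset$test$label)
  list(model = model, report = report, tuning = tuning)
}

#' Save / load a trained model archive
#'
#' The archive bundles the fitted state and manifest in one RDS file; a
#' sidecar `<path>.manifest.json` carries the manifest in plain text.
#'
#' @param model an `m7g_model`.
#' @param path output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "m7g_model"))
  saveRDS(model, path)
  jsonlite::write_json(model$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "m7g_model")) {
    stop(path, " is not a saved m7Gsub model archive")
  }
  model
}
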