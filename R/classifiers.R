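ALGORITHMS <- c("SVM_RBF", "RF", "GLM", "GBT")

# coerce labels to a factor with levels c("negative", "positive")
as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  labels[labels %in% c("pos", "1")] <- "positive"
  labels[labels %in% c("neg", "0")] <- "negative"
  bad <- setdiff(unique(labels), c("positive", "negative"))
  if (length(bad)) stop("unrecognized label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = c("negative", "positive"))
}

#' Area under the ROC curve (rank-based)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counted 1/2 — the Mann-Whitney U statistic
#' divided by n_pos * n_neg.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels binary labels (`"positive"`/`"negative"`, logical, or
#'   0/1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_label_factor(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  n_pos <- sum(y == "positive")
  n_neg <- sum(y == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both classes present (got ", n_pos, " positive, ",
         n_neg, " negative)")
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[y == "positive"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# orientation of e1071 decision values: the column name "a/b" means a
# positive value votes for class a
svm_score <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1]][1L]
  s <- if (first == "positive") dv[, 1L] else -dv[, 1L]
  # monotone squashing to [0,1]; ranking (hence AUROC) is unchanged
  stats::plogis(unname(s))
}

#' Train a substrate classifier
#'
#' One interface over the four supported algorithms: `SVM_RBF`
#' (radial-basis support vector machine), `RF` (random forest), `GLM`
#' (binomial logistic regression) and `GBT` (gradient-boosted trees).
#' If logistic regression fails to converge (e.g. perfect separation) a
#' ridge penalty of 1e-6 is used instead and noted in the model.
#'
#' @param x feature matrix from [encode_windows()] (plain matrices are
#'   accepted; layout checks are then skipped).
#' @param labels binary labels, one per row of `x`.
#' @param algorithm one of `"SVM_RBF"`, `"RF"`, `"GLM"`, `"GBT"`.
#' @param hyper named list of hyperparameters. SVM: `cost` (default 1),
#'   `gamma` (default 1/ncol). RF: `ntree` (default 500). GBT: `nrounds`
#'   (default 100), `max_depth` (default 6), `eta` (default 0.3).
#' @param seed integer seed for the stochastic learners.
#' @return An object of class `m7g_model` with fields `algorithm`,
#'   `hyper`, `fit`, `blocks`, `combo`, `window_length` and `manifest`.
#' @export
train_model <- function(x, labels, algorithm = "SVM_RBF", hyper = list(),
                        seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  y <- as_label_factor(labels)
  stopifnot(is.matrix(x), nrow(x) == length(y), all(is.finite(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (min(table(y)) < 2L) stop("need at least 2 examples per class")
  if (all(apply(x, 2L, function(col) length(unique(col)) == 1L))) {
    stop("all feature columns are constant; nothing to learn from")
  }
  notes <- character(0)
  fit <- switch(
    algorithm,
    SVM_RBF = {
      cost <- hyper$cost %||% 1
      gamma <- hyper$gamma %||% (1 / ncol(x))
      hyper <- list(cost = cost, gamma = gamma)
      e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE)
    },
    RF = {
      ntree <- hyper$ntree %||% 500L
      hyper <- list(ntree = ntree)
      withr::with_seed(seed, randomForest::randomForest(x, y, ntree = ntree))
    },
    GLM = {
      hyper <- list()
      df <- data.frame(.y = y, x, check.names = FALSE)
      g <- withCallingHandlers(
        stats::glm(.y ~ ., data = df, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities|did not converge",
                    conditionMessage(w))) {
            notes <<- union(notes, "glm_separation_ridge_fallback")
            invokeRestart("muffleWarning")
          }
        })
      if (length(notes) || !g$converged) {
        notes <- union(notes, "glm_separation_ridge_fallback")
        g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = 1e-6)
      }
      g
    },
    GBT = {
      nrounds <- hyper$nrounds %||% 100L
      max_depth <- hyper$max_depth %||% 6L
      eta <- hyper$eta %||% 0.3
      hyper <- list(nrounds = nrounds, max_depth = max_depth, eta = eta)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y == "positive"))
      withr::with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1L,
                      max_depth = max_depth, eta = eta),
        data = dtrain, nrounds = nrounds, verbose = 0L))
    })
  structure(list(
    algorithm = algorithm, hyper = hyper, fit = fit, notes = notes,
    feature_names = colnames(x),
    blocks = attr(x, "blocks"), combo = attr(x, "combo"),
    window_length = attr(x, "window_length"),
    manifest = list(algorithm = algorithm, hyper = hyper,
                    combo = attr(x, "combo"),
                    window_length = attr(x, "window_length"),
                    seed = as.integer(seed),
                    n_train = nrow(x), n_features = ncol(x),
                    data_hash = object_hash(list(x, as.character(y))),
                    versions = list(
                      r = as.character(getRversion()),
                      m7Gsub = as.character(utils::packageVersion("m7Gsub"))))),
    class = "m7g_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# check that a feature matrix matches the layout the model was trained on
check_layout <- function(model, x) {
  if (is.null(model$blocks) || is.null(attr(x, "blocks"))) return(invisible())
  fmt <- function(b) paste(sprintf("%s[%d]", names(b), b), collapse = "+")
  same <- identical(unname(model$blocks), unname(attr(x, "blocks"))) &&
    identical(names(model$blocks), names(attr(x, "blocks")))
  if (!same) {
    stop("feature layout mismatch: model expects ", fmt(model$blocks),
         ", got ", fmt(attr(x, "blocks")))
  }
  if (!is.null(model$window_length) &&
      !is.null(attr(x, "window_length")) &&
      model$window_length != attr(x, "window_length")) {
    stop("window length mismatch: model trained on L = ",
         model$window_length, ", got L = ", attr(x, "window_length"))
  }
  invisible()
}

#' Predict substrate scores
#'
#' Returns a probability-like score in \[0, 1\] per window (higher = more
#' likely a substrate). Scores are deterministic and order-independent;
#' their ranking is what [auroc()] consumes.
#'
#' @param object an `m7g_model`.
#' @param x feature matrix with the same layout the model was trained on.
#' @param ... unused.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
predict.m7g_model <- function(object, x, ...) {
  stopifnot(is.matrix(x))
  check_layout(object, x)
  if (ncol(x) != length(object$feature_names)) {
    stop("feature count mismatch: model expects ",
         length(object$feature_names), " features, got ", ncol(x))
  }
  colnames(x) <- object$feature_names
  scores <- switch(
    object$algorithm,
    SVM_RBF = svm_score(object$fit, x),
    RF = unname(stats::predict(object$fit, x, type = "prob")[, "positive"]),
    GLM = {
      if (inherits(object$fit, "glmnet")) {
        as.numeric(stats::predict(object$fit, x, type = "response"))
      } else {
        df <- as.data.frame(x, check.names = FALSE)
        unname(stats::predict(object$fit, newdata = df, type = "response"))
      }
    },
    GBT = as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(x))))
  pmin(1, pmax(0, scores))
}

#' @export
print.m7g_model <- function(x, ...) {
  cat("m7g_model:", x$algorithm)
  if (!is.null(x$combo)) cat(" on", paste(x$combo, collapse = "+"))
  if (!is.null(x$window_length)) cat(", L =", x$window_length)
  cat("\n  hyperparameters:",
      paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a model on held-out windows
#'
#' Computes AUROC plus threshold metrics (accuracy, sensitivity,
#' specificity) and the confusion counts at `threshold`. With a
#' single-class test set the AUROC is undefined and reported as `NA` with
#' a warning; the threshold metrics are still computed.
#'
#' @param model an `m7g_model`.
#' @param x feature matrix of test windows.
#' @param labels their binary labels.
#' @param threshold score threshold for the positive call (default 0.5).
#' @return An `eval_report` list: `auroc`, `acc`, `sn`, `sp`, `confusion`
#'   (TP, FP, TN, FN), `threshold`, `n`.
#' @export
evaluate_model <- function(model, x, labels, threshold = 0.5) {
  y <- as_label_factor(labels)
  scores <- predict(model, x)
  eval_scores(scores, y, threshold)
}

# metrics from raw scores; shared by evaluate_model and cross_predict
eval_scores <- function(scores, labels, threshold = 0.5) {
  y <- as_label_factor(labels)
  auc <- if (length(unique(y)) < 2L) {
    warning("single-class test set: AUROC undefined, reported as NA")
    NA_real_
  } else {
    auroc(scores, y)
  }
  call_pos <- scores >= threshold
  tp <- sum(call_pos & y == "positive")
  fp <- sum(call_pos & y == "negative")
  tn <- sum(!call_pos & y == "negative")
  fn <- sum(!call_pos & y == "positive")
  structure(list(
    auroc = auc,
    acc = (tp + tn) / length(y),
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    threshold = threshold, n = length(y)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (n = %d, threshold = %.2f)\n  AUROC %.4f  ACC %.4f  Sn %.4f  Sp %.4f\n",
    x$n, x$threshold, x$auroc, x$acc, x$sn, x$sp))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}

#' Default RBF hyperparameter grid
#'
#' Cost exponents span -3..9 and gamma exponents -15..-3 in steps of
#' `step` (default 2, the libsvm-guide convention, giving a 7 x 7 grid).
#'
#' @param step exponent step size.
#' @return List with integer vectors `log2_C` and `log2_gamma`.
#' @export
default_svm_grid <- function(step = 2L) {
  list(log2_C = seq(-3L, 9L, by = step),
       log2_gamma = seq(-15L, -3L, by = step))
}

#' Grid search over the RBF cost/gamma lattice
#'
#' Every (C, gamma) cell is scored by stratified k-fold cross-validated
#' AUROC on the training data (default; `validation = "holdout"` scores on
#' a single stratified 80/20 split instead). Ties are broken toward
#' smaller C, then smaller gamma — the less complex model.
#'
#' @param x training feature matrix.
#' @param labels training labels.
#' @param grid list with `log2_C` and `log2_gamma` (see
#'   [default_svm_grid()]).
#' @param validation `"cv"` (default) or `"holdout"`.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return List with `best_cost`, `best_gamma`, `best_log2_C`,
#'   `best_log2_gamma`, `best_auroc` and `surface` (matrix, rows =
#'   log2_gamma, cols = log2_C).
#' @export
grid_search_svm <- function(x, labels, grid = default_svm_grid(),
                            validation = c("cv", "holdout"), folds = 5L,
                            seed = 1L) {
  validation <- match.arg(validation)
  y <- as_label_factor(labels)
  stopifnot(length(grid$log2_C) >= 1L, length(grid$log2_gamma) >= 1L)

  # stratified fold ids (holdout = fold 1 as validation)
  fold_id <- withr::with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (validation == "cv") {
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      } else {
        n_val <- max(1L, round(0.2 * length(idx)))
        val <- idx[sample.int(length(idx), n_val)]
        id[val] <- 1L
        id[setdiff(idx, val)] <- 2L
      }
    }
    id
  })
  eval_folds <- if (validation == "cv") seq_len(folds) else 1L

  surface <- matrix(NA_real_, nrow = length(grid$log2_gamma),
                    ncol = length(grid$log2_C),
                    dimnames = list(paste0("2^", grid$log2_gamma),
                                    paste0("2^", grid$log2_C)))
  best <- list(auroc = -Inf)
  for (ci in seq_along(grid$log2_C)) {
    for (gi in seq_along(grid$log2_gamma)) {
      cost <- 2^grid$log2_C[ci]
      gamma <- 2^grid$log2_gamma[gi]
      aucs <- vapply(eval_folds, function(f) {
        tr <- fold_id != f
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = cost, gamma = gamma, scale = FALSE)
        auroc(svm_score(fit, x[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      surface[gi, ci] <- mean(aucs)
      # strict improvement keeps the first (smallest C, then gamma) on ties
      if (surface[gi, ci] > best$auroc + 1e-12) {
        best <- list(auroc = surface[gi, ci],
                     log2_C = grid$log2_C[ci],
                     log2_gamma = grid$log2_gamma[gi])
      }
    }
  }
  list(best_cost = 2^best$log2_C, best_gamma = 2^best$log2_gamma,
       best_log2_C = best$log2_C, best_log2_gamma = best$log2_gamma,
       best_auroc = best$auroc, surface = surface,
       validation = validation, folds = folds, seed = as.integer(seed))
}
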