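## ---------------------------------------------------------------------------
## Algorithm adapters
##
## The harness (folds, grid search, metrics, importance) is written against a
## minimal adapter interface -- fit(x, y, params, seed) -> model;
## prob(model, x) -> P(class 1); importance(model, feature_names) -> weights --
## so the cross-validation logic is library-agnostic and testable with the
## deterministic "logistic" adapter. The three gradient-boosting flavours are
## backed by xgboost with different tree-growth policies: "gbdt" grows
## depth-wise on exact splits, "xgboost" depth-wise on histogram splits, and
## "lightgbm" leaf-wise (loss-guided) on histogram splits. "rf" is a
## randomForest bagging ensemble.
## ---------------------------------------------------------------------------

.xgb_fit <- function(x, y, params, seed, tree_method, grow_policy) {
  p <- list(objective = "binary:logistic", eval_metric = "logloss",
            nthread = 1L, seed = seed,
            max_depth = as.integer(params$max_depth %||% 4L),
            eta = params$eta %||% 0.1,
            tree_method = tree_method, grow_policy = grow_policy)
  if (grow_policy == "lossguide")
    p$max_leaves <- as.integer(params$max_leaves %||% 2^p$max_depth)
  d <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = p, data = d,
                     nrounds = as.integer(params$nrounds %||% 100L),
                     verbose = 0)
}

.xgb_prob <- function(model, x) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(x)))
}

.xgb_importance <- function(model, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  tab <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0L) {
    found <- intersect(tab$Feature, feature_names)
    imp[found] <- tab$Gain[match(found, tab$Feature)]
  }
  imp
}

.adapters <- function() {
  boosted <- function(tree_method, grow_policy) list(
    fit = function(x, y, params, seed)
      .xgb_fit(x, y, params, seed, tree_method, grow_policy),
    prob = .xgb_prob,
    importance = .xgb_importance)
  list(
    gbdt = boosted("exact", "depthwise"),
    xgboost = boosted("hist", "depthwise"),
    lightgbm = boosted("hist", "lossguide"),
    rf = list(
      fit = function(x, y, params, seed) {
        set.seed(seed)
        randomForest::randomForest(
          x = x, y = factor(y, levels = c(0L, 1L)),
          ntree = as.integer(params$ntree %||% 500L),
          mtry = as.integer(params$mtry %||% max(1L, floor(sqrt(ncol(x))))),
          nodesize = as.integer(params$nodesize %||% 1L))
      },
      prob = function(model, x)
        as.numeric(stats::predict(model, x, type = "prob")[, "1"]),
      importance = function(model, feature_names) {
        imp <- stats::setNames(numeric(length(feature_names)), feature_names)
        gi <- randomForest::importance(model)[, 1L]
        imp[intersect(names(gi), feature_names)] <-
          gi[intersect(names(gi), feature_names)]
        imp
      }),
    logistic = list(   # deterministic reference adapter
      fit = function(x, y, params, seed) {
        df <- as.data.frame(x)
        names(df) <- paste0("x", seq_len(ncol(x)))
        df$y <- y
        suppressWarnings(stats::glm(y ~ ., data = df,
                                    family = stats::binomial()))
      },
      prob = function(model, x) {
        df <- as.data.frame(x)
        names(df) <- paste0("x", seq_len(ncol(x)))
        as.numeric(stats::predict(model, df, type = "response"))
      },
      importance = function(model, feature_names) {
        co <- stats::coef(model)[-1L]
        co[!is.finite(co)] <- 0
        stats::setNames(abs(co), feature_names)
      }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Supported classification algorithms
#' @return Character vector of adapter names.
#' @export
classifier_algorithms <- function() names(.adapters())

#' Default hyperparameter grid for an algorithm
#'
#' A fixed 3 x 3 x 3 grid over tree depth, learning rate and boosting-round
#' count (for the tree-ensemble adapters: trees, variables per split and
#' node size for the random forest). These are software defaults, exposed
#' so that a custom grid can always be supplied to [cross_validate()].
#'
#' @param algorithm One of [classifier_algorithms()].
#' @return Data frame, one row per grid point.
#' @export
default_grid <- function(algorithm) {
  algorithm <- match.arg(algorithm, classifier_algorithms())
  switch(algorithm,
         rf = expand.grid(ntree = c(100L, 300L, 500L),
                          mtry = c(3L, 5L, 9L),
                          nodesize = c(1L, 3L, 5L)),
         logistic = data.frame(dummy = 1),
         expand.grid(max_depth = c(2L, 4L, 6L),
                     eta = c(0.05, 0.1, 0.3),
                     nrounds = c(50L, 100L, 200L)))
}

## stratified fold assignment: per-class shuffled round-robin, so each
## fold's class proportions are within one sample of the global ones
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_labels <- function(dataset, threshold = 2000) {
  if (!is.data.frame(dataset) || !"sequence" %in% names(dataset))
    stop("dataset must be a data frame with a 'sequence' column",
         call. = FALSE)
  if ("label" %in% names(dataset)) {
    lab <- as.integer(dataset$label)
    if (!all(lab %in% 0:1)) stop("labels must be 0/1", call. = FALSE)
  } else if ("ic50_uM" %in% names(dataset)) {
    lab <- label_by_ic50(dataset$ic50_uM, threshold)
  } else {
    stop("dataset needs a 'label' or 'ic50_uM' column", call. = FALSE)
  }
  lab
}

#' Grid-searched stratified k-fold cross-validation
#'
#' Runs the full training protocol for one algorithm: PseAAC featurization,
#' per-fold standardization (fitted on the training folds only), stratified
#' k-fold cross-validation of every grid point, and selection of the grid
#' point with the best mean out-of-fold ROC-AUC (ties broken by mean
#' accuracy, then by grid order). Reported metrics are the out-of-fold
#' values of the winning grid point; the feature-importance vector comes
#' from a final refit on the full standardized training matrix.
#'
#' @param dataset Data frame with `sequence` and either `label` (0/1) or
#'   `ic50_uM` (labelled through [label_by_ic50()]).
#' @param algorithm One of [classifier_algorithms()].
#' @param grid Data frame of hyperparameter combinations
#'   (default [default_grid()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the complete run is reproducible given the
#'   seed.
#' @param w,scales Featurization parameters, see [featurize()].
#' @param threshold IC50 activity threshold in micromolar.
#' @return Object of class `cv_result`: algorithm, best hyperparameters,
#'   per-fold and mean metrics, normalized 27-component feature-importance
#'   vector, and the seed.
#' @export
cross_validate <- function(dataset, algorithm = "lightgbm",
                           grid = default_grid(algorithm), k = 5L,
                           seed = 1L, w = 0.05, scales = default_scales(),
                           threshold = 2000) {
  algorithm <- match.arg(algorithm, classifier_algorithms())
  adapter <- .adapters()[[algorithm]]
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("empty hyperparameter grid", call. = FALSE)
  y <- .fit_labels(dataset, threshold)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < k)
    stop("need at least k = ", k, " samples per class", call. = FALSE)

  x <- featurize_matrix(dataset$sequence, w = w, scales = scales)
  set.seed(seed)
  folds <- .stratified_folds(y, k)

  metric_names <- c("accuracy", "recall", "precision", "f1", "auc")
  eval_grid_point <- function(params) {
    fold_metrics <- matrix(NA_real_, nrow = k, ncol = length(metric_names),
                           dimnames = list(NULL, metric_names))
    for (fold in seq_len(k)) {
      tr <- folds != fold
      std <- fit_standardizer(x[tr, , drop = FALSE])
      xtr <- apply_standardizer(std, x[tr, , drop = FALSE])
      xte <- apply_standardizer(std, x[!tr, , drop = FALSE])
      model <- adapter$fit(xtr, y[tr], as.list(params), seed + fold)
      prob <- adapter$prob(model, xte)
      fold_metrics[fold, ] <- compute_metrics(y[!tr],
                                              as.integer(prob >= 0.5), prob)
    }
    fold_metrics
  }

  best <- NULL
  for (g in seq_len(nrow(grid))) {
    fm <- eval_grid_point(grid[g, , drop = FALSE])
    mean_auc <- mean(fm[, "auc"], na.rm = TRUE)
    mean_acc <- mean(fm[, "accuracy"])
    if (is.null(best) || mean_auc > best$auc + 1e-12 ||
        (abs(mean_auc - best$auc) <= 1e-12 && mean_acc > best$acc + 1e-12)) {
      best <- list(g = g, auc = mean_auc, acc = mean_acc, fold_metrics = fm)
    }
  }

  std <- fit_standardizer(x)
  final <- adapter$fit(apply_standardizer(std, x), y,
                       as.list(grid[best$g, , drop = FALSE]), seed)
  imp <- adapter$importance(final, pseaac_feature_names())
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    rep(1 / length(imp), length(imp))
  names(imp) <- pseaac_feature_names()

  structure(
    list(algorithm = algorithm,
         best_params = as.list(grid[best$g, , drop = FALSE]),
         fold_metrics = best$fold_metrics,
         mean_metrics = colMeans(best$fold_metrics, na.rm = TRUE),
         importance = imp,
         seed = seed),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("<cv_result> %s (%d folds, seed %d)\n", x$algorithm,
              nrow(x$fold_metrics), x$seed))
  cat("  best params:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  print(round(x$mean_metrics, digits))
  invisible(x)
}

#' Rank features by importance
#'
#' @param result A `cv_result` or fitted [dppiv_classifier()].
#' @return Data frame of `feature` and `weight`, sorted descending by
#'   weight (ties broken by feature index); weights sum to one.
#' @export
rank_feature_importance <- function(result) {
  imp <- if (inherits(result, "cv_result")) result$importance
         else if (inherits(result, "dppiv_classifier")) result$importance
         else stop("expected a cv_result or dppiv_classifier", call. = FALSE)
  imp <- imp / sum(imp)
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = names(imp)[ord], weight = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Fit a DPP-IV inhibitory peptide classifier
#'
#' The main modelling entry point of the machine-learning stage: labels the
#' training peptides by the IC50 threshold, grid-searches the chosen
#' algorithm under stratified 5-fold cross-validation (see
#' [cross_validate()]), then refits the winning configuration on the full
#' standardized training matrix. The returned object carries the exact
#' featurization parameters and the standardizer fitted on the training
#' data, so scoring new candidates replays the training transformation
#' identically.
#'
#' @inheritParams cross_validate
#' @return Object of class `dppiv_classifier` with the fitted model,
#'   cross-validation result, standardizer, feature importances and
#'   featurization settings.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' train <- gen_labeled_peptides(120, 80, seed = 7)
#' fit <- dppiv_classifier(train, algorithm = "rf",
#'                         grid = data.frame(ntree = 200), seed = 7)
#' predict(fit, c("FPL", "FPHFDL"))
#' }
dppiv_classifier <- function(dataset, algorithm = "lightgbm",
                             grid = default_grid(algorithm), k = 5L,
                             seed = 1L, w = 0.05,
                             scales = default_scales(), threshold = 2000) {
  cv <- cross_validate(dataset, algorithm = algorithm, grid = grid, k = k,
                       seed = seed, w = w, scales = scales,
                       threshold = threshold)
  y <- .fit_labels(dataset, threshold)
  x <- featurize_matrix(dataset$sequence, w = w, scales = scales)
  std <- fit_standardizer(x)
  adapter <- .adapters()[[cv$algorithm]]
  model <- adapter$fit(apply_standardizer(std, x), y, cv$best_params, seed)
  structure(
    list(algorithm = cv$algorithm, cv = cv, model = model,
         standardizer = std, importance = cv$importance,
         w = w, scales = .validate_scales(scales), threshold = threshold,
         seed = seed, n_train = nrow(x)),
    class = "dppiv_classifier")
}

#' @export
print.dppiv_classifier <- function(x, digits = 4, ...) {
  cat(sprintf("<dppiv_classifier> %s trained on %d peptides (seed %d)\n",
              x$algorithm, x$n_train, x$seed))
  cat("  cross-validated metrics:\n")
  print(round(x$cv$mean_metrics, digits))
  invisible(x)
}

#' @export
summary.dppiv_classifier <- function(object, ...) {
  cat(sprintf("DPP-IV activity classifier (%s)\n", object$algorithm))
  cat(sprintf("Training peptides: %d; activity threshold: IC50 < %g uM\n",
              object$n_train, object$threshold))
  cat("Best hyperparameters:",
      paste(names(object$cv$best_params), unlist(object$cv$best_params),
            sep = "=", collapse = ", "), "\n\n")
  cat("Out-of-fold metrics (mean over folds):\n")
  print(round(object$cv$mean_metrics, 4))
  cat("\nTop 10 features by importance:\n")
  print(utils::head(rank_feature_importance(object), 10))
  invisible(object)
}

#' Score candidate peptides
#'
#' @param object A fitted [dppiv_classifier()].
#' @param newdata Character vector of candidate sequences.
#' @param threshold High-confidence probability cutoff (default 0.9).
#' @param ... Unused.
#' @return Data frame with `sequence`, `probability` and `high_confidence`.
#' @export
predict.dppiv_classifier <- function(object, newdata, threshold = 0.9, ...) {
  predict_candidates(object, newdata, threshold = threshold)
}

#' Screen candidates for high-confidence predicted inhibitors
#'
#' Featurizes and standardizes candidate sequences exactly as during
#' training, scores them with the fitted model, and flags those whose
#' predicted activity probability reaches the confidence threshold.
#' Sequences with invalid residues are skipped with a warning naming them.
#'
#' @param object A fitted [dppiv_classifier()].
#' @param peptides Character vector of sequences.
#' @param threshold Probability cutoff for the `high_confidence` flag.
#' @return Data frame `sequence`, `probability`, `high_confidence`; skipped
#'   rows carry `NA` probability.
#' @export
predict_candidates <- function(object, peptides, threshold = 0.9) {
  stopifnot(inherits(object, "dppiv_classifier"))
  ok <- vapply(peptides, function(s)
    !inherits(try(validate_sequence(s), silent = TRUE), "try-error"),
    logical(1))
  out <- data.frame(sequence = as.character(peptides),
                    probability = NA_real_,
                    high_confidence = NA,
                    stringsAsFactors = FALSE)
  if (any(!ok))
    warning("skipped invalid sequence(s): ",
            paste(peptides[!ok], collapse = ", "))
  if (any(ok)) {
    x <- featurize_matrix(peptides[ok], w = object$w, scales = object$scales)
    xs <- apply_standardizer(object$standardizer, x)
    prob <- .adapters()[[object$algorithm]]$prob(object$model, xs)
    out$probability[ok] <- prob
    out$high_confidence[ok] <- prob >= threshold
  }
  out
}
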