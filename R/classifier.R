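#' Stratified train/test split of candidate loops
#'
#' @param data A data frame with a label column.
#' @param fraction Fraction assigned to the training set (default 2/3).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param label_col Name of the label column (default `"label"`).
#' @return A list with tibbles `train` and `test`; disjoint, exhaustive,
#'   class proportions preserved within one example per class.
#' @export
split_train_test <- function(data, fraction = 2 / 3, seed = 1,
                             label_col = "label") {
  stopifnot(nrow(data) >= 3, fraction > 0, fraction < 1)
  labels <- data[[label_col]]
  if (length(unique(labels)) < 2) {
    abort("Cannot split a single-class data set.")
  }
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), labels), function(rows) {
      sample(rows, round(fraction * length(rows)))
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(train = as_tibble(data[idx_train, , drop = FALSE]),
       test = as_tibble(data[-idx_train, , drop = FALSE]))
}

#' Train the gradient-boosted loop classifier
#'
#' Fits an XGBoost binary classifier (logistic objective) on a loop
#' feature matrix. The feature schema, hyperparameters, seed, per-feature
#' normalised gain importance and the sentinel values used to impute
#' absent anchor-motif scores at predict time are stored with the model.
#'
#' @param features Feature tibble from [extract_features()] (a `loop_id`
#'   column, if present, is dropped).
#' @param labels Vector of `"positive"`/`"negative"` (or logical/0-1).
#' @param nrounds,max_depth,eta Boosting hyperparameters
#'   (defaults 300 trees, depth 4, learning rate 0.1).
#' @param seed Integer seed (training runs single-threaded so results are
#'   reproducible).
#' @param ... Additional parameters passed to [xgboost::xgb.train()]'s
#'   `params` list.
#' @return An object of class `loop_model`.
#' @export
train_loop_model <- function(features, labels, nrounds = 300, max_depth = 4,
                             eta = 0.1, seed = 1, ...) {
  mat <- feature_matrix(features)
  if (any(grepl("rad21", colnames(mat), ignore.case = TRUE))) {
    abort("Feature schema contains a RAD21 column; RAD21 is labeling-only.")
  }
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("Training labels contain a single class.")
  if (length(y) != nrow(mat)) abort("Labels and features differ in length.")
  if (anyNA(mat)) {
    abort("Training features contain missing values; training candidates must have both anchor motifs.")
  }
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed, ...)
  booster <- withr::with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(mat, label = y, nthread = 1)
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  imp <- xgb_importance_tbl(booster, colnames(mat))
  sentinel <- apply(mat, 2, min) - 1
  structure(
    list(booster = booster, schema = colnames(mat),
         hyperparams = list(nrounds = nrounds, max_depth = max_depth,
                            eta = eta, extra = list(...)),
         seed = seed, importance = imp, impute = sentinel,
         n_train = nrow(mat)),
    class = "loop_model"
  )
}

#' Predict loop scores
#'
#' @param model A `loop_model`.
#' @param features Feature tibble with exactly the model's schema columns
#'   (any order; extra `loop_id` allowed). Absent anchor-motif scores
#'   (`NA`) are imputed with the model's training-time sentinel (minimum
#'   observed value minus one).
#' @return Numeric vector of probabilities in `[0, 1]`, one per row, in
#'   input order.
#' @export
predict_scores <- function(model, features) {
  stopifnot(inherits(model, "loop_model"))
  mat <- feature_matrix(features)
  check_schema(colnames(mat), model$schema)
  mat <- mat[, model$schema, drop = FALSE]
  if (nrow(mat) == 0) return(numeric(0))
  for (j in seq_len(ncol(mat))) {
    nas <- is.na(mat[, j])
    if (any(nas)) mat[nas, j] <- model$impute[[model$schema[j]]]
  }
  as.numeric(predict(model$booster,
                     xgboost::xgb.DMatrix(mat, nthread = 1)))
}

#' Ranked feature importances of a trained model
#'
#' Importance is total gain, normalised to sum to one, in descending
#' order. Features never used by a split get importance zero.
#'
#' @param model A `loop_model` (or `binding_model`).
#' @return A tibble with columns `feature` and `importance`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, c("loop_model", "binding_model")))
  model$importance
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf(
    "<loop_model: xgboost, %d features, %d rounds, depth %d, eta %g, seed %d>\n",
    length(x$schema), x$hyperparams$nrounds, x$hyperparams$max_depth,
    x$hyperparams$eta, x$seed))
  invisible(x)
}

#' @rdname train_loop_model
#' @param x A `loop_model`.
#' @method tidy loop_model
#' @export
tidy.loop_model <- function(x, ...) x$importance

#' @rdname train_loop_model
#' @method glance loop_model
#' @export
glance.loop_model <- function(x, ...) {
  tibble(n_features = length(x$schema), nrounds = x$hyperparams$nrounds,
         max_depth = x$hyperparams$max_depth, eta = x$hyperparams$eta,
         seed = x$seed, n_train = x$n_train)
}

#' @rdname train_loop_model
#' @param object A `loop_model`.
#' @method autoplot loop_model
#' @export
autoplot.loop_model <- function(object, ...) {
  imp <- object$importance
  ggplot2::ggplot(imp, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Normalised gain importance") +
    ggplot2::theme_minimal()
}

#' Save / load a trained model
#'
#' The single-file serialisation keeps the feature schema, hyperparameters
#' and seed embedded with the fitted ensemble.
#'
#' @param model A `loop_model` or `binding_model`.
#' @param path Destination file.
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("loop_model", "binding_model")))
  if (inherits(model, "loop_model")) {
    model$booster_raw <- xgboost::xgb.save.raw(model$booster)
    model$booster <- NULL
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!is.null(model$booster_raw)) {
    model$booster <- xgboost::xgb.load.raw(model$booster_raw)
    model$booster_raw <- NULL
  }
  model
}

# -- internals ---------------------------------------------------------------

feature_matrix <- function(features) {
  x <- as_tibble(features)
  x <- x[, setdiff(names(x), c("loop_id", "label", "label_reason")),
         drop = FALSE]
  as.matrix(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("positive", "negative", "bound", "unbound"))
  if (length(bad) > 0) {
    abort(sprintf("Unlabelable class value(s): %s.", paste(bad, collapse = ", ")))
  }
  as.integer(labels %in% c("positive", "bound"))
}

check_schema <- function(have, want) {
  if (!setequal(have, want)) {
    extra <- setdiff(have, want)
    missing <- setdiff(want, have)
    abort(sprintf(
      "Feature schema mismatch. Missing: %s. Unexpected: %s.",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"))
  }
}

xgb_importance_tbl <- function(booster, schema) {
  imp <- tryCatch(
    xgboost::xgb.importance(model = booster),
    error = function(e) NULL
  )
  gain <- setNames(rep(0, length(schema)), schema)
  if (!is.null(imp) && nrow(imp) > 0) {
    gain[imp$Feature] <- imp$Gain
  }
  if (sum(gain) > 0) gain <- gain / sum(gain)
  tibble(feature = names(gain), importance = unname(gain)) |>
    arrange(desc(.data$importance))
}
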