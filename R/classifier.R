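#' Train the random-forest binding classifier
#'
#' Binary classification (bound vs unbound) on the assembled feature
#' table. Trees are grown on bootstrap samples with Gini-impurity splits
#' and per-split feature subsampling; predictions are vote fractions. The
#' forest is fully determined by `(data, seed, n_trees)`.
#'
#' @param features feature table from [assemble_feature_table()] (column
#'   `site_id` plus the schema columns).
#' @param labels factor with levels `c("unbound", "bound")`, aligned to
#'   the rows of `features`.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed for the forest's own RNG.
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param min_node minimum node size to attempt a split (default 1, grow
#'   to purity).
#' @param balanced if `TRUE`, use a stratified bootstrap drawing equally
#'   from both classes (off by default; training data are typically
#'   imbalanced and left so).
#' @param meth_models named list of `meth_model` objects (by context) to
#'   carry inside the trained model for later prediction.
#' @param tf_name label stored in the metadata.
#' @return object of class `tf_model`.
#' @export
train_rf <- function(features, labels, n_trees = 500, seed = 1,
                     mtry = NULL, min_node = 1, balanced = FALSE,
                     meth_models = list(), tf_name = "TF") {
  schema <- attr(features, "schema")
  if (is.null(schema)) schema <- setdiff(names(features), "site_id")
  X <- as.matrix(features[, schema, drop = FALSE])
  if (anyNA(X))
    stop("feature table contains NA values", call. = FALSE)
  labels <- factor(labels, levels = c("unbound", "bound"))
  if (nrow(X) != length(labels))
    stop("features and labels length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  y <- as.integer(labels == "bound")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fit <- rf_train_cpp(X, y, as.integer(n_trees), as.integer(mtry),
                      as.integer(min_node), as.numeric(seed), balanced)
  oob <- oob_error_curve(fit$oob_pred, y, n_trees)
  structure(list(
    version = 1L,
    feature_schema = schema,
    trees = fit$trees,
    importance_raw = stats::setNames(fit$importance, schema),
    oob_pred = fit$oob_pred,
    oob_error = oob[length(oob)],
    meth_models = meth_models,
    metadata = list(tf_name = tf_name, seed = seed, n_trees = n_trees,
                    mtry = mtry, min_node = min_node, balanced = balanced,
                    n_bound = sum(y == 1), n_unbound = sum(y == 0))),
    class = "tf_model")
}

# OOB misclassification error using the first k trees, for each k in
# `at` (defaults to just the full forest). Rows never out-of-bag are
# excluded; tied vote fractions of exactly 0.5 go to "unbound".
oob_error_curve <- function(oob_pred, y, at) {
  vapply(at, function(k) {
    votes <- colMeans(oob_pred[seq_len(k), , drop = FALSE], na.rm = TRUE)
    seen <- !is.nan(votes)
    pred <- as.integer(votes[seen] > 0.5)
    mean(pred != y[seen])
  }, 0)
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf(paste0(
    "tf_model '%s': %d trees (mtry %d), OOB error %.4f\n",
    "  features: %s\n  contexts: %s\n"),
    x$metadata$tf_name, x$metadata$n_trees, x$metadata$mtry, x$oob_error,
    paste(x$feature_schema, collapse = ", "),
    if (length(x$meth_models)) paste(names(x$meth_models), collapse = ", ")
    else "(none attached)"))
  invisible(x)
}

#' Choose the number of trees by out-of-bag stability
#'
#' Trains one forest of `max(grid)` trees and evaluates the OOB error of
#' each prefix of the grid; returns the smallest grid value whose OOB
#' error differs from the next grid point's by less than `stability_tol`.
#' If the curve never stabilises, the grid maximum is returned with a
#' warning.
#'
#' @inheritParams train_rf
#' @param grid increasing vector of candidate tree counts.
#' @param stability_tol absolute OOB-error stability tolerance.
#' @return list with `n_trees` and the OOB `curve` (named by grid value).
#' @export
select_n_trees <- function(features, labels, grid = c(100, 200, 500, 1000),
                           stability_tol = 0.005, seed = 1, ...) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (length(grid) == 1L)
    return(list(n_trees = grid, curve = NULL))
  model <- train_rf(features, labels, n_trees = max(grid), seed = seed, ...)
  y <- as.integer(factor(labels, levels = c("unbound", "bound")) == "bound")
  curve <- oob_error_curve(model$oob_pred, y, grid)
  names(curve) <- grid
  stable <- abs(diff(curve)) < stability_tol
  if (any(stable)) {
    n_trees <- grid[which(stable)[1]]
  } else {
    n_trees <- grid[length(grid)]
    warning("OOB error never stabilised within tolerance ", stability_tol,
            "; using grid maximum ", n_trees)
  }
  list(n_trees = n_trees, curve = curve)
}

#' Predict binding probabilities
#'
#' The probability of binding is the fraction of trees voting `bound`.
#' The feature table must carry exactly the schema the model was trained
#' on.
#'
#' @param model a `tf_model`.
#' @param features feature table.
#' @return numeric vector in `[0, 1]`, named by site_id when present.
#' @export
predict_proba <- function(model, features) {
  schema <- attr(features, "schema")
  if (is.null(schema)) schema <- setdiff(names(features), "site_id")
  if (!identical(schema, model$feature_schema)) {
    extra <- setdiff(schema, model$feature_schema)
    miss <- setdiff(model$feature_schema, schema)
    stop("feature schema mismatch",
         if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         if (!length(miss) && !length(extra)) "; column order differs",
         call. = FALSE)
  }
  X <- as.matrix(features[, model$feature_schema, drop = FALSE])
  if (nrow(X) == 0L) return(stats::setNames(numeric(0), character(0)))
  p <- rf_predict_cpp(model$trees, X)
  if (!is.null(features$site_id)) names(p) <- features$site_id
  p
}

#' Gini importance of the model features
#'
#' Mean decrease in Gini impurity accumulated over all splits, normalised
#' to sum to 1.
#'
#' @param model a `tf_model`.
#' @return named non-negative vector summing to 1, aligned to the schema.
#' @export
gini_importance <- function(model) {
  imp <- model$importance_raw
  s <- sum(imp)
  if (s == 0) {
    warning("no splits in the forest; importance undefined, returning uniform")
    return(stats::setNames(rep(1 / length(imp), length(imp)), names(imp)))
  }
  imp / s
}

#' Save / load a trained model
#'
#' Versioned JSON text holding the feature schema, every tree of the
#' forest, the raw importances, the attached methylation models and the
#' training metadata. Numeric values are written with 17 significant
#' digits, so a load/save round trip reproduces bit-identical predictions
#' (the out-of-bag vote matrix is not persisted).
#'
#' @param model a `tf_model`.
#' @param path file path.
#' @return `load_model` returns the restored `tf_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "methbind/tf_model",
    version = model$version,
    feature_schema = model$feature_schema,
    trees = lapply(model$trees, unclass),
    importance_raw = as.numeric(model$importance_raw),
    oob_error = model$oob_error,
    meth_models = lapply(model$meth_models, unclass),
    metadata = model$metadata)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$format) || payload$format != "methbind/tf_model")
    stop("'", path, "' is not a methbind model file", call. = FALSE)
  if (payload$version != 1L)
    stop("unsupported model version: ", payload$version, call. = FALSE)
  meth_models <- lapply(payload$meth_models, function(m) {
    m$binding <- list(alpha = as.numeric(m$binding$alpha),
                      beta = as.numeric(m$binding$beta))
    m$background <- list(alpha = as.numeric(m$background$alpha),
                         beta = as.numeric(m$background$beta))
    structure(m, class = "meth_model")
  })
  structure(list(
    version = as.integer(payload$version),
    feature_schema = payload$feature_schema,
    trees = lapply(payload$trees, function(t) {
      m <- matrix(as.numeric(t), nrow = nrow(t))
      colnames(m) <- c("feature", "threshold", "left", "right", "pred")
      m
    }),
    importance_raw = stats::setNames(payload$importance_raw,
                                     payload$feature_schema),
    oob_pred = NULL,
    oob_error = payload$oob_error,
    meth_models = meth_models,
    metadata = as.list(payload$metadata)),
    class = "tf_model")
}
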