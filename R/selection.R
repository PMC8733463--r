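# Feature-space reduction: Random-Forest Gini importance under a 5-fold
# cross-validated 3x3 grid search (trees {25,50,100} x minimum samples to
# split {2,4,6} = 9 settings), classifying ictal periods between persons.
# The five most discriminative features form the reduced feature space.

#' Selection configuration
#'
#' @param n_trees_grid Numbers of trees to try (default 25, 50, 100).
#' @param min_split_grid Minimum samples required to split a node (default
#'   2, 4, 6). Mapped onto the forest's minimum terminal-node size as
#'   `min_split - 1`: a node smaller than `min_split` is never split, so
#'   terminal nodes may hold up to `min_split - 1` cases.
#' @param n_folds Cross-validation folds (default 5).
#' @param n_selected Number of features to keep (default 5).
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @param fold_strategy `"stratified_by_person"` (each fold sees every
#'   person) or `"plain"`.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(n_trees_grid = c(25, 50, 100),
                             min_split_grid = c(2, 4, 6),
                             n_folds = 5, n_selected = 5, seed = 1,
                             fold_strategy = c("stratified_by_person",
                                               "plain")) {
  fold_strategy <- match.arg(fold_strategy)
  if (!length(n_trees_grid) || !length(min_split_grid))
    ip_stop("hyperparameter grids must be non-empty", "ip_config_error")
  if (n_folds < 2)
    ip_stop("n_folds must be >= 2", "ip_config_error")
  structure(list(n_trees_grid = sort(as.integer(n_trees_grid)),
                 min_split_grid = sort(as.integer(min_split_grid)),
                 n_folds = as.integer(n_folds),
                 n_selected = as.integer(n_selected),
                 seed = as.integer(seed), fold_strategy = fold_strategy),
            class = "selection_config")
}

# deterministic fold labels
assign_folds <- function(persons, n_folds, seed, strategy) {
  n <- length(persons)
  folds <- integer(n)
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, 71L))
  if (strategy == "stratified_by_person") {
    for (p in sort(unique(persons))) {
      idx <- which(persons == p)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                     length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  folds
}

#' Select the most person-discriminative features
#'
#' Trains a Random-Forest classifier to separate ictal periods between
#' persons for each of the grid's hyperparameter settings under
#' cross-validation, refits the best setting (ties break toward fewer trees,
#' then smaller split minimum) on all ictal rows, and keeps the
#' `n_selected` features with the highest Gini importance (ties break in
#' catalogue order). Fully reproducible given the config seed.
#'
#' @param table A `feature_table`; only rows with `kind == "ictal"` are used.
#' @param config A [selection_config()].
#' @return List of class `reduced_feature_space`: `selected` (ordered names),
#'   `importances` (normalized to sum 1 over the whole catalogue),
#'   `best_hyperparams`, `cv_scores` (data frame over the grid), `n_ictal`.
#' @export
select_features <- function(table, config = selection_config()) {
  if ("kind" %in% names(table))
    table <- table[table$kind == "ictal", , drop = FALSE]
  feats <- setdiff(names(table), feature_meta_cols())
  if (config$n_selected > length(feats))
    ip_stop("n_selected exceeds the catalogue size", "ip_config_error")
  X <- feature_matrix(table, feats)
  if (anyNA(X))
    ip_stop("feature table contains missing values", "ip_validation_error")
  y <- factor(table$person_id)
  if (nlevels(y) < 2)
    ip_stop("feature selection needs at least 2 persons", "ip_config_error")
  counts <- base::table(y)
  if (any(counts < config$n_folds))
    ip_stop(sprintf(
      "person(s) %s have fewer ictal periods than n_folds = %d; reduce n_folds",
      paste(names(counts)[counts < config$n_folds], collapse = ", "),
      config$n_folds), "ip_config_error")
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const))
    ip_warn(sprintf("constant feature column(s) retained with importance 0: %s",
                    paste(feats[const], collapse = ", ")))

  folds <- assign_folds(as.character(y), config$n_folds, config$seed,
                        config$fold_strategy)
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  grid <- expand.grid(min_split = config$min_split_grid,
                      n_trees = config$n_trees_grid)[, c("n_trees", "min_split")]
  grid <- grid[order(grid$n_trees, grid$min_split), , drop = FALSE]
  grid$accuracy <- NA_real_
  mtry <- max(1L, floor(sqrt(length(feats))))
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(config$n_folds)
    for (k in seq_len(config$n_folds)) {
      tr <- folds != k
      set.seed(derive_seed(config$seed, g * 100L + k))
      fit <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = droplevels(y[tr]),
        ntree = grid$n_trees[g], nodesize = grid$min_split[g] - 1L,
        mtry = mtry)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      acc[k] <- mean(as.character(pred) == as.character(y[!tr]))
    }
    grid$accuracy[g] <- mean(acc)
  }
  best <- which(grid$accuracy == max(grid$accuracy))[1]  # grid is tie-ordered

  set.seed(derive_seed(config$seed, 424242L))
  final <- randomForest::randomForest(
    x = X, y = y, ntree = grid$n_trees[best],
    nodesize = grid$min_split[best] - 1L, mtry = mtry)
  imp <- final$importance[, "MeanDecreaseGini"]
  imp <- stats::setNames(as.numeric(imp), feats)
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(imp), length(imp)), feats)
  sel <- feats[order(-imp, seq_along(imp))][seq_len(config$n_selected)]

  structure(list(selected = sel, importances = imp,
                 best_hyperparams = list(n_trees = grid$n_trees[best],
                                         min_split = grid$min_split[best]),
                 cv_scores = grid, n_ictal = nrow(X), config = config),
            class = "reduced_feature_space")
}

#' @export
print.reduced_feature_space <- function(x, ...) {
  cat(sprintf(
    "<reduced_feature_space> %d features selected from %d (best: %d trees, min split %d, CV accuracy %.3f)\n",
    length(x$selected), length(x$importances), x$best_hyperparams$n_trees,
    x$best_hyperparams$min_split, max(x$cv_scores$accuracy)))
  for (f in x$selected)
    cat(sprintf("  %-24s importance %.4f\n", f, x$importances[[f]]))
  invisible(x)
}

#' Restrict a feature table to the selected features
#'
#' Metadata columns are preserved; feature columns are reordered to the
#' selected order. Idempotent.
#'
#' @param table A `feature_table` (any period kinds).
#' @param space A `reduced_feature_space` from [select_features()].
#' @return A `feature_table` with the selected columns only.
#' @export
reduce_table <- function(table, space) {
  missing <- setdiff(space$selected, names(table))
  if (length(missing))
    ip_stop(sprintf("table lacks selected feature column(s): %s",
                    paste(missing, collapse = ", ")), "ip_schema_error")
  out <- table[, c(feature_meta_cols(), space$selected), drop = FALSE]
  class(out) <- unique(c("feature_table", class(out)))
  out
}
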