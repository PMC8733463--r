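# Z-score normalization and principal components in the reduced feature
# space. The Z-score model is fitted on ictal rows only and reused for
# pre-ictal/baseline rows, anchoring the fingerprint to ictal statistics.

#' Fit a Z-score model on the ictal rows of a reduced feature table
#'
#' @param table A `feature_table` (its `kind == "ictal"` rows are used when a
#'   `kind` column is present).
#' @return List of class `zscore_model` with per-feature `mean` and `sd`.
#' @export
fit_zscore <- function(table) {
  if ("kind" %in% names(table))
    table <- table[table$kind == "ictal", , drop = FALSE]
  X <- feature_matrix(table)
  if (nrow(X) < 2)
    ip_stop("Z-scoring needs at least 2 rows (sd undefined on 1)",
            "ip_degenerate_error")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv <= 0))
    ip_stop(sprintf("constant (degenerate) feature(s): %s",
                    paste(colnames(X)[sdv <= 0], collapse = ", ")),
            "ip_degenerate_error")
  structure(list(mean = mu, sd = sdv, features = colnames(X)),
            class = "zscore_model")
}

#' Apply a fitted Z-score model
#'
#' @param model A `zscore_model`.
#' @param table A `feature_table` holding at least the model's features
#'   (any period kinds — the ictal means/sds are reused unchanged).
#' @return The table with the model's feature columns standardized.
#' @export
apply_zscore <- function(model, table) {
  missing <- setdiff(model$features, names(table))
  if (length(missing))
    ip_stop(sprintf("table lacks feature column(s): %s",
                    paste(missing, collapse = ", ")), "ip_schema_error")
  for (f in model$features)
    table[[f]] <- (table[[f]] - model$mean[[f]]) / model$sd[[f]]
  table
}

#' Principal component analysis of Z-scored ictal rows
#'
#' Covariance eigendecomposition with components ordered by explained
#' variance. Sign convention: the largest-magnitude loading of each component
#' is positive, making the decomposition reproducible across platforms.
#'
#' @param z_table Z-scored ictal `feature_table` (rows >= features).
#' @return List of class `pca_model`: orthonormal `loadings`
#'   (features x components), `explained_var` fractions, `center`, `sdev`.
#' @export
fit_pca <- function(z_table) {
  X <- feature_matrix(z_table)
  if (nrow(X) < ncol(X))
    ip_stop(sprintf("PCA needs at least as many rows (%d) as features (%d)",
                    nrow(X), ncol(X)), "ip_rank_error")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  L <- pc$rotation
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  structure(list(loadings = L,
                 explained_var = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, sdev = pc$sdev,
                 features = colnames(X)),
            class = "pca_model")
}

#' Project rows onto fitted principal components
#'
#' @param model A `pca_model`.
#' @param table A (Z-scored) `feature_table` with the model's features.
#' @return Matrix of component scores (rows x components), with the table's
#'   `person_id` as an attribute when present.
#' @export
project_pca <- function(model, table) {
  X <- feature_matrix(table, model$features)
  scores <- sweep(X, 2, model$center) %*% model$loadings
  colnames(scores) <- colnames(model$loadings)
  if ("person_id" %in% names(table))
    attr(scores, "person_id") <- table$person_id
  scores
}
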