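# The ictal fingerprint model: Z-scored reduced feature space, principal
# components, per-person seizure centroids, nearest-centroid clustering,
# radar summaries and ictal vs pre-ictal/baseline separation statistics.

z_crit <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)

# 95 % half-width for a binomial proportion; n is the pooled period count
binom_halfwidth <- function(p, n, method = c("wald", "wilson",
                                             "clopper-pearson")) {
  method <- match.arg(method)
  if (is.na(p) || n == 0) return(NA_real_)
  z <- z_crit()
  switch(method,
    wald = z * sqrt(p * (1 - p) / n),
    wilson = z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n),
    `clopper-pearson` = {
      k <- round(p * n)
      lo <- if (k == 0) 0 else stats::qbeta(0.025, k, n - k + 1)
      hi <- if (k == n) 1 else stats::qbeta(0.975, k + 1, n - k)
      (hi - lo) / 2
    })
}

# nearest-centroid assignment; ties -> person with more seizures, then
# lexicographically smaller id
assign_nearest <- function(S, centroids, n_members, loo_person = NULL,
                           loo_sums = NULL) {
  persons <- rownames(centroids)
  pref <- order(-n_members[persons], persons)  # tie preference order
  apply_one <- function(x, cents) {
    d <- sqrt(colSums((t(cents) - x)^2))
    cand <- which(d <= min(d) + 1e-12)
    persons[pref[pref %in% cand][1]]
  }
  vapply(seq_len(nrow(S)), function(i) {
    cents <- centroids
    if (!is.null(loo_person)) {
      p <- loo_person[i]
      if (n_members[[p]] > 1)
        cents[p, ] <- (loo_sums[p, ] - S[i, ]) / (n_members[[p]] - 1)
    }
    apply_one(S[i, ], cents)
  }, character(1))
}

#' Nearest-centroid person clustering of seizure scores
#'
#' Computes a per-person seizure centroid (arithmetic mean over all that
#' person's seizures) in the first `n_components` principal-component scores
#' and assigns every seizure to the person with the closest centroid
#' (Euclidean distance; exact ties break toward the person with more
#' seizures, then the lexicographically smaller id). Accuracy is the fraction
#' of seizures assigned to their true person.
#'
#' @param scores Score matrix from [project_pca()] (or any row-per-seizure
#'   matrix) with a `person_id` attribute, or supply `persons`.
#' @param persons Character vector of true person ids per row.
#' @param n_components Number of leading components used (default 3).
#' @param subset Optional person ids to restrict to (subset accuracies).
#' @param leave_one_out If `TRUE`, the true person's centroid is recomputed
#'   without the held-out seizure before assignment.
#' @return List of class `centroid_clustering`: `centroids` (persons x
#'   components, class `centroid_set`), `assignments`, `accuracy`, `n`.
#' @export
person_clustering <- function(scores, persons = attr(scores, "person_id"),
                              n_components = 3, subset = NULL,
                              leave_one_out = FALSE) {
  if (is.null(persons) || length(persons) != nrow(scores))
    ip_stop("person labels missing or wrong length", "ip_argument_error")
  persons <- as.character(persons)
  if (!is.null(subset)) {
    keep <- persons %in% subset
    scores <- scores[keep, , drop = FALSE]
    persons <- persons[keep]
  }
  if (!length(persons) || any(base::table(persons) < 1))
    ip_stop("every person needs at least one seizure", "ip_argument_error")
  k <- min(n_components, ncol(scores))
  S <- scores[, seq_len(k), drop = FALSE]
  ids <- sort(unique(persons))
  cents <- t(vapply(ids, function(p)
    colMeans(S[persons == p, , drop = FALSE]), numeric(k)))
  rownames(cents) <- ids
  n_members <- vapply(ids, function(p) sum(persons == p), numeric(1))
  sums <- cents * n_members
  assigned <- assign_nearest(
    S, cents, n_members,
    loo_person = if (leave_one_out) persons else NULL,
    loo_sums = if (leave_one_out) sums else NULL)
  structure(list(
    centroids = structure(list(space_tag = "pca", centroids = cents,
                               n = n_members), class = "centroid_set"),
    assignments = data.frame(person_id = persons, assigned = assigned,
                             correct = assigned == persons,
                             stringsAsFactors = FALSE),
    accuracy = mean(assigned == persons),
    n_components = k, leave_one_out = leave_one_out),
    class = "centroid_clustering")
}

#' Radar-chart fingerprint summaries
#'
#' Per person and per feature, the median and interquartile range
#' (75th minus 25th percentile, linear interpolation) of the Z-scored ictal
#' values, with polar plotting coordinates in the selected feature order
#' (F1, F2, ...).
#'
#' @param z_table Z-scored ictal `feature_table`; every person needs at least
#'   2 rows.
#' @return Data frame of class `radar_fingerprint` with columns `person_id`,
#'   `feature`, `f_label`, `angle`, `median`, `iqr`.
#' @export
build_radar <- function(z_table) {
  feats <- setdiff(names(z_table), feature_meta_cols())
  ids <- sort(unique(z_table$person_id))
  low <- ids[vapply(ids, function(p) sum(z_table$person_id == p) < 2,
                    logical(1))]
  if (length(low))
    ip_stop(sprintf("person(s) %s have fewer than 2 ictal rows; IQR undefined",
                    paste(low, collapse = ", ")), "ip_degenerate_error")
  rows <- expand.grid(person_id = ids, feature = feats,
                      stringsAsFactors = FALSE)
  rows$f_label <- paste0("F", match(rows$feature, feats))
  rows$angle <- 2 * pi * (match(rows$feature, feats) - 1) / length(feats)
  qs <- t(mapply(function(p, f) {
    v <- z_table[[f]][z_table$person_id == p]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(median = q[2], iqr = q[3] - q[1])
  }, rows$person_id, rows$feature))
  rows$median <- qs[, 1]
  rows$iqr <- qs[, 2]
  class(rows) <- unique(c("radar_fingerprint", class(rows)))
  rows
}

#' Ictal versus pre-ictal/baseline separation
#'
#' For each person, each period is classified as the class (ictal or other)
#' whose person-specific cluster average is nearer in the Z-scored reduced
#' feature space (Euclidean norm; ties classify as ictal). Pooling all
#' persons yields accuracy, sensitivity (ictal positive), specificity, PPV
#' and NPV, each with a 95 % half-width computed at the pooled period count.
#' Persons missing one class are excluded with a warning.
#'
#' @param z_ictal,z_other Z-scored reduced `feature_table`s (same features).
#' @param task Label for the result (`"preictal_vs_ictal"` or
#'   `"baseline_vs_ictal"`).
#' @param ci_method `"wald"` (default), `"wilson"` or `"clopper-pearson"`.
#' @return List of class `separation_result` with the pooled metrics,
#'   `ci_halfwidths`, class counts `n`, the confusion counts and per-row
#'   `distances` for distance-to-cluster plots.
#' @export
state_separation <- function(z_ictal, z_other,
                             task = c("preictal_vs_ictal",
                                      "baseline_vs_ictal"),
                             ci_method = c("wald", "wilson",
                                           "clopper-pearson")) {
  task <- match.arg(task)
  ci_method <- match.arg(ci_method)
  feats <- setdiff(names(z_ictal), feature_meta_cols())
  ids_i <- unique(z_ictal$person_id)
  ids_o <- unique(z_other$person_id)
  drop <- union(setdiff(ids_i, ids_o), setdiff(ids_o, ids_i))
  if (length(drop))
    ip_warn(sprintf("person(s) %s missing one class; excluded from separation",
                    paste(sort(drop), collapse = ", ")))
  ids <- sort(intersect(ids_i, ids_o))
  if (!length(ids))
    ip_stop("no person has both classes", "ip_argument_error")

  dist_rows <- list()
  for (p in ids) {
    Xi <- feature_matrix(z_ictal[z_ictal$person_id == p, , drop = FALSE], feats)
    Xo <- feature_matrix(z_other[z_other$person_id == p, , drop = FALSE], feats)
    mi <- colMeans(Xi); mo <- colMeans(Xo)
    for (cls in c("ictal", "other")) {
      tab <- if (cls == "ictal") z_ictal else z_other
      tab <- tab[tab$person_id == p, , drop = FALSE]
      X <- if (cls == "ictal") Xi else Xo
      d_i <- sqrt(rowSums(sweep(X, 2, mi)^2))
      d_o <- sqrt(rowSums(sweep(X, 2, mo)^2))
      dist_rows[[length(dist_rows) + 1L]] <- data.frame(
        person_id = p, seizure_id = tab$seizure_id, kind = tab$kind,
        truth = cls, d_ictal = d_i, d_other = d_o,
        predicted = ifelse(d_i <= d_o, "ictal", "other"),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, dist_rows)
  tp <- sum(d$truth == "ictal" & d$predicted == "ictal")
  fn <- sum(d$truth == "ictal" & d$predicted == "other")
  tn <- sum(d$truth == "other" & d$predicted == "other")
  fp <- sum(d$truth == "other" & d$predicted == "ictal")
  n <- nrow(d)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- c(accuracy = (tp + tn) / n,
               sensitivity = safe(tp, tp + fn),
               specificity = safe(tn, tn + fp),
               ppv = safe(tp, tp + fp),
               npv = safe(tn, tn + fn))
  hw <- vapply(metrics, binom_halfwidth, numeric(1), n = n,
               method = ci_method)
  structure(list(task = task, accuracy = metrics[["accuracy"]],
                 sensitivity = metrics[["sensitivity"]],
                 specificity = metrics[["specificity"]],
                 ppv = metrics[["ppv"]], npv = metrics[["npv"]],
                 ci_halfwidths = hw, ci_method = ci_method,
                 n = c(ictal = tp + fn, other = tn + fp),
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 distances = d),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> %s (n = %d ictal + %d %s)\n", x$task,
              x$n[["ictal"]], x$n[["other"]],
              sub("_vs_ictal", "", x$task)))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("  %-12s %5.1f %% (+/- %.1f)\n", m, 100 * x[[m]],
                100 * x$ci_halfwidths[[m]]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# The fitted fingerprint model

#' Fit an ictal fingerprint model
#'
#' The package's central estimator. From a multimodal feature table it
#' (1) selects the most person-discriminative features by Random-Forest Gini
#' importance under cross-validated grid search, (2) Z-scores the reduced
#' ictal rows, (3) fits principal components, and (4) computes per-person
#' seizure centroids with nearest-centroid clustering accuracy and
#' radar-chart summaries.
#'
#' @param table A `feature_table` from [compute_feature_table()] covering at
#'   least the ictal periods of two or more persons.
#' @param config A [selection_config()] (grids, folds, seed).
#' @param n_components Leading principal components used for centroid
#'   clustering (default 3; the radar and separation statistics always use
#'   the full Z-scored reduced space).
#' @param leave_one_out If `TRUE`, clustering recomputes the true person's
#'   centroid without the held-out seizure.
#' @param ci_method Confidence-interval method for separation statistics.
#' @return Object of class `ictal_fingerprint` with components `space`
#'   (selected features and importances), `zscore`, `pca`, `scores`,
#'   `clustering`, `centroids`, `radar`.
#' @export
ictal_fingerprint <- function(table, config = selection_config(),
                              n_components = 3, leave_one_out = FALSE,
                              ci_method = c("wald", "wilson",
                                            "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  ictal <- table[table$kind == "ictal", , drop = FALSE]
  space <- select_features(ictal, config)
  red <- reduce_table(ictal, space)
  zmod <- fit_zscore(red)
  z_ict <- apply_zscore(zmod, red)
  pca <- fit_pca(z_ict)
  scores <- project_pca(pca, z_ict)
  clust <- person_clustering(scores, n_components = n_components,
                             leave_one_out = leave_one_out)
  structure(list(space = space, zscore = zmod, pca = pca,
                 z_ictal = z_ict, scores = scores,
                 clustering = clust, centroids = clust$centroids,
                 radar = build_radar(z_ict),
                 n_components = n_components, ci_method = ci_method,
                 call = match.call()),
            class = "ictal_fingerprint")
}

#' Separation statistics of a fitted fingerprint against another period kind
#'
#' Applies the model's ictal-fitted Z-scoring to the chosen periods and runs
#' [state_separation()] in the reduced feature space.
#'
#' @param object A fitted [ictal_fingerprint()].
#' @param table The full `feature_table` containing `preictal` and/or
#'   `baseline` rows.
#' @param kind `"preictal"` or `"baseline"`.
#' @return A `separation_result`.
#' @export
fingerprint_separation <- function(object, table,
                                   kind = c("preictal", "baseline")) {
  kind <- match.arg(kind)
  other <- table[table$kind == kind, , drop = FALSE]
  if (!nrow(other))
    ip_stop(sprintf("no %s rows in the table", kind), "ip_argument_error")
  z_other <- apply_zscore(object$zscore, reduce_table(other, object$space))
  state_separation(object$z_ictal, z_other,
                   task = paste0(kind, "_vs_ictal"),
                   ci_method = object$ci_method)
}

#' @export
print.ictal_fingerprint <- function(x, ...) {
  ids <- rownames(x$centroids$centroids)
  cat(sprintf(
    "<ictal_fingerprint> %d persons, %d seizures, %d of %d features\n",
    length(ids), nrow(x$scores), length(x$space$selected),
    length(x$space$importances)))
  cat("  features:", paste(x$space$selected, collapse = ", "), "\n")
  cat(sprintf("  clustering accuracy (%d PCs): %.1f %%\n",
              x$clustering$n_components, 100 * x$clustering$accuracy))
  invisible(x)
}

#' @export
summary.ictal_fingerprint <- function(object, ...) {
  per_person <- vapply(
    sort(unique(object$clustering$assignments$person_id)),
    function(p) {
      a <- object$clustering$assignments
      mean(a$correct[a$person_id == p])
    }, numeric(1))
  out <- list(
    selected = object$space$selected,
    importances = object$space$importances[object$space$selected],
    best_hyperparams = object$space$best_hyperparams,
    cv_accuracy = max(object$space$cv_scores$accuracy),
    explained_var = object$pca$explained_var,
    n_components = object$clustering$n_components,
    accuracy = object$clustering$accuracy,
    per_person_accuracy = per_person)
  class(out) <- "summary.ictal_fingerprint"
  out
}

#' @export
print.summary.ictal_fingerprint <- function(x, ...) {
  cat("Ictal fingerprint\n-----------------\n")
  cat(sprintf("Selection: best forest %d trees, min split %d (CV accuracy %.3f)\n",
              x$best_hyperparams$n_trees, x$best_hyperparams$min_split,
              x$cv_accuracy))
  for (i in seq_along(x$selected))
    cat(sprintf("  F%d %-24s importance %.4f\n", i, x$selected[i],
                x$importances[[i]]))
  cat(sprintf("PCA explained variance: %s\n",
              paste(sprintf("%.1f %%", 100 * x$explained_var), collapse = ", ")))
  cat(sprintf("Nearest-centroid clustering accuracy (%d PCs): %.1f %%\n",
              x$n_components, 100 * x$accuracy))
  for (p in names(x$per_person_accuracy))
    cat(sprintf("  person %s: %.1f %%\n", p, 100 * x$per_person_accuracy[[p]]))
  invisible(x)
}

#' Per-person centroid coordinates of a fitted fingerprint
#' @param object A fitted [ictal_fingerprint()].
#' @param ... Unused.
#' @return Matrix (persons x principal components).
#' @export
coef.ictal_fingerprint <- function(object, ...) {
  object$centroids$centroids[, seq_len(object$clustering$n_components),
                             drop = FALSE]
}

#' Assign new periods to persons by nearest centroid
#'
#' @param object A fitted [ictal_fingerprint()].
#' @param newdata A `feature_table` with the selected feature columns.
#' @param type `"person"` (nearest-centroid assignment) or `"scores"`
#'   (principal-component scores).
#' @param ... Unused.
#' @return Character vector of person ids, or a score matrix.
#' @export
predict.ictal_fingerprint <- function(object, newdata,
                                      type = c("person", "scores"), ...) {
  type <- match.arg(type)
  z <- apply_zscore(object$zscore, reduce_table(newdata, object$space))
  scores <- project_pca(object$pca, z)
  if (type == "scores") return(scores)
  k <- object$clustering$n_components
  assign_nearest(scores[, seq_len(k), drop = FALSE],
                 object$centroids$centroids[, seq_len(k), drop = FALSE],
                 object$centroids$n)
}

#' Radar plot of the per-person ictal fingerprints
#'
#' One polar panel per person showing the median (solid polygon) and the
#' median +/- IQR/2 band of each Z-scored fingerprint feature.
#'
#' @param x A fitted [ictal_fingerprint()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ictal_fingerprint <- function(x, ...) {
  r <- x$radar
  ids <- sort(unique(r$person_id))
  feats <- unique(r$feature)
  labs <- unique(r$f_label)
  rmax <- max(abs(r$median) + r$iqr / 2, 1)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (p in ids) {
    rp <- r[r$person_id == p, ]
    rp <- rp[match(feats, rp$feature), ]
    ang <- rp$angle + pi / 2  # F1 at the top
    close_poly <- function(v) c(v, v[1])
    graphics::plot(NA, xlim = c(-rmax, rmax) * 1.3, ylim = c(-rmax, rmax) * 1.3,
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = paste("person", p), ...)
    for (rr in pretty(c(0, rmax)))
      graphics::lines(rr * cos(seq(0, 2 * pi, length.out = 73)),
                      rr * sin(seq(0, 2 * pi, length.out = 73)),
                      col = "grey85")
    graphics::segments(0, 0, rmax * cos(ang), rmax * sin(ang), col = "grey85")
    graphics::text(1.2 * rmax * cos(ang), 1.2 * rmax * sin(ang), labs)
    rad <- pmax(rp$median - min(r$median), 0)  # shift so the floor is 0
    hi <- rad + rp$iqr / 2
    graphics::polygon(close_poly(hi * cos(ang)), close_poly(hi * sin(ang)),
                      col = grDevices::adjustcolor("steelblue", 0.25),
                      border = NA)
    graphics::polygon(close_poly(rad * cos(ang)), close_poly(rad * sin(ang)),
                      border = "steelblue4", lwd = 2)
  }
  invisible(x)
}
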