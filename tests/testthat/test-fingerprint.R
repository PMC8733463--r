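# Z-scoring, PCA, centroids, radar and separation statistics.

z_table <- function(X, persons, kind = "ictal") {
  tab <- cbind(data.frame(person_id = persons,
                          seizure_id = sprintf("s%03d", seq_len(nrow(X))),
                          kind = kind, stringsAsFactors = FALSE),
               as.data.frame(X))
  class(tab) <- unique(c("feature_table", class(tab)))
  tab
}

test_that("Z-scoring centres and scales ictal rows and transfers to others", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5, mean = 3, sd = 2), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  ict <- z_table(X, rep(c("a", "b"), 20))
  m <- fit_zscore(ict)
  z <- apply_zscore(m, ict)
  zm <- colMeans(as.matrix(z[, 4:8]))
  zs <- apply(as.matrix(z[, 4:8]), 2, sd)
  expect_true(all(abs(zm) < 1e-9))
  expect_true(all(abs(zs - 1) < 1e-9))

  other <- z_table(X + 2, rep(c("a", "b"), 20), kind = "preictal")
  z2 <- apply_zscore(m, other)
  expect_true(all(colMeans(as.matrix(z2[, 4:8])) > 0.5))
})

test_that("degenerate Z-score inputs raise classed errors", {
  X <- matrix(rnorm(10), 2, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_ip_error(fit_zscore(z_table(X[1, , drop = FALSE], "a")),
                  "ip_degenerate_error")
  X2 <- cbind(X, f6 = c(1, 1))
  expect_ip_error(fit_zscore(z_table(X2, c("a", "b"))), "ip_degenerate_error")
})

test_that("PCA recovers a planted dominant axis with a fixed sign convention", {
  set.seed(2)
  axis <- c(2, -1, 0.5, 0, 0) / sqrt(5.25)
  scores <- rnorm(200, sd = 4)
  X <- scores %o% axis + matrix(rnorm(1000, sd = 0.3), 200, 5)
  colnames(X) <- paste0("f", 1:5)
  m <- fit_pca(z_table(X, rep("a", 200)))
  expect_gt(abs(sum(m$loadings[, 1] * axis)), 0.99)
  # largest-magnitude loading of every component is positive
  for (j in 1:5)
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  expect_true(all(abs(crossprod(m$loadings) - diag(5)) < 1e-8))
  expect_true(all(diff(m$explained_var) < 1e-12))
})

test_that("full-rank projection reconstructs the rows", {
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  tab <- z_table(X, rep("a", 20))
  m <- fit_pca(tab)
  sc <- project_pca(m, tab)
  back <- sweep(sc %*% t(m$loadings), 2, -m$center)
  expect_lt(max(abs(back - X)), 1e-8)
  expect_ip_error(fit_pca(z_table(X[1:3, ], rep("a", 3))), "ip_rank_error")
})

test_that("isotropic data spreads explained variance evenly", {
  set.seed(4)
  X <- matrix(rnorm(4000 * 5), 4000, 5, dimnames = list(NULL, paste0("f", 1:5)))
  m <- fit_pca(z_table(X, rep("a", 4000)))
  expect_true(all(abs(m$explained_var - 0.2) < 0.03))
})

test_that("well-separated mirrored clusters are clustered perfectly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20 * 3, mean = 3), 20, 3),
             matrix(rnorm(20 * 3, mean = -3), 20, 3))
  cl <- person_clustering(X, persons = rep(c("a", "b"), each = 20),
                          n_components = 3)
  expect_identical(cl$accuracy, 1)
  # centroid = member mean, exactly
  expect_equal(cl$centroids$centroids["a", ], colMeans(X[1:20, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("one shared distribution clusters at chance level", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(80 * 3), 80, 3)
    cl <- person_clustering(X, persons = rep(c("a", "b", "c", "d"), 20),
                            n_components = 3, leave_one_out = TRUE)
    expect_gt(cl$accuracy, 0.25 - 0.15)
    expect_lt(cl$accuracy, 0.25 + 0.15)
  }
})

test_that("nearest-centroid assignment matches a brute-force oracle", {
  set.seed(6)
  pts <- matrix(rnorm(50 * 3), 50, 3)
  persons <- sample(c("a", "b", "c", "d"), 50, replace = TRUE)
  cl <- person_clustering(pts, persons = persons, n_components = 3)
  cents <- cl$centroids$centroids
  oracle <- character(50)
  for (i in 1:50) {
    d <- numeric(4)
    for (k in 1:4) d[k] <- sqrt(sum((pts[i, ] - cents[k, ])^2))
    oracle[i] <- rownames(cents)[which.min(d)]
  }
  expect_identical(cl$assignments$assigned, oracle)
})

test_that("exact distance ties resolve to the person with more seizures", {
  # two singleton-ish clusters placed symmetrically around a test point
  X <- rbind(c(-1, 0), c(-1, 0), c(-1, 0), c(1, 0), c(1, 0), c(0, 0))
  persons <- c("big", "big", "big", "small", "small", "small")
  cl <- person_clustering(X, persons = persons, n_components = 2)
  # the last point sits exactly between the two centroids' x positions only
  # if centroids are (-1,0) and (0.666,0); construct a clean tie instead
  cents <- rbind(a = c(-1, 0), b = c(1, 0))
  res <- ictalprint:::assign_nearest(matrix(c(0, 0), 1, 2), cents,
                                     c(a = 2, b = 5))
  expect_identical(res, "b")
  res2 <- ictalprint:::assign_nearest(matrix(c(0, 0), 1, 2), cents,
                                      c(a = 3, b = 3))
  expect_identical(res2, "a")
})

test_that("radar summaries give exact medians and IQRs", {
  X <- matrix(c(-1, 0, 1), 3, 5, dimnames = list(NULL, paste0("f", 1:5)))
  r <- build_radar(z_table(X, rep("p", 3)))
  expect_true(all(r$median == 0))
  expect_true(all(r$iqr == 1))
  same <- matrix(2, 4, 5, dimnames = list(NULL, paste0("f", 1:5)))
  r2 <- build_radar(z_table(same, rep("q", 4)))
  expect_true(all(r2$median == 2))
  expect_true(all(r2$iqr == 0))
  expect_ip_error(build_radar(z_table(X[1, , drop = FALSE], "solo")),
                  "ip_degenerate_error")
})

test_that("indistinguishable classes separate at the tie-break floor", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ict <- z_table(X, rep(c("a", "b"), 30))
  other <- z_table(X, rep(c("a", "b"), 30), kind = "preictal")
  res <- state_separation(ict, other)
  # identical rows: every distance ties, ties classify as ictal
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 0)
})

test_that("well-separated classes reach perfect separation with zero CI width", {
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ict <- z_table(X, rep(c("a", "b"), 20))
  other <- z_table(X + 6, rep(c("a", "b"), 20), kind = "baseline")
  res <- state_separation(ict, other, task = "baseline_vs_ictal")
  expect_identical(res$accuracy, 1)
  expect_identical(unname(res$ci_halfwidths["accuracy"]), 0)
})

test_that("separation metrics satisfy the confusion identities and Wald form", {
  set.seed(9)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ict <- z_table(X, rep(c("a", "b"), 30))
  other <- z_table(X + 0.8, rep(c("a", "b"), 30), kind = "preictal")
  res <- state_separation(ict, other)
  P <- res$n[["ictal"]]; N <- res$n[["other"]]
  expect_equal(res$sensitivity * P + res$specificity * N,
               res$accuracy * (P + N), tolerance = 1e-12)
  cm <- res$confusion
  expect_identical(unname(cm["tp"] + cm["tn"] + cm["fp"] + cm["fn"]),
                   as.integer(P + N))
  n <- P + N
  expect_equal(unname(res$ci_halfwidths["accuracy"]),
               qnorm(0.975) * sqrt(res$accuracy * (1 - res$accuracy) / n),
               tolerance = 1e-12)
})

test_that("persons missing one class are excluded with a warning", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("f", 1:5)))
  ict <- z_table(X, rep(c("a", "b", "c"), 10))
  other <- z_table(X[1:20, ] + 1, rep(c("a", "b"), 10), kind = "preictal")
  expect_warning(res <- state_separation(ict, other), "missing one class")
  expect_identical(unname(res$n[["ictal"]]), 20L)
})

test_that("the fitted fingerprint model exposes the standard interface", {
  rep1 <- small_report()
  fp <- rep1$fingerprint
  expect_s3_class(fp, "ictal_fingerprint")
  expect_output(print(fp), "ictal_fingerprint")
  expect_output(print(summary(fp)), "clustering accuracy")
  cf <- coef(fp)
  expect_identical(dim(cf), c(2L, 3L))

  tab <- rep1$feature_table
  pred <- predict(fp, tab[tab$kind == "ictal", ])
  expect_true(mean(pred == tab$person_id[tab$kind == "ictal"]) >= 0.8)
  sc <- predict(fp, tab[tab$kind == "ictal", ], type = "scores")
  expect_identical(ncol(sc), 5L)

  f <- tempfile(fileext = ".png")
  grDevices::png(f, width = 600, height = 600)
  plot(fp)
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
  unlink(f)
})
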