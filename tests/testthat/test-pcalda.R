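test_that("PCA rejects degenerate input and captures exact low-rank structure", {
  X <- matrix(rep(c(1, 2, 3, 4), 5), nrow = 5, byrow = TRUE)
  expect_error(fit_pca(X, 1), "zero total variance")
  # rows in an exact 2-plane: k = 2 captures all variance
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(40 * 2), 40, 2)))
  X2 <- matrix(rnorm(12 * 2), 12, 2) %*% t(basis) +
    matrix(rnorm(40), 12, 40, byrow = TRUE)
  p <- fit_pca(X2, 2)
  expect_equal(sum(p$explained_variance_fraction), 1, tolerance = 1e-12)
  expect_error(fit_pca(X2, 12), "k must be")
})

test_that("PCA matches a dense eigendecomposition oracle within 1e-8", {
  set.seed(21)
  X <- matrix(rnorm(20 * 50), 20, 50)
  p <- fit_pca(X, 4)
  # oracle: eigenvectors of the sample covariance
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (19), symmetric = TRUE)
  for (j in 1:4) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v       # same sign convention
    expect_lt(max(abs(p$loadings[, j] - v)), 1e-8)
  }
  expect_equal(p$explained_variance_fraction,
               (ev$values / sum(ev$values))[1:4], tolerance = 1e-8)
  # orthonormality and variance bounds
  expect_lt(max(abs(crossprod(p$loadings) - diag(4))), 1e-8)
  expect_lte(sum(p$explained_variance_fraction), 1 + 1e-12)
  expect_lte(sum(apply(p$scores, 2, stats::var)),
             sum(apply(X, 2, stats::var)) + 1e-9)
})

test_that("LDA separates symmetric 1D clusters at the midpoint", {
  scores <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c("a", "a", "b", "b")
  d <- fit_lda(scores, lab)
  expect_equal(abs(d$threshold), 5.5)
  expect_identical(lmdpipe:::classify_scores(d, scores), lab)
})

test_that("LDA direction is Sw^-1 (mu1 - mu2), matching the solve oracle", {
  # isotropic within-class scatter: direction parallel to the mean difference
  set.seed(5)
  n <- 200
  a <- matrix(rnorm(2 * n), n, 2)
  b <- sweep(matrix(rnorm(2 * n), n, 2), 2, c(6, 2), `+`)
  d <- fit_lda(rbind(a, b), rep(c("a", "b"), each = n))
  dmu <- colMeans(a) - colMeans(b)
  cosang <- abs(sum(d$direction * dmu)) / sqrt(sum(dmu^2))
  expect_gt(cosang, 0.99)
  # anisotropic case against the explicit linear solve
  sh <- matrix(c(1, 0.8, 0, 0.3), 2, 2)
  a2 <- a %*% sh
  b2 <- sweep(matrix(rnorm(2 * n), n, 2) %*% sh, 2, c(3, -1), `+`)
  d2 <- fit_lda(rbind(a2, b2), rep(c("a", "b"), each = n))
  X <- rbind(a2, b2); lab <- rep(c("a", "b"), each = n)
  Sw <- (crossprod(scale(a2, scale = FALSE)) +
         crossprod(scale(b2, scale = FALSE))) / (2 * n - 2)
  w_ref <- solve(Sw, colMeans(a2) - colMeans(b2))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_lt(max(abs(d2$direction - w_ref)), 1e-8)
  # cross-check against MASS::lda (directions proportional)
  m <- MASS::lda(X, grouping = lab)
  v <- m$scaling[, 1] / sqrt(sum(m$scaling[, 1]^2))
  expect_lt(min(max(abs(v - w_ref)), max(abs(v + w_ref))), 1e-6)
  expect_error(fit_lda(matrix(1:3, 3, 1), c("a", "b", "b")), "at least 2")
})

test_that("LOOCV is at chance for label-free structure, perfect for separated classes", {
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 20), 40, 20)
    loocv_accuracy(X, labels = sample(rep(c("a", "b"), 20)), k = 2)$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.25 & accs <= 0.75))
  set.seed(99)
  sep <- rbind(matrix(rnorm(10 * 5), 10, 5),
               matrix(rnorm(10 * 5) + 10, 10, 5))
  expect_equal(loocv_accuracy(sep, rep(c("a", "b"), each = 10), k = 2)$accuracy, 1)
  expect_error(loocv_accuracy(matrix(rnorm(9), 3, 3), c("a", "b", "b")),
               "at least 4")
})

test_that("apportionment reuses the training frame without refitting", {
  fm <- make_labelled_features(n_each = 10, seed = 14)
  model <- fit_pca_lda(fm, k = 2)
  # training rows reproduce training scores exactly
  app <- apportion(model, fm)
  expect_lt(max(abs(app$scores - model$train_scores)), 1e-10)
  expect_equal(app$accuracy, 1)
  # a class centroid row is assigned to that class
  centroid_row <- colMeans(fm$values[fm$labels == "phacus", , drop = FALSE])
  expect_identical(
    apportion(model, matrix(centroid_row, 1))$predicted, "phacus")
  # empty test set
  empty <- apportion(model, fm$values[0, , drop = FALSE])
  expect_length(empty$predicted, 0)
  expect_true(is.na(empty$accuracy))
  expect_error(apportion(model, matrix(0, 2, 10)), "columns")
})

test_that("a Phacus cell dominated by Euglena signal is classified Euglena", {
  fm <- make_labelled_features(n_each = 15, seed = 23)
  model <- fit_pca_lda(fm, k = 2)
  pr <- default_profiles()
  set.seed(24)
  pha <- generate_spectrum(pr$phacus, noise_sd = 5, seed = NULL)
  eug <- generate_spectrum(pr$euglena, noise_sd = 5, seed = NULL)
  mixed <- normalize_and_bin(contaminate(pha, eug, 0.8))
  pred <- apportion(model, feature_matrix(list(mixed)))$predicted
  expect_identical(pred, "euglena")
})

test_that("LOOCV accuracy is invariant to row order and overall rescaling", {
  fm <- make_labelled_features(n_each = 8, seed = 31, grid_step = 0.02)
  base <- loocv_accuracy(fm, k = 2)
  set.seed(32)
  perm <- sample(nrow(fm$values))
  permuted <- feature_matrix(
    lapply(perm, function(i) binned_spectrum(fm$values[i, ],
                                             normalized = TRUE)),
    labels = fm$labels[perm])
  expect_equal(loocv_accuracy(permuted, k = 2)$accuracy, base$accuracy)
  # total-ion normalization removes any common intensity rescaling upstream
  pr <- default_profiles()
  set.seed(33)
  raw <- generate_spectrum(pr$euglena, noise_sd = 5, seed = NULL)
  scaled <- spectrum_record(raw$mz, raw$intensity * 7.3)
  expect_equal(normalize_and_bin(scaled)$values,
               normalize_and_bin(raw)$values, tolerance = 1e-12)
})

test_that("the discriminant weights point at the class-specific ion bins", {
  pr <- default_profiles()
  shared <- c("chlorophyll a", "pyropheophytin a")
  specific_bins <- function(p) {
    mzs <- p$peaks$mz[!p$peaks$ion %in% c(shared, "chlorophyll b")]
    floor((mzs - 700) / 0.1) + 1
  }
  injected <- c(specific_bins(pr$euglena), specific_bins(pr$phacus))
  hits <- vapply(1:10, function(s) {
    fm <- make_labelled_features(n_each = 8, seed = 40 + s, grid_step = 0.02)
    model <- fit_pca_lda(fm, k = 2)
    w_bins <- as.numeric(model$pca$loadings %*% model$lda$direction)
    top10 <- order(abs(w_bins), decreasing = TRUE)[1:10]
    mean(injected %in% top10)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("models serialize to JSON and classify identically after reload", {
  fm <- make_labelled_features(n_each = 6, seed = 51, grid_step = 0.02)
  model <- fit_pca_lda(fm, k = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_pca_lda(model, f)
  back <- read_pca_lda(f)
  expect_equal(back$pca$loadings, model$pca$loadings, tolerance = 1e-12)
  expect_equal(back$lda$threshold, model$lda$threshold, tolerance = 1e-12)
  expect_identical(apportion(back, fm)$predicted,
                   apportion(model, fm)$predicted)
  png <- withr::local_tempfile(fileext = ".png")
  plot_scores_png(model, test = apportion(model, fm), path = png)
  expect_true(file.exists(png) && file.size(png) > 0)
})
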