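#' Principal component analysis of a feature matrix
#'
#' Column-mean centering (no variance scaling; total-ion-normalized spectra
#' already share a common scale) followed by a singular value decomposition.
#' Loadings are the top-k right singular vectors, sign-fixed so that each
#' loading's largest-magnitude element is positive; explained-variance
#' fractions are the component variances over the total variance.
#'
#' @param X A [feature_matrix()] or bare numeric matrix (rows = cells).
#' @param k Number of components, `<= min(nrow - 1, ncol)`.
#' @return List of class `pca_fit`: `mean` (length-p), `loadings` (p x k,
#'   orthonormal), `explained_variance_fraction` (length-k, non-increasing)
#'   and `scores` (n x k).
#' @export
fit_pca <- function(X, k = 2) {
  mat <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  n <- nrow(mat); p <- ncol(mat)
  if (n < 2) stop("fit_pca: need at least 2 rows")
  if (k < 1 || k > min(n - 1, p)) stop("fit_pca: k must be in [1, min(n-1, p)]")
  mu <- colMeans(mat)
  Xc <- sweep(mat, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1, p))
  total_var <- sum(sv$d^2)
  if (total_var <= 1e-300) stop("fit_pca: zero total variance")
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|.| element of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(list(mean = mu, loadings = loadings,
                 explained_variance_fraction = sv$d[seq_len(k)]^2 / total_var,
                 scores = Xc %*% loadings),
            class = "pca_fit")
}

#' Fisher linear discriminant on PCA scores
#'
#' Two-class Fisher LDA with equal priors and shared (pooled) within-class
#' covariance: direction `w` proportional to `Sw^{-1} (mu1 - mu2)` (classes
#' in alphabetical order, so the first class projects to the positive
#' side), threshold at the midpoint of the projected class means.  A ridge
#' of `1e-8 * mean(diag(Sw))` is added when `Sw` is near-singular.
#'
#' @param scores n x k matrix of component scores.
#' @param labels Length-n labels from a 2-class alphabet, each class with
#'   at least 2 members.
#' @return List of class `lda_fit`: `direction` (unit length-k),
#'   `threshold`, `classes` (alphabetical), `class_means` (k x 2) and
#'   `projected_means`.
#' @export
fit_lda <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("fit_lda: exactly 2 classes required")
  n1 <- sum(labels == classes[1]); n2 <- sum(labels == classes[2])
  if (n1 < 2 || n2 < 2) stop("fit_lda: each class needs at least 2 members")
  k <- ncol(scores)
  x1 <- scores[labels == classes[1], , drop = FALSE]
  x2 <- scores[labels == classes[2], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  c1 <- crossprod(sweep(x1, 2, mu1))
  c2 <- crossprod(sweep(x2, 2, mu2))
  Sw <- (c1 + c2) / (n1 + n2 - 2)
  if (rcond(Sw) < 1e-12) Sw <- Sw + diag(1e-8 * mean(diag(Sw)), k)
  w <- solve(Sw, mu1 - mu2)
  w <- w / sqrt(sum(w^2))
  pm <- c(sum(w * mu1), sum(w * mu2))
  structure(list(direction = w, threshold = mean(pm), classes = classes,
                 class_means = cbind(mu1, mu2, deparse.level = 0),
                 projected_means = pm),
            class = "lda_fit")
}

classify_scores <- function(lda, scores) {
  proj <- drop(as.matrix(scores) %*% lda$direction)
  # tie at the threshold goes to the alphabetically first class
  as.character(ifelse(proj >= lda$threshold, lda$classes[1], lda$classes[2]))
}

#' Fit the full PCA-LDA classification model
#'
#' The classifier used to differentiate the two algal cell types from
#' binned single-cell spectra: PCA to the top `k` components (k = 2 by
#' default; further components add little captured variance), then a Fisher
#' linear discriminant on the component scores.
#'
#' @param X A [feature_matrix()] with labels, or a bare matrix plus
#'   `labels`.
#' @param labels Per-row class labels (taken from `X` when absent).
#' @param k Number of principal components (default 2).
#' @return Object of class `pca_lda`: the PCA fit, the LDA fit, training
#'   scores, class score centroids and `k`.
#' @examples
#' pr <- default_profiles()
#' sp <- c(lapply(1:5, function(i) generate_spectrum(pr$euglena, seed = i)),
#'         lapply(1:5, function(i) generate_spectrum(pr$phacus, seed = 100 + i)))
#' fm <- feature_matrix(lapply(sp, normalize_and_bin),
#'                      labels = rep(c("euglena", "phacus"), each = 5))
#' model <- fit_pca_lda(fm)
#' @export
fit_pca_lda <- function(X, labels = NULL, k = 2) {
  if (inherits(X, "feature_matrix") && is.null(labels)) labels <- X$labels
  if (is.null(labels)) stop("fit_pca_lda: labels required")
  pca <- fit_pca(X, k)
  lda <- fit_lda(pca$scores, labels)
  centroids <- rbind(colMeans(pca$scores[labels == lda$classes[1], , drop = FALSE]),
                     colMeans(pca$scores[labels == lda$classes[2], , drop = FALSE]))
  rownames(centroids) <- lda$classes
  structure(list(pca = pca, lda = lda, k = k,
                 train_scores = pca$scores, train_labels = as.character(labels),
                 score_centroids = centroids),
            class = "pca_lda")
}

#' @export
print.pca_lda <- function(x, ...) {
  cat(sprintf("<pca_lda> k = %d (%.1f%% variance captured), classes %s vs %s\n",
              x$k, 100 * sum(x$pca$explained_variance_fraction),
              x$lda$classes[1], x$lda$classes[2]))
  invisible(x)
}

#' Apportion test cells with a trained PCA-LDA model
#'
#' Test rows are centered with the training mean, projected on the training
#' loadings and classified by the training discriminant -- no part of the
#' model is refit.  Score coordinates are returned for plotting.
#'
#' @param model A fitted [fit_pca_lda()] model.
#' @param X_test A [feature_matrix()] (labels optional) or bare matrix.
#' @return List: `predicted` (character), `scores` (n x k), `accuracy`
#'   (fraction agreeing with recorded labels; `NA` when labels absent or
#'   the test set is empty), `misclassified` (ids of disagreeing rows).
#' @export
apportion <- function(model, X_test) {
  stopifnot(inherits(model, "pca_lda"))
  mat <- if (inherits(X_test, "feature_matrix")) X_test$values else as.matrix(X_test)
  labels <- if (inherits(X_test, "feature_matrix")) X_test$labels else NULL
  ids <- if (inherits(X_test, "feature_matrix")) X_test$ids else seq_len(nrow(mat))
  if (nrow(mat) == 0)
    return(list(predicted = character(0),
                scores = matrix(numeric(0), 0, model$k),
                accuracy = NA_real_, misclassified = integer(0)))
  if (ncol(mat) != length(model$pca$mean))
    stop("apportion: test columns do not match the training grid")
  scores <- sweep(mat, 2, model$pca$mean) %*% model$pca$loadings
  pred <- classify_scores(model$lda, scores)
  acc <- NA_real_
  mis <- integer(0)
  if (!is.null(labels)) {
    wrong <- pred != as.character(labels)
    acc <- mean(!wrong)
    mis <- ids[wrong]
  }
  list(predicted = pred, scores = scores, accuracy = acc, misclassified = mis)
}

#' @rdname apportion
#' @export
predict.pca_lda <- function(object, newdata, ...) apportion(object, newdata)

#' Leave-one-out cross-validated accuracy of the PCA-LDA model
#'
#' For every cell, the whole model -- PCA mean, loadings and the
#' discriminant -- is refit on the remaining cells (no information leaks
#' from the held-out row) and the held-out cell is classified.  Setting
#' `refit_pca = FALSE` instead fixes the PCA on the full data and refits
#' only the LDA per fold (faster, mildly optimistic; kept as a documented
#' alternative).
#'
#' @param X A labelled [feature_matrix()] (>= 4 rows, both classes >= 2).
#' @param labels Labels (taken from `X` when absent).
#' @param k Number of principal components.
#' @param refit_pca Refit PCA inside every fold (default TRUE).
#' @return List: `accuracy` (fraction in \[0, 1\]) and `verdicts`
#'   (data.frame id, label, predicted, correct).
#' @export
loocv_accuracy <- function(X, labels = NULL, k = 2, refit_pca = TRUE) {
  mat <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (inherits(X, "feature_matrix") && is.null(labels)) labels <- X$labels
  ids <- if (inherits(X, "feature_matrix")) X$ids else seq_len(nrow(mat))
  labels <- as.character(labels)
  n <- nrow(mat)
  if (n < 4) stop("loocv_accuracy: need at least 4 rows")
  full_pca <- if (!refit_pca) fit_pca(mat, k)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- mat[-i, , drop = FALSE]
    trl <- labels[-i]
    if (refit_pca) {
      pca <- fit_pca(tr, k)
    } else pca <- full_pca
    sc_tr <- sweep(tr, 2, pca$mean) %*% pca$loadings
    lda <- fit_lda(sc_tr, trl)
    sc_te <- (mat[i, ] - pca$mean) %*% pca$loadings
    pred[i] <- classify_scores(lda, sc_te)
  }
  verdicts <- data.frame(id = ids, label = labels, predicted = pred,
                         correct = pred == labels)
  list(accuracy = mean(verdicts$correct), verdicts = verdicts)
}

#' Serialize / restore a PCA-LDA model as JSON
#'
#' A single JSON document holding the mean spectrum, loadings,
#' explained-variance fractions, discriminant, class names, `k` and a hash
#' of the bin grid, sufficient to classify new feature matrices.
#'
#' @param model A [fit_pca_lda()] model.
#' @param path Output `.json` path.
#' @return `read_pca_lda()` returns the restored `pca_lda` model (without
#'   training scores).
#' @export
write_pca_lda <- function(model, path) {
  doc <- list(
    k = model$k,
    grid_hash = rlang::hash(bin_grid_edges()),
    mean = as.numeric(model$pca$mean),
    loadings = lapply(seq_len(model$k),
                      function(j) as.numeric(model$pca$loadings[, j])),
    explained_variance_fraction =
      as.numeric(model$pca$explained_variance_fraction),
    discriminant = list(direction = as.numeric(model$lda$direction),
                        threshold = model$lda$threshold,
                        classes = model$lda$classes,
                        projected_means = as.numeric(model$lda$projected_means)),
    score_centroids = lapply(seq_len(nrow(model$score_centroids)),
                             function(i) as.numeric(model$score_centroids[i, ])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_lda
#' @export
read_pca_lda <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- if (is.matrix(doc$loadings)) t(doc$loadings)
              else do.call(cbind, doc$loadings)
  pca <- structure(list(mean = doc$mean, loadings = loadings,
                        explained_variance_fraction =
                          doc$explained_variance_fraction,
                        scores = NULL),
                   class = "pca_fit")
  lda <- structure(list(direction = doc$discriminant$direction,
                        threshold = doc$discriminant$threshold,
                        classes = doc$discriminant$classes,
                        class_means = NULL,
                        projected_means = doc$discriminant$projected_means),
                   class = "lda_fit")
  centroids <- if (is.matrix(doc$score_centroids)) doc$score_centroids
               else do.call(rbind, doc$score_centroids)
  rownames(centroids) <- lda$classes
  structure(list(pca = pca, lda = lda, k = doc$k,
                 train_scores = NULL, train_labels = NULL,
                 score_centroids = centroids),
            class = "pca_lda")
}

#' Score plot of a PCA-LDA model
#'
#' Training scores (open symbols) and optional test scores (filled), the
#' analogue of the published two-component score plots, written as PNG.
#'
#' @param model A [fit_pca_lda()] model with training scores.
#' @param test Optional result of [apportion()] on a test set.
#' @param path Output `.png` path.
#' @export
plot_scores_png <- function(model, test = NULL, path) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  tr <- model$train_scores
  cls <- model$lda$classes
  col_tr <- ifelse(model$train_labels == cls[1], "steelblue", "black")
  xlim <- range(tr[, 1], if (!is.null(test)) test$scores[, 1])
  ylim <- range(tr[, 2], if (!is.null(test)) test$scores[, 2])
  graphics::plot(tr[, 1], tr[, 2], col = col_tr,
                 pch = ifelse(model$train_labels == cls[1], 0, 1),
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * model$pca$explained_variance_fraction[1]),
                 ylab = sprintf("PC2 (%.1f%%)",
                                100 * model$pca$explained_variance_fraction[2]),
                 xlim = xlim, ylim = ylim,
                 main = "PCA-LDA score plot")
  if (!is.null(test)) {
    col_te <- ifelse(test$predicted == cls[1], "steelblue", "black")
    graphics::points(test$scores[, 1], test$scores[, 2], col = col_te,
                     pch = ifelse(test$predicted == cls[1], 15, 16))
  }
  graphics::legend("topright", legend = cls, col = c("steelblue", "black"),
                   pch = c(0, 1), bty = "n")
  invisible(path)
}
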