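# Baseline classifiers for head-to-head benchmarks: PCA + minimum distance
# to class mean, and a thin adapter over an off-the-shelf SVM.

#' Fit a PCA + minimum-distance classifier
#'
#' PCA on the pooled, centered training spectra; the number of retained
#' components is the smallest reaching `variance_kept` of total variance;
#' class means are stored in the projected space and prediction assigns each
#' pixel to the nearest mean (Euclidean distance in raw principal-component
#' coordinates).
#'
#' @param training named list (by class code) of training spectra matrices.
#' @param variance_kept fraction of variance to retain, in `(0, 1]`.
#' @return an object of class `"pca_mind"`: `center`, `rotation`
#'   (bands x p, orthonormal columns), `class_means` (class x p),
#'   `class_code`, `p`.
#' @export
fit_pca_mind <- function(training, variance_kept = 0.99) {
  stopifnot(variance_kept > 0, variance_kept <= 1)
  codes <- as.integer(names(training))
  if (any(is.na(codes))) codes <- seq_along(training)
  ord <- order(codes); training <- training[ord]; codes <- codes[ord]
  X <- do.call(rbind, lapply(training, as.matrix))
  if (nrow(X) < 2L) stop("need at least 2 training spectra")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) == 0) stop("training spectra are all identical (zero variance)")
  cum <- cumsum(v) / sum(v)
  p <- which(cum >= variance_kept - 1e-12)[1]
  rot <- pc$rotation[, seq_len(p), drop = FALSE]
  proj <- function(m) sweep(as.matrix(m), 2L, pc$center) %*% rot
  means <- matrix(vapply(training, function(m) colMeans(proj(m)),
                         numeric(p)),
                  ncol = p, byrow = TRUE)
  structure(list(center = pc$center, rotation = rot,
                 class_means = means, class_code = codes, p = p),
            class = "pca_mind")
}

#' @export
print.pca_mind <- function(x, ...) {
  cat(sprintf("<pca_mind> %d components, %d classes\n",
              x$p, length(x$class_code)))
  invisible(x)
}

#' Classify a cube with a fitted PCA + minimum-distance model
#'
#' @param object a `"pca_mind"` model.
#' @param cube an [hsi_cube()] (or a pixel-by-band matrix).
#' @param ... unused.
#' @return a [label_map()] when given a cube, otherwise an integer vector of
#'   class codes.
#' @export
predict.pca_mind <- function(object, cube, ...) {
  is_cube <- inherits(cube, "hsi_cube")
  px <- if (is_cube) cube_to_matrix(cube) else as.matrix(cube)
  if (ncol(px) != length(object$center)) stop("band count mismatch")
  proj <- sweep(px, 2L, object$center) %*% object$rotation
  # squared distances to each class mean
  d2 <- outer(rowSums(proj^2), rep(1, nrow(object$class_means))) -
    2 * proj %*% t(object$class_means) +
    outer(rep(1, nrow(proj)), rowSums(object$class_means^2))
  pred <- object$class_code[apply(d2, 1L, which.min)]
  if (!is_cube) return(pred)
  label_map(matrix(pred, cube$rows, cube$cols, byrow = TRUE))
}

#' SVM baseline adapter
#'
#' Thin wrapper over an off-the-shelf RBF support vector machine (package
#' \pkg{e1071}) for comparison runs; its hyperparameters are exposed, not
#' tuned here.
#'
#' @param training named list (by class code) of training spectra matrices.
#' @param cube an [hsi_cube()] to classify.
#' @param ... passed to [e1071::svm()] (e.g. `cost`, `gamma`).
#' @return a [label_map()].
#' @export
svm_baseline <- function(training, cube, ...) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("the SVM baseline needs the e1071 package")
  codes <- as.integer(names(training))
  if (any(is.na(codes))) codes <- seq_along(training)
  X <- do.call(rbind, lapply(training, as.matrix))
  y <- factor(rep(codes, vapply(training, nrow, integer(1))))
  fit <- e1071::svm(X, y, kernel = "radial", ...)
  px <- cube_to_matrix(cube)
  pred <- as.integer(as.character(stats::predict(fit, px)))
  label_map(matrix(pred, cube$rows, cube$cols, byrow = TRUE))
}
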