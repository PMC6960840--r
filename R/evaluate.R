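# Accuracy assessment: confusion matrix, overall / per-class (producer's)
# accuracy, Cohen's kappa.

#' Confusion matrix between truth and prediction
#'
#' Pixels with truth code 0 (unlabeled) are excluded. The matrix is square
#' over the union of nonzero codes present in either map; rows index truth,
#' columns prediction.
#'
#' @param truth,pred [label_map()]s (or integer matrices/vectors) of the
#'   same shape.
#' @return an object of class `"ddsr_confusion"`: integer matrix with
#'   `total` attribute.
#' @export
confusion <- function(truth, pred) {
  tv <- if (inherits(truth, "label_map")) truth$labels else as.matrix(truth)
  pv <- if (inherits(pred, "label_map")) pred$labels else as.matrix(pred)
  if (!identical(dim(tv), dim(pv)))
    stop("truth and prediction shapes differ")
  keep <- tv > 0L
  tv <- tv[keep]; pv <- pv[keep]
  codes <- sort(unique(c(tv, pv)))
  codes <- codes[codes > 0L]
  f <- factor(tv, levels = codes)
  g <- factor(pv, levels = codes)
  m <- table(truth = f, predicted = g)
  m <- matrix(as.integer(m), length(codes), length(codes),
              dimnames = list(truth = codes, predicted = codes))
  structure(m, class = c("ddsr_confusion", "matrix"), total = sum(m))
}

.cm_matrix <- function(cm) {
  if (inherits(cm, "ddsr_confusion")) unclass(cm) else as.matrix(cm)
}

#' Overall accuracy (percent)
#' @param cm a confusion matrix.
#' @return `100 * trace / total`.
#' @export
overall_accuracy <- function(cm) {
  m <- .cm_matrix(cm)
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(m)) / tot
}

#' Per-class producer's accuracy (percent)
#'
#' Diagonal over row totals: the fraction of each ground-truth class that
#' was labeled correctly.
#'
#' @param cm a confusion matrix.
#' @return named numeric vector of percentages.
#' @export
per_class_accuracy <- function(cm) {
  m <- .cm_matrix(cm)
  rt <- rowSums(m)
  if (any(rt == 0)) stop("class with zero truth pixels")
  stats::setNames(100 * diag(m) / rt, rownames(m))
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_o = trace/total` and `p_e = sum_i row_i * col_i / total^2`. A
#' degenerate single-cell matrix (perfect agreement on one class) returns 1.
#'
#' @param cm a confusion matrix.
#' @return kappa in `[-1, 1]`.
#' @export
kappa_coef <- function(cm) {
  m <- .cm_matrix(cm)
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / tot
  pe <- sum(rowSums(m) * colSums(m)) / tot^2
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Full accuracy report for a classification map
#'
#' @param truth,pred [label_map()]s of the same shape.
#' @return list with `confusion`, `overall_accuracy`, `per_class_accuracy`,
#'   `kappa`, `n` (evaluated pixels).
#' @export
evaluate_map <- function(truth, pred) {
  cm <- confusion(truth, pred)
  list(confusion = cm,
       overall_accuracy = overall_accuracy(cm),
       per_class_accuracy = per_class_accuracy(cm),
       kappa = kappa_coef(cm),
       n = attr(cm, "total"))
}

#' Mean and standard deviation of metrics over repeated runs
#'
#' Runs a user-supplied single-run function once per seed (each run should
#' re-draw its training samples from the seed) and reports mean and sample
#' standard deviation of overall accuracy and kappa, the form accuracy
#' tables in the remote-sensing literature are reported in.
#'
#' @param run_fn function(seed) returning a list with at least
#'   `overall_accuracy` and `kappa`.
#' @param seeds integer vector of seeds (default 3 runs).
#' @return list with `oa_mean`, `oa_sd`, `kappa_mean`, `kappa_sd`, `runs`
#'   (per-run metric list).
#' @export
repeat_runs <- function(run_fn, seeds = 1:3) {
  runs <- lapply(seeds, run_fn)
  oa <- vapply(runs, `[[`, numeric(1), "overall_accuracy")
  ka <- vapply(runs, `[[`, numeric(1), "kappa")
  list(oa_mean = mean(oa), oa_sd = stats::sd(oa),
       kappa_mean = mean(ka), kappa_sd = stats::sd(ka),
       runs = runs)
}
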