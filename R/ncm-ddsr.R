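#' Fit a diverse-density sparse-representation classifier
#'
#' The main fitting function. For each ground-cover class a representative
#' spectrum (dictionary atom) is learned by maximizing the diverse-density
#' multiple-instance objective over the class's training spectra (positive
#' bags) against all other classes (negative bags); the unit-normalized
#' atoms form the classification dictionary. Prediction sparse-codes each
#' pixel over the dictionary with a sign- and simplex-constrained matching
#' pursuit and applies the hybrid coefficient-threshold / minimum-residual
#' decision rule.
#'
#' The method targets the small-sample regime: with fewer training pixels
#' than spectral bands, a single noise-robust atom per class avoids both the
#' information loss of dimension reduction and the hyperparameter
#' sensitivity of margin classifiers.
#'
#' @param training named list (by class code) of matrices, one training
#'   spectrum per row; at least 2 classes.
#' @param bag_size instances per multiple-instance bag (default 1: every
#'   training pixel is its own bag).
#' @param refine run continuous (BFGS) refinement of each class's
#'   diverse-density maximum beyond the best training instance.
#' @param normalize L2-normalize spectra before diverse-density learning.
#' @param atoms_per_class atoms learned per class (see [learn_dictionary()]).
#' @param xi matching-pursuit relaxation factor (residual-norm stopping
#'   tolerance on unit-norm pixels).
#' @param max_iter matching-pursuit iteration cap (`NULL`: 4 x atoms).
#' @param coef_threshold decision threshold for the direct coefficient rule.
#' @param class_names optional character names for the class codes.
#' @return an object of class `"ncm_ddsr"` with elements `dictionary`
#'   (a `"ddsr_dictionary"`), `cfg` (an [mp_config()]), `n_train` (per-class
#'   training counts), `call`.
#' @seealso [predict.ncm_ddsr()], [learn_dictionary()], [matching_pursuit()],
#'   [decide()]
#' @examples
#' set.seed(1)
#' tr <- list(`1` = matrix(rnorm(40, 5), 8), `2` = matrix(rnorm(40, -5), 8))
#' fit <- ncm_ddsr(tr)
#' fit
#' @export
ncm_ddsr <- function(training, bag_size = 1L, refine = FALSE,
                     normalize = FALSE, atoms_per_class = 1L, xi = 1e-3,
                     max_iter = NULL, coef_threshold = 0.5,
                     class_names = NULL) {
  dict <- learn_dictionary(training, bag_size = bag_size, refine = refine,
                           normalize = normalize,
                           atoms_per_class = atoms_per_class,
                           class_names = class_names)
  structure(
    list(dictionary = dict,
         cfg = mp_config(xi = xi, max_iter = max_iter,
                         coef_threshold = coef_threshold),
         n_train = vapply(training, nrow, integer(1)),
         call = match.call()),
    class = "ncm_ddsr"
  )
}

#' Predict ground-cover classes for a cube or spectra
#'
#' @param object a fitted [ncm_ddsr()] model.
#' @param newdata an [hsi_cube()] or a pixel-by-band numeric matrix.
#' @param ... passed to [decide()] (e.g. `refit_residual`).
#' @return a [label_map()] for a cube; an integer vector of class codes for
#'   a matrix.
#' @export
predict.ncm_ddsr <- function(object, newdata, ...) {
  if (inherits(newdata, "hsi_cube"))
    return(classify_cube(newdata, object$dictionary, object$cfg, ...))
  px <- as.matrix(newdata)
  vapply(seq_len(nrow(px)), function(p) {
    xn <- normalize_pixel(px[p, ])
    sc <- matching_pursuit(xn, object$dictionary, object$cfg)
    decide(sc, xn, object$dictionary,
           threshold = object$cfg$coef_threshold, ...)$class_code
  }, integer(1))
}

#' Extract the learned dictionary atoms
#' @param object a fitted [ncm_ddsr()] model.
#' @param ... unused.
#' @return bands x atoms matrix with class codes as column names.
#' @export
coef.ncm_ddsr <- function(object, ...) {
  a <- object$dictionary$atoms
  colnames(a) <- object$dictionary$class_code
  a
}

#' @export
print.ncm_ddsr <- function(x, ...) {
  cat("Diverse-density sparse-representation classifier\n")
  cat(sprintf("  classes: %d   bands: %d   training spectra: %d\n",
              length(unique(x$dictionary$class_code)), x$dictionary$bands,
              sum(x$n_train)))
  cat(sprintf("  bag size %d, refine %s, pre-normalize %s\n",
              x$dictionary$bag_size, x$dictionary$refine,
              x$dictionary$normalize))
  cat(sprintf("  pursuit: xi = %g, coefficient threshold = %g\n",
              x$cfg$xi, x$cfg$coef_threshold))
  invisible(x)
}

#' @export
summary.ncm_ddsr <- function(object, ...) {
  d <- object$dictionary
  codes <- unique(d$class_code)
  logdd <- if (!is.null(d$concepts))
    vapply(d$concepts, `[[`, numeric(1), "log_dd") else rep(NA_real_, length(codes))
  out <- data.frame(
    class_code = codes,
    class_name = unname(d$class_names[as.character(codes)]),
    n_atoms = as.integer(table(factor(d$class_code, levels = codes))),
    n_train = unname(object$n_train[order(as.integer(names(object$n_train)))]),
    log_dd = logdd
  )
  structure(list(table = out, bands = d$bands, cfg = object$cfg),
            class = "summary.ncm_ddsr")
}

#' @export
print.summary.ncm_ddsr <- function(x, ...) {
  cat("Diverse-density sparse-representation classifier\n")
  cat(sprintf("  %d bands; per-class concepts:\n", x$bands))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot learned dictionary atoms
#'
#' One curve per class atom against band index.
#'
#' @param x a fitted [ncm_ddsr()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ncm_ddsr <- function(x, ...) {
  a <- x$dictionary$atoms
  graphics::matplot(a, type = "l", lty = 1,
                    xlab = "band", ylab = "atom value (unit-norm)", ...)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = seq_len(ncol(a)),
                   legend = x$dictionary$class_names[
                     as.character(x$dictionary$class_code)])
  invisible(x)
}
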