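# Hybrid coefficient / residual decision rule, and whole-cube classification.

#' Decide a pixel's class from its sparse code
#'
#' If any finalized coefficient exceeds `threshold` (default 0.5), the pixel
#' is assigned that atom's class directly. Otherwise the per-class squared
#' reconstruction residual `r_k = ||x - D_k alpha_k||^2` is computed using
#' only class-k atoms with their pursuit coefficients, and the class with
#' the minimum residual wins. Ties break to the lowest class code; an
#' all-zero code degenerates to a tie across all classes and is flagged.
#'
#' @param code a `"sparse_code"` from [matching_pursuit()].
#' @param x the unit-normalized pixel.
#' @param dict the `"ddsr_dictionary"` used for the pursuit.
#' @param threshold coefficient decision threshold in `(0, 1]`.
#' @param per_class_sum treat the per-class *sum* of coefficients as the
#'   thresholded quantity instead of single atoms (only differs for
#'   multi-atom-per-class dictionaries).
#' @param refit_residual re-fit `alpha_k` per class by least squares before
#'   computing `r_k`, instead of reusing the pursuit coefficients.
#' @return an object of class `"ddsr_decision"`: `class_code`, `rule_used`
#'   (`"coefficient"` or `"residual"`), `top_coefficient`,
#'   `per_class_residuals` (named, `NULL` when the coefficient rule fired),
#'   `degenerate` (logical: all-zero code).
#' @export
decide <- function(code, x, dict, threshold = 0.5,
                   per_class_sum = FALSE, refit_residual = FALSE) {
  stopifnot(inherits(code, "sparse_code"), inherits(dict, "ddsr_dictionary"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  a <- code$coefficients
  top <- max(a)
  if (per_class_sum) {
    sums <- tapply(a, dict$class_code, sum)
    if (max(sums) > threshold) {
      k <- as.integer(names(sums)[which.max(sums)])
      return(structure(list(class_code = k, rule_used = "coefficient",
                            top_coefficient = top,
                            per_class_residuals = NULL, degenerate = FALSE),
                       class = "ddsr_decision"))
    }
  } else if (top > threshold) {
    k <- dict$class_code[which.max(a)]
    return(structure(list(class_code = k, rule_used = "coefficient",
                          top_coefficient = top,
                          per_class_residuals = NULL, degenerate = FALSE),
                     class = "ddsr_decision"))
  }
  codes <- sort(unique(dict$class_code))
  res <- vapply(codes, function(k) {
    sel <- dict$class_code == k
    Dk <- dict$atoms[, sel, drop = FALSE]
    ak <- a[sel]
    if (refit_residual && any(sel)) {
      fit <- stats::lsfit(Dk, x, intercept = FALSE)
      ak <- pmax(fit$coefficients, 0)
    }
    sum((x - Dk %*% ak)^2)
  }, numeric(1))
  names(res) <- codes
  structure(list(class_code = codes[which.min(res)],
                 rule_used = "residual",
                 top_coefficient = top,
                 per_class_residuals = res,
                 degenerate = all(a == 0)),
            class = "ddsr_decision")
}

#' @export
print.ddsr_decision <- function(x, ...) {
  cat(sprintf("<ddsr_decision> class %d via %s rule (top coef %.4f)\n",
              x$class_code, x$rule_used, x$top_coefficient))
  invisible(x)
}

#' Classify every pixel of a cube
#'
#' Applies normalize -> matching pursuit -> decide to each pixel of the
#' cube, producing a classification map. Deterministic given its inputs.
#' Pixels that are exactly zero in every band cannot be normalized and
#' receive `fill_code` (default 0, the background code).
#'
#' @param cube an [hsi_cube()], band count matching the dictionary.
#' @param dict a `"ddsr_dictionary"`.
#' @param cfg an [mp_config()].
#' @param fill_code label for unclassifiable zero pixels.
#' @param audit optional path: write a tab-separated per-pixel decision log
#'   (row, col, class, rule, top coefficient, residual norm).
#' @param ... further arguments passed to [decide()].
#' @return a [label_map()] of the same spatial shape.
#' @export
classify_cube <- function(cube, dict, cfg = mp_config(), fill_code = 0L,
                          audit = NULL, ...) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(dict, "ddsr_dictionary"))
  if (cube$bands != dict$bands)
    stop("cube band count does not match dictionary")
  px <- cube_to_matrix(cube)
  out <- integer(nrow(px))
  log_rows <- if (!is.null(audit)) vector("list", nrow(px))
  for (p in seq_len(nrow(px))) {
    v <- px[p, ]
    rr <- (p - 1L) %/% cube$cols + 1L
    cc <- (p - 1L) %% cube$cols + 1L
    if (all(v == 0)) {
      out[p] <- fill_code
      if (!is.null(audit))
        log_rows[[p]] <- data.frame(row = rr, col = cc, class = fill_code,
                                    rule = "fill", top_coefficient = NA_real_,
                                    residual_norm = NA_real_)
      next
    }
    xn <- normalize_pixel(v)
    sc <- matching_pursuit(xn, dict, cfg)
    d <- decide(sc, xn, dict, threshold = cfg$coef_threshold, ...)
    out[p] <- d$class_code
    if (!is.null(audit))
      log_rows[[p]] <- data.frame(row = rr, col = cc, class = d$class_code,
                                  rule = d$rule_used,
                                  top_coefficient = d$top_coefficient,
                                  residual_norm = sc$final_residual_norm)
  }
  if (!is.null(audit))
    utils::write.table(do.call(rbind, log_rows), audit, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (any(out == fill_code) && fill_code == 0L && any(px != 0))
    if (any(rowSums(abs(px)) == 0))
      message("zero-vector pixels assigned fill code ", fill_code)
  labels <- matrix(out, cube$rows, cube$cols, byrow = TRUE)
  nm <- dict$class_names
  label_map(labels, class_names = nm)
}
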