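# Sign- and simplex-constrained matching pursuit over a class-tagged
# dictionary.
#
# At each step the residual is projected onto the atom with the largest
# *positive* inner product (negatively correlated atoms are never selected:
# reflectance mixtures have non-negative abundances), the projection is
# subtracted, and the coefficient accumulates onto that atom. The pursuit
# stops when the residual norm falls below the relaxation factor xi, when
# the accumulated coefficient mass reaches 1, when no atom has positive
# correlation, or at the iteration cap. Accumulated coefficients are then
# rescaled to sum to 1 (simplex projection by rescaling; preserves ranking).

#' Matching-pursuit configuration
#'
#' @param xi relaxation factor: the pursuit stops once the residual norm of
#'   the (unit-norm) pixel drops to `xi` or below. Dimensionless, on the
#'   scale of a unit vector.
#' @param max_iter iteration cap; `NULL` means 4 x number of atoms, set at
#'   pursuit time.
#' @param coef_threshold decision threshold used downstream: a finalized
#'   coefficient above it classifies the pixel directly.
#' @return an object of class `"mp_config"`.
#' @export
mp_config <- function(xi = 1e-3, max_iter = NULL, coef_threshold = 0.5) {
  stopifnot(xi >= 0, is.null(max_iter) || max_iter >= 1,
            coef_threshold > 0, coef_threshold <= 1)
  structure(list(xi = xi,
                 max_iter = if (is.null(max_iter)) NULL else as.integer(max_iter),
                 coef_threshold = coef_threshold),
            class = "mp_config")
}

#' Normalize a pixel spectrum to unit L2 norm
#' @param x numeric vector, not all zero.
#' @return `x / ||x||_2`.
#' @export
normalize_pixel <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalize a zero spectrum")
  x / nrm
}

#' Select the best positively-correlated atom
#'
#' Returns the atom index maximizing the inner product with the residual,
#' provided that maximum is strictly positive; `NULL` otherwise. Ties break
#' to the lowest atom index.
#'
#' @param residual numeric vector.
#' @param dict a `"ddsr_dictionary"`.
#' @return list with `index` and `inner_product`, or `NULL` when no atom has
#'   positive inner product.
#' @export
select_atom <- function(residual, dict) {
  stopifnot(inherits(dict, "ddsr_dictionary"))
  if (length(residual) != dict$bands)
    stop("residual length does not match dictionary band count")
  ip <- colSums(dict$atoms * residual)
  i <- which.max(ip)
  if (ip[i] <= 0) return(NULL)
  list(index = i, inner_product = ip[i])
}

#' Constrained matching pursuit of one pixel
#'
#' @param x unit-normalized pixel spectrum (see [normalize_pixel()]).
#' @param dict a `"ddsr_dictionary"`.
#' @param cfg an [mp_config()].
#' @return an object of class `"sparse_code"`: `coefficients` (per-atom,
#'   non-negative, summing to 1 when any atom was selected), `raw_sum` (the
#'   pre-rescaling mass), `selected` (data.frame of iteration, atom index,
#'   raw inner product), `final_residual_norm`, `residual` (the final
#'   residual vector), and `terminated_by` (one of `"simplex_full"`,
#'   `"no_positive_atom"`, `"residual_tol"`, `"max_iter"`).
#' @export
matching_pursuit <- function(x, dict, cfg = mp_config()) {
  stopifnot(inherits(dict, "ddsr_dictionary"), inherits(cfg, "mp_config"))
  if (length(x) != dict$bands)
    stop("pixel length does not match dictionary band count")
  if (abs(sum(x^2) - 1) > 1e-6)
    stop("x must be unit-normalized (see normalize_pixel)")
  m_atoms <- ncol(dict$atoms)
  max_iter <- if (is.null(cfg$max_iter)) 4L * m_atoms else cfg$max_iter
  coefs <- numeric(m_atoms)
  sel_iter <- integer(0); sel_atom <- integer(0); sel_ip <- numeric(0)
  r <- x
  terminated <- "max_iter"
  for (it in seq_len(max_iter)) {
    s <- select_atom(r, dict)
    if (is.null(s)) { terminated <- "no_positive_atom"; break }
    cm <- s$inner_product
    r <- r - cm * dict$atoms[, s$index]
    coefs[s$index] <- coefs[s$index] + cm
    sel_iter <- c(sel_iter, it); sel_atom <- c(sel_atom, s$index)
    sel_ip <- c(sel_ip, cm)
    if (sqrt(sum(r^2)) <= cfg$xi) { terminated <- "residual_tol"; break }
    if (sum(coefs) >= 1) { terminated <- "simplex_full"; break }
  }
  raw_sum <- sum(coefs)
  final <- if (raw_sum > 0) coefs / raw_sum else coefs
  structure(
    list(coefficients = final,
         raw_sum = raw_sum,
         selected = data.frame(iteration = sel_iter, atom = sel_atom,
                               inner_product = sel_ip),
         final_residual_norm = sqrt(sum(r^2)),
         residual = r,
         terminated_by = terminated),
    class = "sparse_code"
  )
}

#' @export
print.sparse_code <- function(x, ...) {
  nz <- which(x$coefficients > 0)
  cat(sprintf("<sparse_code> %d atoms selected, residual %.3g (%s)\n",
              length(nz), x$final_residual_norm, x$terminated_by))
  if (length(nz))
    cat("  coefficients:",
        paste(sprintf("[%d] %.4f", nz, x$coefficients[nz]), collapse = ", "),
        "\n")
  invisible(x)
}

#' Energy-conservation check of a pursuit expansion
#'
#' The greedy residual update satisfies the Pythagorean decomposition
#' `||x||^2 = sum_m c_m^2 + ||R^M x||^2` over the raw (pre-rescaling)
#' expansion coefficients. Returns the absolute defect
#' `| ||x||^2 - sum c_m^2 - ||R^M x||^2 |`, which should sit at rounding
#' level for any completed pursuit.
#'
#' @param code a `"sparse_code"` with its selection trace.
#' @param x the unit-normalized pixel the code was computed from.
#' @return non-negative defect.
#' @export
expansion_energy_check <- function(code, x) {
  stopifnot(inherits(code, "sparse_code"))
  if (is.null(code$selected)) stop("sparse code lacks its selection trace")
  abs(sum(x^2) - sum(code$selected$inner_product^2) -
        code$final_residual_norm^2)
}
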