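#' Construct a hyperspectral cube
#'
#' In-memory container for a reflectance cube. Data are always held as a
#' numeric array indexed `(row, col, band)` regardless of the interleave the
#' file on disk used; the band axis is last by convention throughout the
#' package.
#'
#' @param data numeric array of dimension `rows x cols x bands`, or a matrix
#'   (interpreted as a single-band image).
#' @param wavelengths optional numeric vector of per-band centers in nm;
#'   must be strictly increasing and of length `bands`.
#' @param interleave storage interleave to use when the cube is written out;
#'   one of `"bsq"`, `"bil"`, `"bip"`. Irrelevant in memory.
#' @return an object of class `"hsi_cube"` with elements `data`, `rows`,
#'   `cols`, `bands`, `wavelengths`, `interleave`.
#' @examples
#' cube <- hsi_cube(array(runif(4 * 5 * 3), c(4, 5, 3)))
#' dim(cube$data)
#' @export
hsi_cube <- function(data, wavelengths = NULL, interleave = "bsq") {
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x bands array")
  d <- dim(data)
  if (any(d < 1L)) stop("rows, cols and bands must all be >= 1")
  if (!all(is.finite(data))) stop("cube contains non-finite values")
  storage.mode(data) <- "double"
  interleave <- match.arg(tolower(interleave), c("bsq", "bil", "bip"))
  if (!is.null(wavelengths)) {
    if (length(wavelengths) != d[3L])
      stop("wavelengths length must equal the number of bands")
    if (any(diff(wavelengths) <= 0))
      stop("wavelengths must be strictly increasing")
  }
  structure(
    list(data = data, rows = d[1L], cols = d[2L], bands = d[3L],
         wavelengths = wavelengths, interleave = interleave),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%s)\n",
              x$rows, x$cols, x$bands, x$interleave))
  if (!is.null(x$wavelengths))
    cat(sprintf("  wavelengths: %.1f - %.1f nm\n",
                min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Construct a label map
#'
#' Integer class codes per pixel. Code 0 is reserved for unlabeled /
#' background pixels and is never emitted by the classifiers.
#'
#' @param labels integer matrix (`rows x cols`) of class codes, 0 = unlabeled.
#' @param class_names optional character vector naming classes; either named
#'   by code (e.g. `c("1" = "water")`) or unnamed and matched to the sorted
#'   nonzero codes present.
#' @return an object of class `"label_map"`.
#' @export
label_map <- function(labels, class_names = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers (0 = unlabeled)")
  codes <- sort(unique(labels[labels > 0L]))
  if (is.null(class_names)) {
    class_names <- stats::setNames(paste0("class_", codes), codes)
  } else if (is.null(names(class_names))) {
    if (length(class_names) != length(codes))
      stop("unnamed class_names must match the number of nonzero codes")
    class_names <- stats::setNames(as.character(class_names), codes)
  } else {
    missing <- setdiff(as.character(codes), names(class_names))
    if (length(missing))
      stop("class_names missing entries for codes: ",
           paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, class_names = class_names),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  codes <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<label_map> %d x %d, %d classes, %d labeled pixels\n",
              nrow(x$labels), ncol(x$labels), length(codes),
              sum(x$labels > 0L)))
  invisible(x)
}

#' Extract pixel spectra for one class
#'
#' Pulls the band vectors of every pixel carrying a given label code, in
#' row-major order (row varies slowest).
#'
#' @param cube an [hsi_cube()].
#' @param map a [label_map()] with the same spatial shape as `cube`.
#' @param class_code integer class code to extract.
#' @return a numeric matrix, one row per pixel, `bands` columns. Zero rows
#'   when the code is absent.
#' @export
extract_pixels <- function(cube, map, class_code) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(map, "label_map"))
  if (!identical(dim(map$labels), c(cube$rows, cube$cols)))
    stop("label map shape does not match cube shape")
  class_code <- as.integer(class_code)
  if (class_code != 0L &&
      !as.character(class_code) %in% names(map$class_names))
    stop("unknown class code: ", class_code)
  idx <- which(t(map$labels) == class_code)   # row-major order
  if (!length(idx))
    return(matrix(numeric(0), 0L, cube$bands))
  # convert row-major linear index back to (row, col)
  rr <- ((idx - 1L) %/% cube$cols) + 1L
  cc <- ((idx - 1L) %% cube$cols) + 1L
  flat <- matrix(cube$data, cube$rows * cube$cols, cube$bands)
  flat[(cc - 1L) * cube$rows + rr, , drop = FALSE]
}

#' Flatten a cube to a pixel-by-band matrix
#'
#' @param cube an [hsi_cube()].
#' @return matrix with `rows*cols` rows (row-major pixel order) and `bands`
#'   columns.
#' @keywords internal
cube_to_matrix <- function(cube) {
  flat <- matrix(cube$data, cube$rows * cube$cols, cube$bands)
  # column-major -> row-major pixel order
  ord <- as.vector(t(matrix(seq_len(cube$rows * cube$cols),
                            cube$rows, cube$cols)))
  flat[ord, , drop = FALSE]
}
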