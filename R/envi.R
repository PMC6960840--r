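# ENVI header + flat-binary cube I/O.
# Supported data types: 1 (uint8), 2 (int16), 4 (float32), 12 (uint16).
# Interleaves: BSQ, BIL, BIP. Byte order field honored. Unknown header keys
# are ignored with a warning.

.envi_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.known_keys <- c("envi", "description", "samples", "lines", "bands",
                 "header offset", "file type", "data type", "interleave",
                 "byte order", "wavelength", "wavelength units", "classes",
                 "class names")

#' Parse an ENVI header file
#' @param header_path path to a `.hdr` file.
#' @return named list of header fields (values as character).
#' @keywords internal
parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[[1]], ignore.case = TRUE))
    stop("not an ENVI header: ", header_path)
  # join brace-continued values onto one line
  txt <- paste(lines[-1], collapse = "\n")
  fields <- list()
  pos <- 1L
  for (ln in strsplit(txt, "\n", fixed = TRUE)[[1]]) {
    if (!nzchar(trimws(ln))) next
    if (!grepl("=", ln, fixed = TRUE)) {
      # continuation of a brace block
      if (length(fields)) {
        k <- names(fields)[length(fields)]
        fields[[k]] <- paste(fields[[k]], trimws(ln))
      }
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- tolower(trimws(kv[1]))
    val <- trimws(paste(kv[-1], collapse = "="))
    fields[[key]] <- val
  }
  # merge multiline brace blocks that were split across entries
  unknown <- setdiff(names(fields), .known_keys)
  if (length(unknown))
    warning("ignoring unknown ENVI header keys: ",
            paste(unknown, collapse = ", "))
  fields
}

.parse_brace_list <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

#' Read an ENVI cube
#'
#' Reads a header (`.hdr`) plus flat-binary pair into an [hsi_cube()] with
#' values reordered to the package's `(row, col, band)` convention,
#' independent of the file's interleave.
#'
#' @param header_path path to the `.hdr` file. The binary companion is the
#'   same path without the `.hdr` extension (or with `.img`/`.dat` appended).
#' @return an [hsi_cube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- parse_envi_header(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("header missing required fields: ", paste(miss, collapse = ", "))
  cols <- as.integer(h$samples); rows <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  dtype <- .envi_types[[h[["data type"]]]]
  if (is.null(dtype))
    stop("unsupported ENVI data type: ", h[["data type"]])
  interleave <- tolower(h$interleave)
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L)
    "big" else "little"

  bin_path <- envi_binary_path(header_path)
  if (is.null(bin_path)) stop("binary companion not found for ", header_path)
  n <- rows * cols * bands
  expected <- offset + n * dtype$size
  if (file.info(bin_path)$size != expected)
    stop(sprintf("binary size mismatch: %s has %d bytes, header implies %d",
                 bin_path, file.info(bin_path)$size, expected))
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  vals <- readBin(con, dtype$what, n = n, size = dtype$size,
                  signed = dtype$signed, endian = endian)
  data <- switch(interleave,
    bsq = aperm(array(vals, c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(vals, c(bands, cols, rows)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave)
  )
  wl <- if (!is.null(h$wavelength)) .parse_brace_list(h$wavelength) else NULL
  hsi_cube(data, wavelengths = wl, interleave = interleave)
}

envi_binary_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (cand in c(base, paste0(base, ".img"), paste0(base, ".dat")))
    if (file.exists(cand) && !dir.exists(cand)) return(cand)
  NULL
}

#' Write an ENVI cube
#'
#' Writes a header + flat-binary pair readable by [read_envi()]. Round trips
#' are exact for integer data types; float32 payloads round-trip bitwise at
#' single precision.
#'
#' @param cube an [hsi_cube()].
#' @param header_path output `.hdr` path; the binary goes to the same path
#'   without the extension.
#' @param data_type ENVI data type code: 1 (uint8), 2 (int16), 4 (float32),
#'   12 (uint16).
#' @return invisibly, the binary path.
#' @export
write_envi <- function(cube, header_path, data_type = 4L) {
  stopifnot(inherits(cube, "hsi_cube"))
  dtype <- .envi_types[[as.character(data_type)]]
  if (is.null(dtype)) stop("unsupported ENVI data type: ", data_type)
  bin_path <- sub("\\.hdr$", "", header_path)
  if (identical(bin_path, header_path))
    stop("header_path must end in .hdr")
  interleave <- cube$interleave
  arr <- switch(interleave,
    bsq = aperm(cube$data, c(2, 1, 3)),
    bil = aperm(cube$data, c(2, 3, 1)),
    bip = aperm(cube$data, c(3, 2, 1))
  )
  vals <- as.vector(arr)
  con <- tryCatch(file(bin_path, "wb"),
                  error = function(e) stop("cannot write: ", bin_path))
  if (dtype$what == "integer") {
    writeBin(as.integer(vals), con, size = dtype$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dtype$size, endian = "little")
  }
  close(con)
  hdr <- c(
    "ENVI",
    "description = { ddsr hyperspectral cube }",
    sprintf("samples = %d", cube$cols),
    sprintf("lines = %d", cube$rows),
    sprintf("bands = %d", cube$bands),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", as.integer(data_type)),
    sprintf("interleave = %s", interleave),
    "byte order = 0"
  )
  if (!is.null(cube$wavelengths))
    hdr <- c(hdr, paste0("wavelength = { ",
                         paste(format(cube$wavelengths, digits = 17,
                                      trim = TRUE),
                               collapse = ", "), " }"))
  writeLines(hdr, header_path)
  invisible(bin_path)
}

#' Read a label map from a whitespace-delimited integer grid
#' @param path text file with one image row per line.
#' @param class_names optional class names (see [label_map()]).
#' @return a [label_map()].
#' @export
read_label_grid <- function(path, class_names = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  label_map(m, class_names)
}

#' Write a label map as a whitespace-delimited integer grid
#' @param map a [label_map()].
#' @param path output text path.
#' @export
write_label_grid <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  utils::write.table(map$labels, path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a label map as an ENVI classification raster
#' @param map a [label_map()].
#' @param header_path output `.hdr` path.
#' @export
write_envi_labels <- function(map, header_path) {
  stopifnot(inherits(map, "label_map"))
  cube <- hsi_cube(array(map$labels, c(dim(map$labels), 1L)))
  write_envi(cube, header_path, data_type = 2L)
  # amend header with classification metadata
  hdr <- readLines(header_path)
  hdr <- sub("file type = ENVI Standard", "file type = ENVI Classification",
             hdr, fixed = TRUE)
  codes <- sort(unique(map$labels[map$labels > 0L]))
  hdr <- c(hdr,
           sprintf("classes = %d", length(codes)),
           paste0("class names = { ",
                  paste(map$class_names[as.character(codes)], collapse = ", "),
                  " }"))
  writeLines(hdr, header_path)
  invisible(header_path)
}

#' Read an ENVI classification raster as a label map
#' @param header_path `.hdr` path of a single-band classification raster.
#' @return a [label_map()].
#' @export
read_envi_labels <- function(header_path) {
  cube <- suppressWarnings(read_envi(header_path))
  if (cube$bands != 1L) stop("classification raster must have one band")
  h <- suppressWarnings(parse_envi_header(header_path))
  nms <- NULL
  if (!is.null(h[["class names"]])) {
    nms <- trimws(strsplit(gsub("[{}]", "", h[["class names"]]), ",")[[1]])
  }
  label_map(cube$data[, , 1L], class_names = nms)
}
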