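# Synthetic hyperspectral scenes with known ground truth.
#
# Endmembers are sums of Gaussian bumps on the band grid (rescaled to peak 1),
# laid out in rectangular per-class patches; pure pixels get additive white
# Gaussian noise calibrated to a stated SNR, and an optional fraction of
# labeled pixels are two-endmember convex mixtures.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Specify a synthetic hyperspectral scene
#'
#' @param rows,cols spatial size in pixels.
#' @param bands number of spectral bands.
#' @param n_classes number of ground-cover classes (>= 2).
#' @param snr_db signal-to-noise ratio of the rendered scene in dB
#'   (mean signal power / noise power = `10^(snr_db/10)`).
#' @param mix_fraction fraction in `[0, 1)` of labeled pixels rendered as
#'   two-class convex mixtures rather than pure endmember + noise.
#' @param seed integer seed; all scene randomness derives from it.
#' @param endmember_spec optional list, one element per class, each a matrix
#'   with columns `center`, `width`, `amplitude` describing Gaussian bumps
#'   (band units). When `NULL`, bumps are drawn from `seed` so that classes
#'   are distinct but partially overlapping in support.
#' @param preset `"phi"` (65 bands, 7 classes) or `"aviris"` (166 bands,
#'   6 classes) fills in band/class counts matching the airborne scenes the
#'   simulator emulates; explicit arguments override.
#' @return an object of class `"scene_spec"`.
#' @examples
#' sp <- scene_spec(preset = "phi", snr_db = 30, seed = 1)
#' sp$bands
#' @export
scene_spec <- function(rows = 42, cols = 42, bands = NULL, n_classes = NULL,
                       snr_db = 30, mix_fraction = 0, seed = 1,
                       endmember_spec = NULL,
                       preset = c("none", "phi", "aviris")) {
  preset <- match.arg(preset)
  if (preset == "phi") {
    if (is.null(bands)) bands <- 65L
    if (is.null(n_classes)) n_classes <- 7L
  } else if (preset == "aviris") {
    if (is.null(bands)) bands <- 166L
    if (is.null(n_classes)) n_classes <- 6L
  }
  if (is.null(bands)) bands <- 65L
  if (is.null(n_classes)) n_classes <- 7L
  stopifnot(n_classes >= 2, bands >= 2, rows >= 1, cols >= 1,
            mix_fraction >= 0, mix_fraction < 1, is.finite(snr_db))
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         bands = as.integer(bands), n_classes = as.integer(n_classes),
         snr_db = snr_db, mix_fraction = mix_fraction,
         seed = as.integer(seed), endmember_spec = endmember_spec),
    class = "scene_spec"
  )
}

# default bump layout: two broad "backbone" bumps shared by every class
# (ground covers of one biome share most of their reflectance shape) plus
# two small class-specific bumps. This yields the high inter-class spectral
# correlation typical of vegetation scenes, where classifiers make errors
# rather than saturating.
default_endmember_spec <- function(spec) {
  with_seed(spec$seed + 1000L, {
    backbone <- cbind(
      center = stats::runif(2, 0.2 * spec$bands, 0.8 * spec$bands),
      width = stats::runif(2, spec$bands / 5, spec$bands / 3),
      amplitude = stats::runif(2, 0.8, 1)
    )
    K <- spec$n_classes
    slot <- spec$bands / K
    in_slot <- function(s) stats::runif(1, (s - 1) * slot + 0.25 * slot,
                                        s * slot - 0.25 * slot)
    lapply(seq_len(K), function(cls) {
      # own bumps stratified into class-specific slots of the band range
      # (second slot offset by ~K/2) so classes stay distinct by
      # construction for any seed
      # offset o with 2o != 0 (mod K), so no two classes share both slots
      o <- K %/% 2L
      if (K > 2L && (2L * o) %% K == 0L) o <- o + 1L
      s2 <- ((cls - 1L + o) %% K) + 1L
      own <- cbind(
        center = c(in_slot(cls), in_slot(s2)),
        width = stats::runif(2, spec$bands / 25, spec$bands / 10),
        amplitude = stats::runif(2, 0.2, 0.45)
      )
      rbind(backbone, own)
    })
  })
}

#' Generate per-class endmember spectra
#'
#' Each class spectrum is a sum of Gaussian bumps evaluated on the band grid
#' and rescaled to a maximum of 1. Classes must be spectrally distinct
#' (pairwise cosine similarity < 0.999).
#'
#' @param spec a [scene_spec()].
#' @return numeric matrix, one row per class, `bands` columns.
#' @export
make_endmembers <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  es <- spec$endmember_spec
  if (is.null(es)) es <- default_endmember_spec(spec)
  if (length(es) != spec$n_classes)
    stop("endmember_spec must have one entry per class")
  grid <- seq_len(spec$bands)
  E <- t(vapply(es, function(bumps) {
    bumps <- as.matrix(bumps)
    s <- rowSums(vapply(seq_len(nrow(bumps)), function(i) {
      bumps[i, 3] * exp(-((grid - bumps[i, 1])^2) / (2 * bumps[i, 2]^2))
    }, numeric(spec$bands)))
    s / max(s)
  }, numeric(spec$bands)))
  # distinctness check
  En <- E / sqrt(rowSums(E^2))
  cs <- tcrossprod(En)
  diag(cs) <- 0
  if (any(cs >= 0.999))
    stop("degenerate endmember spec: two classes are spectrally identical")
  E
}

# rectangular patch layout: classes tile a ceiling(sqrt(K)) grid; unused
# cells stay background (code 0)
patch_layout <- function(rows, cols, n_classes) {
  gc <- ceiling(sqrt(n_classes))
  gr <- ceiling(n_classes / gc)
  ph <- rows %/% gr
  pw <- cols %/% gc
  if (ph < 2L || pw < 2L)
    stop("patch layout impossible: scene too small for ", n_classes, " classes")
  labels <- matrix(0L, rows, cols)
  cls <- 0L
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    cls <- cls + 1L
    if (cls > n_classes) break
    r0 <- (i - 1L) * ph; c0 <- (j - 1L) * pw
    labels[(r0 + 1L):(r0 + ph), (c0 + 1L):(c0 + pw)] <- cls
  }
  labels
}

#' Render a synthetic scene
#'
#' Builds the labeled cube: block layout of per-class patches, pure pixels as
#' endmember plus zero-mean Gaussian noise calibrated to `snr_db`, and a
#' `mix_fraction` subset of labeled pixels drawn as convex combinations of
#' the patch's endmember and the next class's endmember (cyclic), with
#' weights from a symmetric Dirichlet; the larger weight goes to the patch's
#' own class so the recorded label stays the dominant material.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `"scene_truth"` with elements `cube`
#'   ([hsi_cube()]), `labels` ([label_map()]), `endmembers` (class x band
#'   matrix), `abundances` (pixel x class matrix, row-major pixel order),
#'   `mixed` (logical matrix of mixed pixels), `noise_sd`, `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  E <- make_endmembers(spec)
  labels <- patch_layout(spec$rows, spec$cols, spec$n_classes)
  npix <- spec$rows * spec$cols
  with_seed(spec$seed, {
    A <- matrix(0, npix, spec$n_classes)   # abundances, row-major pixel order
    signal <- matrix(0, npix, spec$bands)
    lab_rm <- as.vector(t(labels))         # row-major labels
    labeled <- which(lab_rm > 0L)
    mixed <- rep(FALSE, npix)
    if (spec$mix_fraction > 0) {
      n_mix <- floor(spec$mix_fraction * length(labeled))
      mixed[sample(labeled, n_mix)] <- TRUE
    }
    for (p in labeled) {
      k <- lab_rm[p]
      if (mixed[p]) {
        k2 <- if (k == spec$n_classes) 1L else k + 1L
        # symmetric Dirichlet(2,2) == Beta(2,2); dominant weight to own class
        w <- stats::rbeta(1, 2, 2)
        w <- max(w, 1 - w)
        A[p, k] <- w; A[p, k2] <- 1 - w
        signal[p, ] <- w * E[k, ] + (1 - w) * E[k2, ]
      } else {
        A[p, k] <- 1
        signal[p, ] <- E[k, ]
      }
    }
    p_sig <- mean(signal[labeled, ]^2)
    noise_sd <- sqrt(p_sig / 10^(spec$snr_db / 10))
    noise <- matrix(stats::rnorm(npix * spec$bands, sd = noise_sd),
                    npix, spec$bands)
    data_rm <- signal + noise
    # row-major pixel matrix back into (row, col, band) array
    ord <- as.vector(t(matrix(seq_len(npix), spec$rows, spec$cols)))
    flat <- matrix(0, npix, spec$bands)
    flat[ord, ] <- data_rm
    arr <- array(flat, c(spec$rows, spec$cols, spec$bands))
    structure(
      list(cube = hsi_cube(arr),
           labels = label_map(labels),
           endmembers = E,
           abundances = A,
           mixed = matrix(mixed, spec$rows, spec$cols, byrow = TRUE),
           noise_sd = noise_sd,
           spec = spec),
      class = "scene_truth"
    )
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d x %d, %d classes, SNR %.1f dB, mix %.2f\n",
              x$spec$rows, x$spec$cols, x$spec$bands, x$spec$n_classes,
              x$spec$snr_db, x$spec$mix_fraction))
  invisible(x)
}

#' Draw training spectra from a rendered scene
#'
#' Total training count is `round(ratio_to_bands * bands)`, split as evenly
#' as possible across classes with the remainder going to the lowest class
#' codes; sampling is without replacement and reproducible under `seed`.
#' An explicit `per_class` count overrides the ratio interface (e.g. exactly
#' 4 samples per class).
#'
#' @param truth a `"scene_truth"` from [render_scene()].
#' @param ratio_to_bands training-set size as a multiple of the band count
#'   (e.g. 0.5 means half as many samples as bands).
#' @param seed integer seed for the draw.
#' @param per_class optional integer: exactly this many samples per class,
#'   ignoring `ratio_to_bands`.
#' @return named list (by class code) of matrices, one training spectrum per
#'   row.
#' @export
sample_training <- function(truth, ratio_to_bands = 0.5, seed = 1,
                            per_class = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  K <- truth$spec$n_classes
  if (!is.null(per_class)) {
    quotas <- rep(as.integer(per_class), K)
  } else {
    total <- round(ratio_to_bands * truth$spec$bands)
    base <- total %/% K
    rem <- total %% K
    quotas <- rep(base, K) + c(rep(1L, rem), rep(0L, K - rem))
  }
  with_seed(seed, {
    out <- vector("list", K)
    for (k in seq_len(K)) {
      px <- extract_pixels(truth$cube, truth$labels, k)
      if (nrow(px) < quotas[k])
        stop(sprintf("class %d has %d labeled pixels but quota is %d",
                     k, nrow(px), quotas[k]))
      out[[k]] <- px[sample.int(nrow(px), quotas[k]), , drop = FALSE]
    }
    names(out) <- as.character(seq_len(K))
    out
  })
}

#' Contaminate training sets with other-class spectra
#'
#' Replaces a fraction of each class's training spectra with pixels drawn at
#' random from *other* classes' labeled pixels, emulating impure training
#' samples (mislabeled or mixed field picks). Exercises the robustness of
#' diverse-density dictionary learning to label noise.
#'
#' @param training per-class list of spectra (from [sample_training()]).
#' @param truth the `"scene_truth"` the training came from.
#' @param fraction fraction in `[0, 1)` of each class's samples to replace.
#' @param seed integer seed.
#' @return contaminated training list, same shape.
#' @export
contaminate_training <- function(training, truth, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(training)
  K <- length(training)
  with_seed(seed, {
    for (k in seq_len(K)) {
      n <- nrow(training[[k]])
      n_bad <- round(fraction * n)
      if (n_bad == 0) next
      others <- setdiff(seq_len(K), k)
      repl <- t(vapply(sample(others, n_bad, replace = TRUE), function(o) {
        px <- extract_pixels(truth$cube, truth$labels, o)
        px[sample.int(nrow(px), 1L), ]
      }, numeric(truth$spec$bands)))
      training[[k]][sample.int(n, n_bad), ] <- repl
    }
    training
  })
}
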