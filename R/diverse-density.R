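# Diverse-density (DD) multiple-instance learning of one representative
# spectrum per class.
#
# The DD objective scores a candidate point t by how probable it is under
# every positive bag (noisy-OR over instances) and how improbable under
# every negative instance:
#
#   DD(t) = prod_i [ 1 - prod_j (1 - Pr(t | B_ij+)) ] * prod_i prod_j (1 - Pr(t | B_ij-))
#
# with the instance kernel Pr(t | B_ij) = exp(-||B_ij - t||^2).
# All arithmetic runs in the log domain; an exact zero factor is carried as
# a -Inf sentinel.

#' Construct a training bag
#'
#' A bag is a labeled set of spectra. A positive bag contains at least one
#' instance of the target class; a negative bag contains none.
#'
#' @param instances numeric matrix, one instance (spectrum) per row.
#' @param polarity `"positive"` or `"negative"`.
#' @param target_class integer class code the bag is labeled for.
#' @return an object of class `"dd_bag"`.
#' @export
dd_bag <- function(instances, polarity = c("positive", "negative"),
                   target_class = NA_integer_) {
  polarity <- match.arg(polarity)
  if (is.vector(instances)) instances <- matrix(instances, nrow = 1L)
  instances <- as.matrix(instances)
  if (nrow(instances) < 1L) stop("a bag needs at least one instance")
  if (!all(is.finite(instances))) stop("bag instances must be finite")
  structure(list(instances = instances, polarity = polarity,
                 target_class = as.integer(target_class)),
            class = "dd_bag")
}

#' Instance-level membership probability
#'
#' The Gaussian-type kernel `exp(-||instance - t||^2)` (squared Euclidean
#' distance, no bandwidth parameter).
#'
#' @param instance,t numeric vectors of equal length.
#' @return probability in `(0, 1]`.
#' @examples
#' instance_prob(0, 1)   # exp(-1)
#' @export
instance_prob <- function(instance, t) {
  if (length(instance) != length(t))
    stop("instance and t must have the same length")
  exp(-sum((instance - t)^2))
}

# log(1 - exp(s)) for s <= 0, stable near both ends
log1mexp <- function(s) {
  ifelse(s > -log(2), log(-expm1(s)), log1p(-exp(s)))
}

# log of the noisy-OR / product factors from squared distances
.log_pos_bag <- function(d2) {
  # log[ 1 - prod_j (1 - exp(-d2_j)) ]
  if (any(d2 == 0)) return(0)                 # some instance equals t
  s <- sum(log1p(-exp(-d2)))                  # log prod (1 - p_j) <= 0
  if (s == 0) {                               # all p_j underflowed to 0:
    m <- max(-d2)                             # 1 - prod(1-p) ~ sum p; logsumexp
    return(m + log(sum(exp(-d2 - m))))
  }
  log1mexp(s)
}

.log_neg_bag <- function(d2) {
  if (any(d2 == 0)) return(-Inf)              # bag contains t exactly
  sum(log1p(-exp(-d2)))
}

.sq_dists <- function(instances, t) {
  colSums((t(instances) - t)^2)
}

#' Positive-bag probability (noisy-OR)
#'
#' `1 - prod_j (1 - Pr(t | B_ij))` over the bag's instances: 1 exactly when
#' some instance equals `t`.
#'
#' @param bag a positive [dd_bag()].
#' @param t candidate spectrum.
#' @return probability in `[0, 1]`.
#' @export
positive_bag_prob <- function(bag, t) {
  stopifnot(inherits(bag, "dd_bag"))
  if (bag$polarity != "positive") stop("bag is not positive")
  exp(.log_pos_bag(.sq_dists(bag$instances, t)))
}

#' Negative-bag probability
#'
#' `prod_j (1 - Pr(t | B_ij))`: 0 exactly when some instance equals `t`.
#'
#' @param bag a negative [dd_bag()].
#' @param t candidate spectrum.
#' @return probability in `[0, 1)`.
#' @export
negative_bag_prob <- function(bag, t) {
  stopifnot(inherits(bag, "dd_bag"))
  if (bag$polarity != "negative") stop("bag is not negative")
  exp(.log_neg_bag(.sq_dists(bag$instances, t)))
}

#' Diverse density at a point
#'
#' Product over positive-bag (noisy-OR) and negative-bag probabilities.
#' The log value is accumulated by summing per-bag logs, never by logging
#' the product, so `dd` may underflow to 0 while `log_dd` stays finite;
#' `log_dd = -Inf` only when some factor is exactly zero.
#'
#' @param bags list of [dd_bag()]s, at least one positive.
#' @param t candidate spectrum.
#' @return list with elements `dd` and `log_dd`.
#' @export
dd_value <- function(bags, t) {
  pol <- vapply(bags, function(b) b$polarity, character(1))
  if (!any(pol == "positive")) stop("at least one positive bag required")
  lp <- vapply(bags, function(b) {
    d2 <- .sq_dists(b$instances, t)
    if (b$polarity == "positive") .log_pos_bag(d2) else .log_neg_bag(d2)
  }, numeric(1))
  log_dd <- sum(lp)
  list(dd = exp(log_dd), log_dd = log_dd)
}

# analytic gradient of log DD(t); p clamped away from 1 so the
# positive-bag weight q/(1-q) and per-instance factor p/(1-p) stay finite
.dd_log_grad <- function(bags, t) {
  g <- numeric(length(t))
  for (b in bags) {
    B <- b$instances
    d2 <- .sq_dists(B, t)
    p <- pmin(exp(-d2), 1 - 1e-12)
    w <- 2 * p / (1 - p)                       # per-instance weight
    diffs <- sweep(B, 2L, t)                   # rows B_j - t
    if (b$polarity == "negative") {
      g <- g - colSums(diffs * w)              # sum 2p/(1-p) (t - B_j)
    } else {
      lq <- sum(log1p(-p))                     # log prod (1 - p_j)
      if (lq == 0) {                           # all p underflowed:
        sm <- exp(-d2 - max(-d2))              # grad of logsumexp(-d2)
        g <- g + colSums(diffs * (2 * sm / sum(sm)))
      } else {
        q_over <- exp(lq - log1mexp(lq))       # q / (1 - q)
        g <- g + q_over * colSums(diffs * w)
      }
    }
  }
  g
}

#' Maximize diverse density
#'
#' Candidate-set maximization: evaluates log-DD at every instance of every
#' positive bag and returns the argmax (ties broken by first occurrence in
#' bag order, then instance order). With `refine = TRUE` a quasi-Newton
#' ascent (BFGS on the negative log-DD) is started from the best candidate
#' and the better of the two points is returned, since the DD optimum lives
#' in the continuous spectral space, not necessarily on an instance.
#'
#' @param bags list of [dd_bag()]s, at least one positive.
#' @param refine logical; run local ascent from the best candidate.
#' @return an object of class `"dd_concept"`: list with `point` (the
#'   maximizing spectrum), `dd_value`, `log_dd`, `refined` (logical).
#' @export
maximize_dd <- function(bags, refine = FALSE) {
  pol <- vapply(bags, function(b) b$polarity, character(1))
  if (!any(pol == "positive")) stop("at least one positive bag required")
  cands <- do.call(rbind, lapply(bags[pol == "positive"],
                                 function(b) b$instances))
  logs <- apply(cands, 1L, function(t) dd_value(bags, t)$log_dd)
  best <- which.max(logs)   # first max wins ties
  point <- cands[best, ]
  best_log <- logs[best]
  refined <- FALSE
  if (refine && is.finite(best_log)) {
    negloss <- function(t) {
      v <- dd_value(bags, t)$log_dd
      if (!is.finite(v)) return(1e12)
      -v
    }
    neggrad <- function(t) -.dd_log_grad(bags, t)
    opt <- tryCatch(
      stats::optim(point, negloss, neggrad, method = "BFGS",
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value > best_log) {
      point <- opt$par
      best_log <- -opt$value
      refined <- TRUE
    }
  }
  structure(list(point = as.numeric(point),
                 dd_value = exp(best_log),
                 log_dd = best_log,
                 refined = refined),
            class = "dd_concept")
}

#' @export
print.dd_concept <- function(x, ...) {
  cat(sprintf("<dd_concept> %d bands, log-DD = %.4g%s\n",
              length(x$point), x$log_dd,
              if (x$refined) " (refined)" else ""))
  invisible(x)
}

# partition rows of a matrix into bags of bag_size (last may be short)
.make_bags <- function(mat, bag_size, polarity, target_class) {
  n <- nrow(mat)
  starts <- seq(1L, n, by = bag_size)
  lapply(starts, function(s) {
    dd_bag(mat[s:min(s + bag_size - 1L, n), , drop = FALSE],
           polarity, target_class)
  })
}

#' Learn a spectral dictionary by diverse density
#'
#' For each class, positive bags are formed by partitioning that class's
#' training spectra into bags of `bag_size` (singleton bags by default),
#' negative bags likewise from all other classes' spectra; the DD maximum
#' over the positive-bag candidates becomes the class's dictionary atom,
#' L2-normalized. Atoms are ordered by ascending class code.
#'
#' DD runs on raw reflectance spectra by default. The `exp(-d^2)` kernel has
#' no bandwidth parameter, so the spectra's scale *is* the bandwidth:
#' on raw reflectance, within-class distances sit near the kernel's
#' sensitive range while cross-class distances drive probabilities toward
#' 0, which is what makes the objective discriminate. L2-pre-normalizing
#' every spectrum (`normalize = TRUE`) compresses all pairwise distances
#' far below 1, saturating every kernel value near 1 and flattening the
#' objective; it is provided as a switch for data whose raw scale is
#' arbitrary (e.g. uncalibrated radiance counts).
#'
#' @param training named list (by class code) of matrices, one training
#'   spectrum per row; at least 2 classes, at least 1 spectrum each.
#' @param bag_size instances per bag (default 1).
#' @param refine run continuous refinement of each class's DD maximum.
#' @param normalize L2-normalize spectra before DD (default `FALSE`: raw
#'   reflectance scale; see Details).
#' @param atoms_per_class number of atoms learned per class (default 1).
#'   Additional atoms are the next-best DD candidates, with previously
#'   chosen candidates excluded; atoms stay grouped by class.
#' @param class_names optional character names for the class codes.
#' @return an object of class `"ddsr_dictionary"`: list with `atoms`
#'   (bands x m matrix, unit-norm columns), `class_code` (per atom),
#'   `class_names`, `bands`, `concepts` (per-class `"dd_concept"`s), and the
#'   settings used.
#' @export
learn_dictionary <- function(training, bag_size = 1L, refine = FALSE,
                             normalize = FALSE, atoms_per_class = 1L,
                             class_names = NULL) {
  if (length(training) < 2L) stop("need at least 2 classes")
  atoms_per_class <- as.integer(atoms_per_class)
  stopifnot(atoms_per_class >= 1L)
  codes <- as.integer(names(training))
  if (any(is.na(codes))) codes <- seq_along(training)
  ord <- order(codes)
  training <- training[ord]; codes <- codes[ord]
  mats <- lapply(training, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 1L) stop("every class needs at least one training spectrum")
    m
  })
  bands <- ncol(mats[[1]])
  if (normalize)
    mats <- lapply(mats, function(m) m / sqrt(rowSums(m^2)))
  concepts <- vector("list", length(mats))
  atom_cols <- list()
  atom_codes <- integer(0)
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) < atoms_per_class)
      stop(sprintf("class %d has %d samples but %d atoms were requested",
                   codes[i], nrow(mats[[i]]), atoms_per_class))
    pos <- .make_bags(mats[[i]], bag_size, "positive", codes[i])
    neg <- unlist(lapply(seq_along(mats)[-i], function(j)
      .make_bags(mats[[j]], bag_size, "negative", codes[i])),
      recursive = FALSE)
    bags <- c(pos, neg)
    concepts[[i]] <- maximize_dd(bags, refine = refine)
    pts <- list(concepts[[i]]$point)
    if (atoms_per_class > 1L) {
      # next-best candidates with previously chosen ones excluded
      cands <- mats[[i]]
      logs <- apply(cands, 1L, function(t) dd_value(bags, t)$log_dd)
      taken <- which.max(logs)
      for (k in seq_len(atoms_per_class - 1L)) {
        logs[taken] <- -Inf
        taken <- c(taken, which.max(logs))
        pts[[k + 1L]] <- cands[taken[k + 1L], ]
      }
    }
    for (p in pts) {
      atom_cols[[length(atom_cols) + 1L]] <- p / sqrt(sum(p^2))
      atom_codes <- c(atom_codes, codes[i])
    }
  }
  atoms <- do.call(cbind, atom_cols)
  if (is.null(class_names))
    class_names <- stats::setNames(paste0("class_", codes), codes)
  structure(
    list(atoms = atoms, class_code = atom_codes, class_names = class_names,
         bands = bands, concepts = concepts,
         bag_size = as.integer(bag_size), refine = refine,
         normalize = normalize),
    class = "ddsr_dictionary"
  )
}

#' @export
print.ddsr_dictionary <- function(x, ...) {
  cat(sprintf("<ddsr_dictionary> %d atoms (%d classes), %d bands\n",
              ncol(x$atoms), length(unique(x$class_code)), x$bands))
  invisible(x)
}

#' Write a dictionary to a text file
#'
#' One atom per line: class code, class name, band values; preceded by a
#' `#`-commented metadata block (normalization flag, bag size, band count).
#'
#' @param dict a `"ddsr_dictionary"`.
#' @param path output path.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "ddsr_dictionary"))
  meta <- c(
    "# ddsr dictionary",
    sprintf("# bands: %d", dict$bands),
    sprintf("# bag_size: %d", dict$bag_size),
    sprintf("# normalize: %s", dict$normalize),
    sprintf("# refine: %s", dict$refine)
  )
  rows <- vapply(seq_len(ncol(dict$atoms)), function(i) {
    paste(c(dict$class_code[i],
            dict$class_names[as.character(dict$class_code[i])],
            format(dict$atoms[, i], digits = 17, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(meta, rows), path)
  invisible(path)
}

#' Read a dictionary written by [write_dictionary()]
#' @param path input path.
#' @return a `"ddsr_dictionary"` (without the per-class concept traces).
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  rows <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(ln)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  codes <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  nms <- vapply(parts, function(p) p[2], character(1))
  atoms <- vapply(parts, function(p) as.numeric(p[-(1:2)]),
                  numeric(length(parts[[1]]) - 2L))
  structure(
    list(atoms = atoms, class_code = codes,
         class_names = stats::setNames(nms, codes)[!duplicated(codes)],
         bands = nrow(atoms), concepts = NULL,
         bag_size = as.integer(get_meta("bag_size")),
         refine = as.logical(get_meta("refine")),
         normalize = as.logical(get_meta("normalize"))),
    class = "ddsr_dictionary"
  )
}
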