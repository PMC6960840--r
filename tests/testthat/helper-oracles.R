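# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's log-domain / incremental code paths:
# the diverse-density oracle multiplies plain probabilities, the pursuit
# oracle recomputes every inner product from scratch each step.

# linear-domain diverse density by direct products of Eq-style factors
brute_dd <- function(bags, t) {
  val <- 1
  for (b in bags) {
    p <- apply(b$instances, 1L, function(row) exp(-sum((row - t)^2)))
    val <- val * if (b$polarity == "positive") 1 - prod(1 - p) else prod(1 - p)
  }
  val
}

# brute-force candidate maximization: first argmax over positive instances
brute_maximize_dd <- function(bags) {
  cands <- do.call(rbind, lapply(
    Filter(function(b) b$polarity == "positive", bags),
    function(b) b$instances))
  vals <- apply(cands, 1L, function(t) brute_dd(bags, t))
  cands[which.max(vals), ]
}

# random bag sets: dims <= 10, bags <= 10, coordinates in [-1, 1]
random_bags <- function(seed) {
  set.seed(seed)
  d <- sample(2:10, 1)
  n_pos <- sample(1:5, 1)
  n_neg <- sample(0:5, 1)
  mk <- function(pol) dd_bag(matrix(stats::runif(sample(1:4, 1) * d, -1, 1),
                                    ncol = d), pol, 1L)
  c(lapply(seq_len(n_pos), function(i) mk("positive")),
    if (n_neg > 0) lapply(seq_len(n_neg), function(i) mk("negative")))
}

# independent greedy pursuit: recomputes all inner products each step,
# same stopping rules, returns the selected atom sequence
brute_mp_sequence <- function(x, atoms, xi = 1e-3, max_iter = 4L * ncol(atoms)) {
  r <- x
  seq_sel <- integer(0)
  total <- 0
  for (it in seq_len(max_iter)) {
    ips <- vapply(seq_len(ncol(atoms)),
                  function(i) sum(r * atoms[, i]), numeric(1))
    i <- which.max(ips)
    if (ips[i] <= 0) break
    seq_sel <- c(seq_sel, i)
    r <- r - ips[i] * atoms[, i]
    total <- total + ips[i]
    if (sqrt(sum(r^2)) <= xi) break
    if (total >= 1) break
  }
  seq_sel
}

# small dictionary from explicit atom columns (normalized), one class each
make_dict <- function(atoms, class_code = seq_len(ncol(atoms))) {
  atoms <- apply(atoms, 2L, function(a) a / sqrt(sum(a^2)))
  structure(
    list(atoms = atoms, class_code = as.integer(class_code),
         class_names = stats::setNames(paste0("class_", unique(class_code)),
                                       unique(class_code)),
         bands = nrow(atoms), concepts = NULL,
         bag_size = 1L, refine = FALSE, normalize = FALSE),
    class = "ddsr_dictionary"
  )
}

# random unit-norm dictionary with positive-leaning atoms
random_dict <- function(seed, bands, m) {
  set.seed(seed)
  make_dict(matrix(stats::runif(bands * m), bands, m))
}
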