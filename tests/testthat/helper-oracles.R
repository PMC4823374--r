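# Shared test fixtures and independent oracles.

# 6-neighborhood edge list of a small grid, as one 2-column matrix
grid_edges_all <- function(d) {
  e <- vemseg:::grid_edges(d)
  rbind(e$exy, e$ez)
}

# Exhaustive minimum of a binary pairwise energy by enumerating all 2^n
# labelings (vectorized over labelings).
enumerate_binary_min <- function(u0, u1, edges, w) {
  n <- length(u0)
  X <- as.matrix(expand.grid(rep(list(0:1), n)))
  e <- as.vector(X %*% u1 + (1 - X) %*% u0)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      e <- e + w[k] * (X[, edges[k, 1]] != X[, edges[k, 2]])
    }
  }
  min(e)
}

binary_cut_energy <- function(x1, u0, u1, edges, w) {
  e <- sum(ifelse(x1, u1, u0))
  if (nrow(edges)) e <- e + sum(w * (x1[edges[, 1]] != x1[edges[, 2]]))
  e
}

# random small binary CRF instance on a grid of shape <= max_d
random_binary_instance <- function(max_d = c(3, 3, 2), umax = 5, wmax = 2) {
  d <- c(sample(seq_len(max_d[1]), 1), sample(seq_len(max_d[2]), 1),
         sample(seq_len(max_d[3]), 1))
  n <- prod(d)
  edges <- grid_edges_all(d)
  list(d = d, n = n, edges = edges,
       u0 = runif(n, 0, umax), u1 = runif(n, 0, umax),
       w = if (nrow(edges)) runif(nrow(edges), 0, wmax) else numeric(0))
}

# probability map with given per-voxel label weights (columns), normalized
probmap_from_matrix <- function(p, d, labels = seq_len(ncol(p))) {
  p <- p / rowSums(p)
  vemseg:::probability_map(p, d, labels,
                           stats::setNames(as.integer(labels),
                                           as.character(labels)))
}

# seeded random probability map over a grid
random_probmap <- function(d, n_labels = 2, peak = 6) {
  n <- prod(d)
  p <- matrix(runif(n * n_labels, 0.05, 1), n, n_labels)
  probmap_from_matrix(p, d)
}

# small phantom spec that generates quickly in unit tests
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(48L, 48L, 16L), n_mitochondria = 2L,
               n_synapses = 1L, mito_radius_range = c(4, 6),
               sheet_extent_range = c(4, 6), n_membranes = 2L, ...)
}

# dense 2D convolution of image with a separable kernel, valid-interior
# comparison oracle: returns the convolution at pixels where the kernel
# support lies fully inside the image, plus the index range
dense_conv2d_interior <- function(img, kx, ky) {
  rx <- (length(kx) - 1) / 2
  ry <- (length(ky) - 1) / 2
  nx <- nrow(img); ny <- ncol(img)
  xs <- (rx + 1):(nx - rx)
  ys <- (ry + 1):(ny - ry)
  out <- matrix(NA_real_, length(xs), length(ys))
  K <- outer(kx, ky)
  for (a in seq_along(xs)) {
    for (b in seq_along(ys)) {
      x <- xs[a]; y <- ys[b]
      patch <- img[(x + rx):(x - rx), (y + ry):(y - ry)]  # flipped = conv
      out[a, b] <- sum(patch * K)
    }
  }
  list(values = out, xs = xs, ys = ys)
}
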