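# CRF regularization of the voxel-wise posteriors.
#
# Energy over labelings Y:  sum_i -log P(y_i | f_i(x))
#                          + theta_XY * sum_{(i,j) in E_XY} D[y_i, y_j]
#                          + theta_Z  * sum_{(i,j) in E_Z}  D[y_i, y_j]
# with the 6-neighborhood split into in-plane edges E_XY and across-section
# edges E_Z, and D a symmetric zero-diagonal label distance matrix with
# entries in {0, 1, Inf}.  Two labels: exact global minimum by one
# max-flow/min-cut.  Three or more: alpha-beta swap, each move solved as an
# exact binary cut.

#' Default label distance matrix
#'
#' Background may touch anything (distance 1 across the boundary), while
#' synaptic junctions and mitochondria are forbidden from being adjacent
#' (distance `Inf`).  The diagonal is zero: no penalty within a label.
#'
#' @param forbid list of length-2 vectors of label ids that may not touch.
#' @param label_ids integer ids, in the order used by the probability map.
#' @return symmetric L x L matrix with zero diagonal.
#' @export
default_distance_matrix <- function(label_ids = c(1L, 2L, 3L),
                                    forbid = list(c(2L, 3L))) {
  L <- length(label_ids)
  D <- matrix(1, L, L) - diag(L)
  dimnames(D) <- list(label_ids, label_ids)
  for (p in forbid) {
    i <- match(p[1], label_ids)
    j <- match(p[2], label_ids)
    if (!is.na(i) && !is.na(j)) D[i, j] <- D[j, i] <- Inf
  }
  D
}

#' CRF configuration
#'
#' @param theta_xy in-plane pairwise weight (>= 0).
#' @param theta_z across-section pairwise weight; defaults to
#'   `theta_xy / rho`, the anisotropy-corrected rule.
#' @param rho anisotropy factor used for the `theta_z` default.
#' @param distance_matrix symmetric L x L label distance matrix with zero
#'   diagonal (entries typically 0, 1 or `Inf`).
#' @param tile_shape tile size in voxels for [regularize_tiled()].
#' @param margin overlap margin in voxels around each tile.
#' @param inf_value finite surrogate for `Inf` pairwise entries; when `NULL`
#'   it is derived per instance as `1e6 * (max finite unary + theta_xy +
#'   theta_z)`.
#' @param posterior_floor posteriors are floored here before `-log`.
#' @return an object of class `CRFConfig`.
#' @export
crf_config <- function(theta_xy, theta_z = NULL, rho = NULL,
                       distance_matrix = NULL,
                       tile_shape = c(256L, 256L, 64L), margin = 10L,
                       inf_value = NULL, posterior_floor = 1e-12) {
  stopifnot(theta_xy >= 0)
  if (is.null(theta_z)) {
    if (is.null(rho)) stop("either theta_z or rho must be given",
                           call. = FALSE)
    theta_z <- theta_xy / rho
  }
  stopifnot(theta_z >= 0, margin >= 0)
  if (!is.null(distance_matrix)) {
    D <- distance_matrix
    if (!is.matrix(D) || nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D))) ||
        any(diag(D) != 0)) {
      stop("distance_matrix must be square, symmetric, with zero diagonal",
           call. = FALSE)
    }
  }
  structure(list(theta_xy = theta_xy, theta_z = theta_z,
                 distance_matrix = distance_matrix,
                 tile_shape = as.integer(tile_shape),
                 margin = as.integer(margin), inf_value = inf_value,
                 posterior_floor = posterior_floor),
            class = "CRFConfig")
}

# 6-neighborhood edges of an (nx, ny, nz) grid as 2-column matrices of
# 1-based linear voxel indices, split into in-plane (E_XY) and
# across-section (E_Z) sets.
grid_edges <- function(d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  idx <- array(seq_len(prod(d)), dim = d)
  ex <- if (nx > 1) cbind(as.vector(idx[-nx, , , drop = FALSE]),
                          as.vector(idx[-1, , , drop = FALSE]))
        else matrix(integer(0), 0, 2)
  ey <- if (ny > 1) cbind(as.vector(idx[, -ny, , drop = FALSE]),
                          as.vector(idx[, -1, , drop = FALSE]))
        else matrix(integer(0), 0, 2)
  ez <- if (nz > 1) cbind(as.vector(idx[, , -nz, drop = FALSE]),
                          as.vector(idx[, , -1, drop = FALSE]))
        else matrix(integer(0), 0, 2)
  list(exy = rbind(ex, ey), ez = ez)
}

#' Build a CRF energy instance from a probability map
#'
#' Unary costs are `-log` posteriors (floored at `posterior_floor`); the
#' 6-neighborhood is split into in-plane and across-section edge sets.
#'
#' @param probmap a `ProbabilityMap`.
#' @param config a [crf_config()]; when its `distance_matrix` is `NULL` the
#'   [default_distance_matrix()] over the map's labels is used.
#' @return an object of class `EnergyInstance` with elements `unary`
#'   (voxels x labels), `labels`, `dim`, `exy`, `ez`, `D`.
#' @export
build_energy <- function(probmap, config) {
  stopifnot(inherits(probmap, "ProbabilityMap"), inherits(config, "CRFConfig"))
  d <- dim(probmap)[1:3]
  labels <- attr(probmap, "labels")
  L <- length(labels)
  p <- matrix(as.double(probmap), nrow = prod(d), ncol = L)
  unary <- -log(pmax(p, config$posterior_floor))
  D <- config$distance_matrix
  if (is.null(D)) D <- default_distance_matrix(labels,
                                               forbid = if (L >= 3)
                                                 list(c(2L, 3L)) else list())
  if (nrow(D) != L) {
    stop(sprintf("distance matrix is %dx%d but there are %d labels",
                 nrow(D), ncol(D), L), call. = FALSE)
  }
  e <- grid_edges(d)
  structure(list(unary = unary, labels = labels, dim = d,
                 exy = e$exy, ez = e$ez, D = D,
                 label_table = attr(probmap, "label_table")),
            class = "EnergyInstance")
}

inf_surrogate <- function(energy, config) {
  if (!is.null(config$inf_value)) return(config$inf_value)
  1e6 * (max(energy$unary) + config$theta_xy + config$theta_z)
}

#' Energy of a labeling
#'
#' Evaluates the CRF objective for a given hard labeling; `Inf` pairwise
#' entries contribute the finite surrogate `inf_value`.
#'
#' @param labeling a [label_volume()] (or integer array) over the same grid.
#' @param energy an `EnergyInstance` from [build_energy()].
#' @param config the [crf_config()].
#' @return scalar energy value.
#' @export
labeling_energy <- function(labeling, energy, config) {
  lab <- if (inherits(labeling, "LabelVolume")) labeling$labels else labeling
  stopifnot(identical(dim(lab), as.integer(energy$dim)) ||
              all(dim(lab) == energy$dim))
  y <- match(as.vector(lab), energy$labels)
  if (anyNA(y)) stop("labeling contains ids not present in the energy",
                     call. = FALSE)
  infv <- inf_surrogate(energy, config)
  Df <- energy$D
  Df[!is.finite(Df)] <- infv
  e <- sum(energy$unary[cbind(seq_along(y), y)])
  if (nrow(energy$exy)) {
    e <- e + config$theta_xy * sum(Df[cbind(y[energy$exy[, 1]],
                                            y[energy$exy[, 2]])])
  }
  if (nrow(energy$ez)) {
    e <- e + config$theta_z * sum(Df[cbind(y[energy$ez[, 1]],
                                           y[energy$ez[, 2]])])
  }
  e
}

# exact s-t min-cut for a binary submodular instance:
# cost(x) = sum_i (x_i ? u1_i : u0_i) + sum_e w_e [x_i != x_j]
# returns logical vector: TRUE -> label 1 (sink side)
st_mincut <- function(u0, u1, edges, w) {
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2)
  .bk_mincut(length(u0), edges, as.double(w), as.double(u0), as.double(u1))
}

check_submodular <- function(D) {
  L <- nrow(D)
  for (a in seq_len(L)) for (b in seq_len(L)) {
    if (D[a, a] + D[b, b] > D[a, b] + D[b, a]) {
      stop("distance matrix is not submodular: D[a,a] + D[b,b] > D[a,b] + D[b,a]",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Exact binary CRF minimization by max-flow/min-cut
#'
#' For two labels with submodular pairwise terms a single
#' max-flow/min-cut computation yields the global minimum of the energy.
#'
#' @param energy an `EnergyInstance` with exactly 2 labels.
#' @param config the [crf_config()].
#' @return a [label_volume()] attaining the global minimum; the attained
#'   energy is attached as attribute `energy`.
#' @export
minimize_binary <- function(energy, config) {
  stopifnot(inherits(energy, "EnergyInstance"))
  if (length(energy$labels) != 2L) {
    stop("minimize_binary requires exactly 2 labels", call. = FALSE)
  }
  check_submodular(energy$D)
  infv <- inf_surrogate(energy, config)
  d12 <- energy$D[1, 2]
  if (!is.finite(d12)) d12 <- infv
  w <- c(rep(config$theta_xy * d12, nrow(energy$exy)),
         rep(config$theta_z * d12, nrow(energy$ez)))
  edges <- rbind(energy$exy, energy$ez)
  x1 <- st_mincut(energy$unary[, 1], energy$unary[, 2], edges, w)
  lab <- array(energy$labels[1L + x1], dim = energy$dim)
  out <- label_volume(lab, label_table_for(energy))
  e <- labeling_energy(out, energy, config)
  if (e >= infv) {
    stop("infeasible energy: minimizer could not avoid a forbidden adjacency",
         call. = FALSE)
  }
  attr(out, "energy") <- e
  out
}

label_table_for <- function(energy) {
  lt <- energy$label_table
  if (is.null(lt)) lt <- setNames(energy$labels, as.character(energy$labels))
  lt
}

#' Approximate multilabel CRF minimization by alpha-beta swap
#'
#' Starts from the maximum-posterior labeling and repeatedly solves, for each
#' label pair (alpha, beta) in ascending lexicographic order, the exact
#' binary subproblem that optimally re-assigns all voxels currently labeled
#' alpha or beta (all other voxels held fixed, their pairwise interactions
#' folded into the unary terms).  A move is accepted only if it strictly
#' decreases the energy; sweeps continue until a full pass yields no
#' decrease.
#'
#' @inheritParams minimize_binary
#' @param init optional initial labeling (a [label_volume()] or integer
#'   array); defaults to the maximum-posterior labeling.
#' @return a [label_volume()]; attributes `energy` (final value) and
#'   `energy_trace` (energy after each accepted move, starting with the
#'   initialization) are attached.
#' @export
minimize_multilabel <- function(energy, config, init = NULL) {
  stopifnot(inherits(energy, "EnergyInstance"))
  L <- length(energy$labels)
  infv <- inf_surrogate(energy, config)
  Df <- energy$D
  Df[!is.finite(Df)] <- infv

  y <- if (is.null(init)) {
    max.col(-energy$unary, ties.method = "first")      # argmax init
  } else {
    lab0 <- if (inherits(init, "LabelVolume")) init$labels else init
    match(as.vector(lab0), energy$labels)
  }
  cur <- labeling_energy(array(energy$labels[y], dim = energy$dim),
                         energy, config)
  trace <- cur

  edges <- rbind(energy$exy, energy$ez)
  etheta <- c(rep(config$theta_xy, nrow(energy$exy)),
              rep(config$theta_z, nrow(energy$ez)))
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  repeat {
    improved <- FALSE
    for (p in seq_len(nrow(pairs))) {
      a <- pairs[p, 1]; b <- pairs[p, 2]
      S <- which(y == a | y == b)
      if (length(S) == 0L) next
      pos <- integer(length(y))
      pos[S] <- seq_along(S)
      u0 <- energy$unary[S, a]
      u1 <- energy$unary[S, b]
      pi <- pos[edges[, 1]]
      pj <- pos[edges[, 2]]
      both <- pi > 0L & pj > 0L
      ionly <- pi > 0L & pj == 0L
      jonly <- pi == 0L & pj > 0L
      # fixed-neighbor interactions fold into the unaries
      if (any(ionly)) {
        fix <- y[edges[ionly, 2]]
        th <- etheta[ionly]
        u0 <- u0 + tab_accum(pi[ionly], th * Df[cbind(a, fix)], length(S))
        u1 <- u1 + tab_accum(pi[ionly], th * Df[cbind(b, fix)], length(S))
      }
      if (any(jonly)) {
        fix <- y[edges[jonly, 1]]
        th <- etheta[jonly]
        u0 <- u0 + tab_accum(pj[jonly], th * Df[cbind(a, fix)], length(S))
        u1 <- u1 + tab_accum(pj[jonly], th * Df[cbind(b, fix)], length(S))
      }
      sub_edges <- cbind(pi[both], pj[both])
      sub_w <- etheta[both] * Df[a, b]
      x1 <- st_mincut(u0, u1, sub_edges, sub_w)
      ynew <- y
      ynew[S] <- ifelse(x1, b, a)
      enew <- labeling_energy(array(energy$labels[ynew], dim = energy$dim),
                              energy, config)
      if (enew < cur) {
        y <- ynew
        cur <- enew
        trace <- c(trace, cur)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  out <- label_volume(array(energy$labels[y], dim = energy$dim),
                      label_table_for(energy))
  if (cur >= infv) {
    stop("infeasible energy: minimizer could not avoid a forbidden adjacency",
         call. = FALSE)
  }
  attr(out, "energy") <- cur
  attr(out, "energy_trace") <- trace
  out
}

tab_accum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, group = index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Regularize a probability map (untiled)
#'
#' Dispatches to the exact binary cut for 2 labels and to alpha-beta swap for
#' 3 or more.
#'
#' @param probmap a `ProbabilityMap`.
#' @param config a [crf_config()].
#' @return a [label_volume()].
#' @export
regularize <- function(probmap, config) {
  energy <- build_energy(probmap, config)
  if (length(energy$labels) == 2L) {
    minimize_binary(energy, config)
  } else {
    minimize_multilabel(energy, config)
  }
}

#' Regularize a probability map in overlapping tiles
#'
#' The volume is partitioned into disjoint tiles of `config$tile_shape`; each
#' tile is extended by `config$margin` voxels in every direction (clipped at
#' the volume border), the CRF is minimized on the extended tile, and only
#' the core tile's voxels are written to the output.  The margin gives the
#' CRF enough context at tile boundaries to avoid seam artifacts while
#' bounding peak memory.
#'
#' @inheritParams regularize
#' @return a [label_volume()].
#' @export
regularize_tiled <- function(probmap, config) {
  stopifnot(inherits(probmap, "ProbabilityMap"), inherits(config, "CRFConfig"))
  d <- dim(probmap)[1:3]
  ts <- pmin(config$tile_shape, d)
  m <- config$margin
  starts <- lapply(1:3, function(ax) seq.int(1L, d[ax], by = ts[ax]))
  out <- array(NA_integer_, dim = d)
  lt <- attr(probmap, "label_table")
  for (z0 in starts[[3]]) for (y0 in starts[[2]]) for (x0 in starts[[1]]) {
    core <- list(x = x0:min(x0 + ts[1] - 1L, d[1]),
                 y = y0:min(y0 + ts[2] - 1L, d[2]),
                 z = z0:min(z0 + ts[3] - 1L, d[3]))
    ext <- list(x = max(1L, min(core$x) - m):min(d[1], max(core$x) + m),
                y = max(1L, min(core$y) - m):min(d[2], max(core$y) + m),
                z = max(1L, min(core$z) - m):min(d[3], max(core$z) + m))
    sub <- probability_map(
      probmap[ext$x, ext$y, ext$z, , drop = FALSE],
      c(length(ext$x), length(ext$y), length(ext$z)),
      attr(probmap, "labels"), lt)
    res <- regularize(sub, config)
    out[core$x, core$y, core$z] <-
      res$labels[core$x - min(ext$x) + 1L,
                 core$y - min(ext$y) + 1L,
                 core$z - min(ext$z) + 1L]
  }
  label_volume(out, if (is.null(lt))
    setNames(attr(probmap, "labels"), as.character(attr(probmap, "labels")))
    else lt)
}
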