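# Deterministic synthetic EM-like phantom generator.
#
# Emulates the appearance of FIB/SEM stacks at the level the pipeline cares
# about: a bright background crossed by faint dark membrane curves,
# mitochondria as dark ellipsoidal blobs with internal darker stripes
# (cristae-like texture), synaptic junctions as thin curved dark sheets with
# a darker rim, and additive Gaussian noise.  Geometry is generated in nm
# space and sampled at the voxel size, so anisotropy is reproduced exactly
# as in real serial-section data.  All randomness flows through one seeded
# generator; the same spec and seed give bit-identical output.

#' Phantom specification
#'
#' Default values describe a 128 x 128 x 32 stack at 10 x 10 x 20 nm voxels
#' (anisotropy factor 2) with 5 mitochondria and 4 synaptic sheets.  The
#' class-conditional intensity means (background 0.70, membranes 0.45,
#' mitochondria 0.35 with 0.25 stripes, synapses ~0.25) overlap through the
#' noise (sigma 0.06), so the Gaussian classifier is adequate but not
#' trivially perfect.
#'
#' @param shape volume shape `(X, Y, Z)` in voxels.
#' @param voxel_size `(sx, sy, sz)` in nm.
#' @param n_mitochondria,n_synapses object counts.
#' @param mito_radius_range ellipsoid semi-axis range, in-plane pixels.
#' @param sheet_thickness synaptic sheet thickness, in-plane pixels.
#' @param sheet_extent_range synaptic sheet lateral radius range, pixels.
#' @param n_membranes faint background membrane curves.
#' @param intensity named list of per-class means and stripe/rim contrasts.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param clearance minimum spacing (voxels) between objects and to the
#'   volume border.
#' @param seed RNG seed recorded in the output.
#' @return an object of class `PhantomSpec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 32L),
                         voxel_size = c(10, 10, 20),
                         n_mitochondria = 5L, n_synapses = 4L,
                         mito_radius_range = c(8, 14),
                         sheet_thickness = 2,
                         sheet_extent_range = c(12, 20),
                         n_membranes = 6L,
                         intensity = list(bg = 0.70, membrane = 0.45,
                                          mito = 0.35, mito_stripe = 0.25,
                                          syn = 0.28, syn_rim = 0.22),
                         noise_sigma = 0.06,
                         clearance = 2L,
                         seed = 1L) {
  check_voxel_size(voxel_size)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            n_mitochondria >= 0L, n_synapses >= 0L, noise_sigma >= 0)
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 n_mitochondria = as.integer(n_mitochondria),
                 n_synapses = as.integer(n_synapses),
                 mito_radius_range = mito_radius_range,
                 sheet_thickness = sheet_thickness,
                 sheet_extent_range = sheet_extent_range,
                 n_membranes = as.integer(n_membranes),
                 intensity = intensity, noise_sigma = noise_sigma,
                 clearance = as.integer(clearance), seed = as.integer(seed)),
            class = "PhantomSpec")
}

# binary dilation under 6-connectivity, `iter` voxel layers
dilate6 <- function(mask, iter = 1L) {
  d <- dim(mask)
  for (k in seq_len(iter)) {
    out <- mask
    if (d[1] > 1) {
      out[-1, , ] <- out[-1, , , drop = FALSE] | mask[-d[1], , , drop = FALSE]
      out[-d[1], , ] <- out[-d[1], , , drop = FALSE] | mask[-1, , , drop = FALSE]
    }
    if (d[2] > 1) {
      out[, -1, ] <- out[, -1, , drop = FALSE] | mask[, -d[2], , drop = FALSE]
      out[, -d[2], ] <- out[, -d[2], , drop = FALSE] | mask[, -1, , drop = FALSE]
    }
    if (d[3] > 1) {
      out[, , -1] <- out[, , -1, drop = FALSE] | mask[, , -d[3], drop = FALSE]
      out[, , -d[3]] <- out[, , -d[3], drop = FALSE] | mask[, , -1, drop = FALSE]
    }
    mask <- out
  }
  mask
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# orthonormal frame (n, t1, t2) with n given
frame_from_normal <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- ref - sum(ref * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  cbind(t1, t2)
}

#' Generate a synthetic EM phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `stack` (an [image_stack()]), `labels` (a
#'   [label_volume()]: bg = 1, syn = 2, mit = 3) and `spec` (with the seed,
#'   as generation metadata).  Objects never overlap and keep the spec's
#'   clearance to each other and to the volume border, so synaptic sheets
#'   and mitochondria are never adjacent.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$shape
  vs <- spec$voxel_size
  sx <- vs[1]
  n <- prod(d)
  # voxel centers in nm
  px <- (rep.int(seq_len(d[1]), d[2] * d[3]) - 1) * vs[1]
  py <- (rep.int(rep(seq_len(d[2]), each = d[1]), d[3]) - 1) * vs[2]
  pz <- (rep(seq_len(d[3]), each = d[1] * d[2]) - 1) * vs[3]
  extent_nm <- (d - 1) * vs

  img <- rep(spec$intensity$bg, n)
  lab <- rep(1L, n)

  # faint background membranes: thin curved sheets, intensity only
  for (k in seq_len(spec$n_membranes)) {
    cen <- runif(3) * extent_nm
    nrm <- random_unit_vector()
    tt <- frame_from_normal(nrm)
    kap <- runif(2, -1, 1) / (2 * runif(2, 60, 120) * sx)
    dx <- px - cen[1]; dy <- py - cen[2]; dz <- pz - cen[3]
    u1 <- dx * tt[1, 1] + dy * tt[2, 1] + dz * tt[3, 1]
    u2 <- dx * tt[1, 2] + dy * tt[2, 2] + dz * tt[3, 2]
    s <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3] - kap[1] * u1^2 - kap[2] * u2^2
    hit <- abs(s) <= 0.75 * sx
    img[hit] <- spec$intensity$membrane
  }

  occupied <- array(FALSE, dim = d)

  place_object <- function(make_mask, bound_vox) {
    # bound_vox: per-axis half extent in voxels, for border clearance
    for (try in 1:50) {
      lo <- (bound_vox + spec$clearance) * vs
      hi <- extent_nm - lo
      if (any(hi < lo)) stop("phantom object does not fit in the volume",
                             call. = FALSE)
      cen <- lo + runif(3) * (hi - lo)
      res <- make_mask(cen)
      mask <- array(res$mask, dim = d)
      if (!any(mask)) next
      grown <- dilate6(mask, spec$clearance)
      if (!any(grown & occupied)) {
        return(list(mask = mask, aux = res))
      }
    }
    stop("could not place a phantom object without overlap after 50 retries",
         call. = FALSE)
  }

  # mitochondria: ellipsoids with cristae-like stripes
  for (k in seq_len(spec$n_mitochondria)) {
    ax <- runif(3, spec$mito_radius_range[1], spec$mito_radius_range[2]) * sx
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    stripe_dir <- random_unit_vector()
    stripe_period <- runif(1, 5, 8) * sx
    res <- place_object(function(cen) {
      dx <- px - cen[1]; dy <- py - cen[2]; dz <- pz - cen[3]
      q1 <- (dx * R[1, 1] + dy * R[2, 1] + dz * R[3, 1]) / ax[1]
      q2 <- (dx * R[1, 2] + dy * R[2, 2] + dz * R[3, 2]) / ax[2]
      q3 <- (dx * R[1, 3] + dy * R[2, 3] + dz * R[3, 3]) / ax[3]
      list(mask = q1^2 + q2^2 + q3^2 <= 1, cen = cen)
    }, bound_vox = ceiling(max(ax) / vs))
    m <- res$mask
    occupied <- occupied | m
    idx <- which(m)
    phase <- (px[idx] * stripe_dir[1] + py[idx] * stripe_dir[2] +
                pz[idx] * stripe_dir[3]) / stripe_period * 2 * pi
    base <- rep(spec$intensity$mito, length(idx))
    base[sin(phase) > 0.3] <- spec$intensity$mito_stripe
    img[idx] <- base
    lab[idx] <- 3L
  }

  # synaptic junctions: thin curved sheets with darker rim
  for (k in seq_len(spec$n_synapses)) {
    nrm <- random_unit_vector()
    tt <- frame_from_normal(nrm)
    ext <- runif(1, spec$sheet_extent_range[1], spec$sheet_extent_range[2]) * sx
    kap <- runif(2, -1, 1) / (2 * runif(2, 30, 60) * sx)
    half_th <- spec$sheet_thickness * sx / 2
    res <- place_object(function(cen) {
      dx <- px - cen[1]; dy <- py - cen[2]; dz <- pz - cen[3]
      u1 <- dx * tt[1, 1] + dy * tt[2, 1] + dz * tt[3, 1]
      u2 <- dx * tt[1, 2] + dy * tt[2, 2] + dz * tt[3, 2]
      s <- dx * nrm[1] + dy * nrm[2] + dz * nrm[3] -
        kap[1] * u1^2 - kap[2] * u2^2
      r2 <- u1^2 + u2^2
      list(mask = abs(s) <= half_th & r2 <= ext^2, r2 = r2)
    }, bound_vox = ceiling((ext + half_th) / vs))
    m <- res$mask
    occupied <- occupied | m
    idx <- which(m)
    rel <- sqrt(res$aux$r2[idx]) / ext
    base <- rep(spec$intensity$syn, length(idx))
    base[rel > 0.7] <- spec$intensity$syn_rim
    img[idx] <- base
    lab[idx] <- 2L
  }

  img <- img + rnorm(n, 0, spec$noise_sigma)
  img <- pmin(pmax(img, 0), 1)

  list(stack = image_stack(array(img, dim = d), vs),
       labels = label_volume(array(lab, dim = d), default_label_table()),
       spec = spec)
}

#' Sparse training scribbles from dense labels
#'
#' Emulates interactive brush training: a random per-class subset of the
#' labeled voxels is retained (each voxel kept independently with
#' probability `fraction`), the rest set to the unlabeled id 0.
#' Deterministic under `seed`.
#'
#' @param labels a [label_volume()].
#' @param fraction probability of keeping each labeled voxel, in (0, 1].
#' @param seed RNG seed.
#' @return a [label_volume()] of scribbles (subset of the input labels).
#' @export
make_training_scribbles <- function(labels, fraction, seed = 1L) {
  stopifnot(inherits(labels, "LabelVolume"),
            fraction > 0, fraction <= 1)
  with_seed(seed, {
    lab <- labels$labels
    out <- array(0L, dim = dim(lab))
    for (id in sort(setdiff(unique(as.vector(lab)), 0L))) {
      idx <- which(lab == id)
      keep <- idx[runif(length(idx)) < fraction]
      out[keep] <- id
    }
    label_volume(out, labels$label_table)
  })
}
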