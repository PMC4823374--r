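# Multiscale rotationally invariant Gaussian derivative features.
#
# At each scale sigma the image is convolved with the Gaussian and its first
# and second derivatives, normalized by sigma^order so responses are
# comparable across scales.  The per-scale feature components are the
# smoothed intensity, the gradient magnitude and the ordered eigenvalues of
# the Hessian of the smoothed image — all invariant to in-plane rotation.

#' Scale sequence and scale sets
#'
#' Scales form a half-octave geometric sequence starting at the base scale:
#' \eqn{\sigma_i = 2^{i/2}\sigma_0}, i = 0..n-1.  With `sigma0 = 4` and
#' `n = 4` the scales run from 4 to 11.31 pixels.
#'
#' @param sigma0 base scale in pixels (> 0).
#' @param n number of scales (>= 1).
#' @return `scale_sequence`: numeric vector of scales in pixels.
#' @export
scale_sequence <- function(sigma0, n) {
  stopifnot(is.numeric(sigma0), length(sigma0) == 1L, sigma0 > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  2^((seq_len(n) - 1) / 2) * sigma0
}

#' @rdname scale_sequence
#' @return `scale_set`: an object of class `ScaleSet` with elements `sigma0`,
#'   `n`, `sigmas`.
#' @export
scale_set <- function(sigma0, n = 4L) {
  structure(list(sigma0 = sigma0, n = as.integer(n),
                 sigmas = scale_sequence(sigma0, n)),
            class = "ScaleSet")
}

#' @export
print.ScaleSet <- function(x, ...) {
  cat(sprintf("ScaleSet: sigma0 = %g px, n = %d, scales = [%s] px\n",
              x$sigma0, x$n, paste(sprintf("%.2f", x$sigmas), collapse = ", ")))
  invisible(x)
}

# Sampled Gaussian derivative kernel of given order (0, 1, 2), truncated at
# 4 sigma, mirror-padded at borders by the convolution routine.  Discrete
# moments are calibrated so that the response to polynomials is exact:
# order 0 sums to 1; order 1 has zero sum and unit first moment; order 2 has
# zero sum and second moment 2.  The sigma^order normalization of the
# feature definition is applied on top.
gaussian_kernel <- function(sigma, order, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) {
    k <- g / sum(g)
  } else if (order == 1L) {
    k <- -x / sigma^2 * g
    k <- k - mean(k)                       # zero DC response
    k <- k * (-1 / sum(x * k))             # exact unit derivative on ramps
    k <- sigma * k
  } else if (order == 2L) {
    k <- (x^2 - sigma^2) / sigma^4 * g
    k <- k - mean(k)
    k <- k * (2 / sum(x^2 * k))            # exact second derivative on x^2
    k <- sigma^2 * k
  } else {
    stop("derivative order must be 0, 1 or 2", call. = FALSE)
  }
  k
}

# separable convolution of a 3D array (or 2D matrix promoted to one slice)
# with per-axis derivative orders; sigma-normalization is in the kernels
conv_sep <- function(vol, sigma, orders, truncate = 4) {
  d <- dim(vol)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- as.double(vol)
  for (axis in 0:2) {
    ord <- orders[axis + 1L]
    if (is.na(ord)) next                   # axis not filtered (2D features)
    k <- gaussian_kernel(sigma, ord, truncate)
    out <- .conv3d_axis(out, as.integer(d), k, axis)
  }
  array(out, dim = d)
}

#' Gaussian derivative responses of a single image
#'
#' Computes the six sigma-normalized responses of a 2D image at one scale:
#' the smoothed image `s00`, first derivatives `s10`, `s01` (times sigma) and
#' second derivatives `s20`, `s11`, `s02` (times sigma^2).  Convolutions use
#' mirror (reflect) boundary handling and kernels truncated at 4 sigma.
#'
#' @param image 2D numeric matrix indexed `[x, y]`.
#' @param sigma scale in pixels.
#' @return named list with elements `s00`, `s10`, `s01`, `s20`, `s11`, `s02`,
#'   each a matrix of the input size.
#' @export
derivative_responses_2d <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  d2 <- function(ox, oy) {
    r <- conv_sep(array(image, dim = c(dim(image), 1L)), sigma,
                  c(ox, oy, NA))
    array(r, dim = dim(image))
  }
  list(s00 = d2(0L, 0L), s10 = d2(1L, 0L), s01 = d2(0L, 1L),
       s20 = d2(2L, 0L), s11 = d2(1L, 1L), s02 = d2(0L, 2L))
}

#' Eigenvalues of the 2x2 Hessian of smoothed-image responses
#'
#' Closed-form eigenvalues of \eqn{[[s_{20}, s_{11}], [s_{11}, s_{02}]]},
#' returned in descending order:
#' \deqn{\lambda_{1,2} = \tfrac12\big(s_{20}+s_{02} \pm
#'   \sqrt{(s_{20}-s_{02})^2 + 4 s_{11}^2}\big).}
#'
#' @param s20,s11,s02 second-derivative responses (vectors/arrays of equal
#'   shape).
#' @return list with elements `l1`, `l2` (`l1 >= l2` elementwise).
#' @export
hessian_eigenvalues_2d <- function(s20, s11, s02) {
  disc <- sqrt((s20 - s02)^2 + 4 * s11^2)
  tr <- s20 + s02
  list(l1 = (tr + disc) / 2, l2 = (tr - disc) / 2)
}

#' Eigenvalues of the symmetric 3x3 Hessian, vectorized
#'
#' Analytic (trigonometric) eigenvalues of the per-voxel matrix
#' \eqn{[[s_{200}, s_{110}, s_{101}], [s_{110}, s_{020}, s_{011}],
#' [s_{101}, s_{011}, s_{002}]]}, in descending order.
#'
#' @param s200,s020,s002 pure second derivatives.
#' @param s110,s101,s011 mixed second derivatives.
#' @return list with elements `l1`, `l2`, `l3` (`l1 >= l2 >= l3`).
#' @export
hessian_eigenvalues_3d <- function(s200, s020, s002, s110, s101, s011) {
  a <- as.double(s200); b <- as.double(s020); c <- as.double(s002)
  d <- as.double(s110); e <- as.double(s101); f <- as.double(s011)
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(p2 / 6)
  l1 <- l2 <- l3 <- q                      # p == 0: triple eigenvalue q
  pos <- p > 0
  if (any(pos)) {
    aa <- (a[pos] - q[pos]) / p[pos]; bb <- (b[pos] - q[pos]) / p[pos]
    cc <- (c[pos] - q[pos]) / p[pos]
    dd <- d[pos] / p[pos]; ee <- e[pos] / p[pos]; ff <- f[pos] / p[pos]
    detB <- aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
      ee * (dd * ff - bb * ee)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[pos] + 2 * p[pos] * cos(phi)
    e3 <- q[pos] + 2 * p[pos] * cos(phi + 2 * pi / 3)
    l1[pos] <- e1
    l3[pos] <- e3
    l2[pos] <- 3 * q[pos] - e1 - e3
  }
  shp <- dim(s200)
  if (!is.null(shp)) {
    dim(l1) <- shp; dim(l2) <- shp; dim(l3) <- shp
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

feature_stack <- function(values, spatial_dim, scales, extractor) {
  structure(list(values = values, spatial_dim = as.integer(spatial_dim),
                 scale_set = scales, extractor = extractor),
            class = "FeatureStack")
}

#' @export
print.FeatureStack <- function(x, ...) {
  cat(sprintf("FeatureStack %s: %d x %d x %d voxels, %d channels (%d scales)\n",
              x$extractor, x$spatial_dim[1], x$spatial_dim[2],
              x$spatial_dim[3], ncol(x$values), x$scale_set$n))
  invisible(x)
}

#' Per-slice (2D) multiscale features
#'
#' The anisotropy-robust extractor: every Z slice is processed independently
#' with no cross-slice mixing.  Per voxel and scale the four components are
#' the smoothed intensity, the gradient magnitude
#' \eqn{\sqrt{s_{10}^2+s_{01}^2}} and the two ordered Hessian eigenvalues,
#' concatenated over scales into a `4n`-channel vector.
#'
#' @param stack an [image_stack()].
#' @param scales a [scale_set()].
#' @param truncate Gaussian truncation radius in sigmas.
#' @return a `FeatureStack` whose `values` matrix has one row per voxel
#'   (column-major `[x, y, z]` order) and `4n` columns.
#' @export
extract_f2d <- function(stack, scales, truncate = 4) {
  stopifnot(inherits(stack, "ImageStack"), inherits(scales, "ScaleSet"))
  d <- dim(stack$data)
  nvox <- prod(d)
  n <- scales$n
  values <- matrix(NA_real_, nrow = nvox, ncol = 4L * n)
  for (i in seq_len(n)) {
    s <- scales$sigmas[i]
    # x/y-only convolutions never mix slices, so the whole volume goes at once
    s00 <- conv_sep(stack$data, s, c(0L, 0L, NA), truncate)
    s10 <- conv_sep(stack$data, s, c(1L, 0L, NA), truncate)
    s01 <- conv_sep(stack$data, s, c(0L, 1L, NA), truncate)
    s20 <- conv_sep(stack$data, s, c(2L, 0L, NA), truncate)
    s11 <- conv_sep(stack$data, s, c(1L, 1L, NA), truncate)
    s02 <- conv_sep(stack$data, s, c(0L, 2L, NA), truncate)
    ev <- hessian_eigenvalues_2d(s20, s11, s02)
    j <- 4L * (i - 1L)
    values[, j + 1L] <- s00
    values[, j + 2L] <- sqrt(s10^2 + s01^2)
    values[, j + 3L] <- ev$l1
    values[, j + 4L] <- ev$l2
  }
  feature_stack(values, d, scales, "F2D")
}

#' Volumetric (3D) multiscale features
#'
#' Generalization of [extract_f2d()] for (near-)isotropic stacks: per voxel
#' and scale the five components are the smoothed intensity, the 3D gradient
#' magnitude and the three ordered eigenvalues of the 3D Hessian,
#' concatenated over scales into a `5n`-channel vector.  A warning is issued
#' when the stack's anisotropy factor exceeds `rho_warn`, since the isotropic
#' operators are then applied across sections of very different physical
#' spacing.
#'
#' @inheritParams extract_f2d
#' @param rho_warn anisotropy factor above which a warning is issued.
#' @return a `FeatureStack` with `5n` channels.
#' @export
extract_f3d <- function(stack, scales, truncate = 4, rho_warn = 1.5) {
  stopifnot(inherits(stack, "ImageStack"), inherits(scales, "ScaleSet"))
  r <- rho(stack)
  if (r > rho_warn) {
    warning(sprintf(
      "stack anisotropy factor %.2f exceeds %.2f; the per-slice extractor (extract_f2d) is recommended",
      r, rho_warn), call. = FALSE)
  }
  d <- dim(stack$data)
  n <- scales$n
  values <- matrix(NA_real_, nrow = prod(d), ncol = 5L * n)
  for (i in seq_len(n)) {
    s <- scales$sigmas[i]
    dr <- function(ox, oy, oz) conv_sep(stack$data, s, c(ox, oy, oz), truncate)
    s000 <- dr(0L, 0L, 0L)
    s100 <- dr(1L, 0L, 0L); s010 <- dr(0L, 1L, 0L); s001 <- dr(0L, 0L, 1L)
    s200 <- dr(2L, 0L, 0L); s020 <- dr(0L, 2L, 0L); s002 <- dr(0L, 0L, 2L)
    s110 <- dr(1L, 1L, 0L); s101 <- dr(1L, 0L, 1L); s011 <- dr(0L, 1L, 1L)
    ev <- hessian_eigenvalues_3d(s200, s020, s002, s110, s101, s011)
    j <- 5L * (i - 1L)
    values[, j + 1L] <- s000
    values[, j + 2L] <- sqrt(s100^2 + s010^2 + s001^2)
    values[, j + 3L] <- ev$l1
    values[, j + 4L] <- ev$l2
    values[, j + 5L] <- ev$l3
  }
  feature_stack(values, d, scales, "F3D")
}

#' Extract features, choosing the extractor from the anisotropy factor
#'
#' With `extractor = "auto"`, the volumetric extractor is used for
#' near-isotropic stacks (`rho <= rho_threshold`) and the per-slice extractor
#' otherwise.
#'
#' @inheritParams extract_f2d
#' @param extractor `"auto"`, `"f2d"` or `"f3d"`.
#' @param rho_threshold anisotropy cutoff for the automatic choice.
#' @return a `FeatureStack`.
#' @export
extract_features <- function(stack, scales,
                             extractor = c("auto", "f2d", "f3d"),
                             rho_threshold = 1.5, truncate = 4) {
  extractor <- match.arg(extractor)
  if (extractor == "auto") {
    extractor <- if (rho(stack) <= rho_threshold) "f3d" else "f2d"
  }
  switch(extractor,
         f2d = extract_f2d(stack, scales, truncate),
         f3d = extract_f3d(stack, scales, truncate,
                           rho_warn = rho_threshold))
}
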