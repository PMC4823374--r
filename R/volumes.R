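# Core volumetric containers and stack / label I/O.
#
# Convention used throughout the package: volumes are 3D arrays indexed
# [x, y, z]; the slice index is Z and corresponds to the section number.
# Voxel sizes are nanometres (sx, sy, sz) with sx == sy.

#' Anisotropy factor of a voxel grid
#'
#' Serial-section EM stacks usually have a coarser resolution across sections
#' (Z) than within a section (X/Y).  The anisotropy factor is the ratio of the
#' Z voxel size to the in-plane voxel size,
#' \deqn{\rho = s_z / s_x,}
#' so \eqn{\rho = 1} for isotropic data and \eqn{\rho > 1} for stacks whose
#' sections are thicker than their pixels.
#'
#' @param voxel_size numeric length-3 vector `(sx, sy, sz)` in nm; `sx` must
#'   equal `sy` and all entries must be positive.
#' @return the dimensionless ratio `sz / sx`.
#' @examples
#' anisotropy_factor(c(3.7, 3.7, 20))   # 5.405...
#' anisotropy_factor(c(20, 20, 20))     # 1
#' @export
anisotropy_factor <- function(voxel_size) {
  check_voxel_size(voxel_size)
  voxel_size[3] / voxel_size[1]
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      anyNA(voxel_size)) {
    stop("invalid geometry: voxel_size must be a numeric (sx, sy, sz) triple",
         call. = FALSE)
  }
  if (any(voxel_size <= 0)) {
    stop("invalid geometry: voxel sizes must be positive", call. = FALSE)
  }
  if (voxel_size[1] != voxel_size[2]) {
    stop("invalid geometry: in-plane voxel sizes sx and sy must be equal",
         call. = FALSE)
  }
  invisible(voxel_size)
}

#' Image stack container
#'
#' Wraps a 3D scalar grid (indexed `[x, y, z]`, Z = section index) together
#' with its voxel size in nm.  The anisotropy factor is always derived from
#' the voxel size, never stored separately.
#'
#' @param data 3D numeric array of finite intensities.
#' @param voxel_size `(sx, sy, sz)` in nm, `sx == sy`, all positive.
#' @return an object of class `ImageStack` with elements `data` and
#'   `voxel_size`; `rho(stack)` gives the anisotropy factor.
#' @export
image_stack <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3D array indexed [x, y, z]", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  check_voxel_size(voxel_size)
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "ImageStack")
}

#' @rdname image_stack
#' @param x an `ImageStack` (or an object with a `voxel_size` element).
#' @export
rho <- function(x) {
  UseMethod("rho")
}

#' @export
rho.ImageStack <- function(x) anisotropy_factor(x$voxel_size)

#' @export
rho.default <- function(x) anisotropy_factor(x$voxel_size)

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack %d x %d x %d (X x Y x Z), voxel %g x %g x %g nm, rho = %.3g\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], rho(x)))
  invisible(x)
}

#' Default label dictionary
#'
#' Label ids used throughout: 0 = unlabeled/ignore (training volumes only),
#' 1 = background, 2 = synaptic junction, 3 = mitochondrion.
#'
#' @return named integer vector mapping names to ids.
#' @export
default_label_table <- function() {
  c(unlabeled = 0L, bg = 1L, syn = 2L, mit = 3L)
}

#' Label volume container
#'
#' An integer-valued 3D grid of the same shape as its image stack, plus a
#' dictionary mapping label names to integer ids.  Id 0 is reserved for
#' "unlabeled" voxels in training volumes.
#'
#' @param labels 3D integer array, indexed `[x, y, z]`.
#' @param label_table named integer vector (name -> id); every value occurring
#'   in `labels` must be present.
#' @return an object of class `LabelVolume` with elements `labels` and
#'   `label_table`.
#' @export
label_volume <- function(labels, label_table = default_label_table()) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("labels must be a 3D array indexed [x, y, z]", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  ids <- sort(unique(as.vector(labels)))
  if (!all(ids %in% label_table)) {
    stop("label ids not in label_table: ",
         paste(setdiff(ids, label_table), collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, label_table = label_table),
            class = "LabelVolume")
}

#' @export
dim.LabelVolume <- function(x) dim(x$labels)

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- table(factor(x$labels, levels = x$label_table))
  names(tab) <- names(x$label_table)
  cat(sprintf("LabelVolume %d x %d x %d (X x Y x Z)\n", d[1], d[2], d[3]))
  print(tab)
  invisible(x)
}

# ---- I/O ------------------------------------------------------------------

# Slice images come in as [row, col] = [y, x]; transpose to the package's
# [x, y] convention.  Color slices are collapsed to grayscale by channel mean.
slice_to_xy <- function(m, path) {
  if (length(dim(m)) == 3L) m <- rowMeans(m, dims = 2L)
  if (length(dim(m)) != 2L) {
    stop(sprintf("format error: slice '%s' is not a 2D image", path),
         call. = FALSE)
  }
  t(m)
}

read_slice_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("format error: unsupported slice format '%s' (%s)", ext, path),
         call. = FALSE))
  slice_to_xy(img, path)
}

#' Read an image stack
#'
#' Accepts either a multipage TIFF or a directory of equally sized 2D slice
#' images (TIFF or PNG); slices are stacked in lexicographic filename order,
#' which must correspond to increasing Z.  Intensities are rescaled to
#' `[0, 1]` at load time (8-/16-bit sources are promoted losslessly to
#' doubles), so derivative magnitudes are comparable across bit depths.
#'
#' @param path multipage TIFF file or a directory of slices.
#' @param voxel_size `(sx, sy, sz)` in nm.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size = c(1, 1, 1)) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      stop(sprintf("format error: no TIFF/PNG slices found in '%s'", path),
           call. = FALSE)
    }
    files <- files[order(basename(files))]
    slices <- lapply(files, read_slice_file)
    ref <- dim(slices[[1L]])
    for (i in seq_along(slices)) {
      if (!identical(dim(slices[[i]]), ref)) {
        stop(sprintf(
          "format error: slice '%s' has size %s, expected %s",
          basename(files[i]), paste(dim(slices[[i]]), collapse = "x"),
          paste(ref, collapse = "x")), call. = FALSE)
      }
    }
    data <- array(unlist(slices, use.names = FALSE),
                  dim = c(ref, length(slices)))
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(seq_along(pages), function(i) {
      slice_to_xy(pages[[i]], sprintf("%s [page %d]", path, i))
    })
    ref <- dim(pages[[1L]])
    for (i in seq_along(pages)) {
      if (!identical(dim(pages[[i]]), ref)) {
        stop(sprintf("format error: page %d of '%s' has size %s, expected %s",
                     i, path, paste(dim(pages[[i]]), collapse = "x"),
                     paste(ref, collapse = "x")), call. = FALSE)
      }
    }
    data <- array(unlist(pages, use.names = FALSE),
                  dim = c(ref, length(pages)))
  } else {
    stop(sprintf("format error: '%s' does not exist", path), call. = FALSE)
  }
  rng <- range(data)
  if (rng[2] > 1 || rng[1] < 0) {            # not already in [0,1]
    data <- (data - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  image_stack(data, voxel_size)
}

#' Write an image stack as a multipage TIFF
#'
#' Intensities are stored as 32-bit floats; values outside `[0, 1]` are
#' clipped by the TIFF writer.
#'
#' @param path output TIFF file.
#' @param stack an [image_stack()].
#' @export
write_stack <- function(path, stack) {
  stopifnot(inherits(stack, "ImageStack"))
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(z) t(stack$data[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write / read label volumes as multipage TIFF
#'
#' Label ids are stored as 8-bit gray values (id/255), which round-trips
#' bit-exactly for ids 0..255.
#'
#' @param path TIFF file.
#' @param labels a [label_volume()].
#' @export
write_labels <- function(path, labels) {
  stopifnot(inherits(labels, "LabelVolume"))
  if (max(labels$labels) > 255L) {
    stop("label ids > 255 cannot be stored in an 8-bit label TIFF",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(labels$labels)[3]),
                  function(z) t(labels$labels[, , z]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels
#' @param label_table dictionary for the volume being read.
#' @export
read_labels <- function(path, label_table = default_label_table()) {
  if (!file.exists(path)) {
    stop(sprintf("format error: '%s' does not exist", path), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ref <- NULL
  slices <- lapply(seq_along(pages), function(i) {
    m <- slice_to_xy(pages[[i]], sprintf("%s [page %d]", path, i))
    as.integer(round(m * 255))
  })
  dims <- dim(slice_to_xy(pages[[1L]], path))
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(dims, length(pages)))
  label_volume(arr, label_table)
}
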