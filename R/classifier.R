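# PCA-reduced Gaussian Bayes voxel classifier.
#
# Class-conditional densities are multivariate Gaussians fitted per label in
# a PCA subspace retaining a fixed fraction of the total variance (default
# 99 %); posteriors follow Bayes' rule with priors estimated from labeled
# voxel frequencies.  All densities are evaluated in log space via cached
# Cholesky factors and normalized by log-sum-exp, so posteriors stay finite
# arbitrarily far from the class means.

#' Fit a PCA basis retaining a fraction of variance
#'
#' The retained dimension is the smallest number of leading principal axes
#' whose cumulative variance fraction reaches `variance_to_retain`.  For
#' tractability the fit may subsample the rows uniformly at random (with a
#' fixed seed) before decomposition.
#'
#' @param x numeric matrix, one sample per row.
#' @param variance_to_retain fraction of total variance to keep (default
#'   0.99).
#' @param max_samples rows are subsampled to at most this count.
#' @param seed seed for the subsampling.
#' @return list with elements `center` (k-vector), `basis` (k x k' matrix,
#'   orthonormal columns) and `k` (retained dimension).
#' @export
fit_pca <- function(x, variance_to_retain = 0.99, max_samples = 1e6,
                    seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (nrow(x) > max_samples) {
    idx <- with_seed(seed, sample.int(nrow(x), max_samples))
    x <- x[idx, , drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= 0) {                         # zero-variance data
    return(list(center = pc$center, basis = pc$rotation[, 1L, drop = FALSE],
                k = 1L))
  }
  kprime <- which(cumsum(vars) / total >= variance_to_retain - 1e-12)[1L]
  if (is.na(kprime)) kprime <- length(vars)
  list(center = pc$center,
       basis = pc$rotation[, seq_len(kprime), drop = FALSE],
       k = as.integer(kprime))
}

project_pca <- function(pca, x) {
  sweep(x, 2L, pca$center) %*% pca$basis
}

# run expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

regularize_covariance <- function(sigma, eps = 1e-6) {
  k <- nrow(sigma)
  tr <- sum(diag(sigma))
  floor_val <- if (tr > 0) eps * tr / k else eps
  sigma + diag(floor_val, k)
}

#' Train the Gaussian voxel classifier
#'
#' Fits the PCA basis on the whole feature cloud, then per label the sample
#' mean and covariance of the projected features of the voxels carrying that
#' label, and the label priors as labeled-voxel frequencies.  Voxels with
#' label id 0 (unlabeled) are ignored.  Covariances are regularized by adding
#' `eps * trace/k'` to the diagonal (a fixed `eps` floor for degenerate
#' classes) so the Cholesky factor always exists.
#'
#' @param features a `FeatureStack` for the training stack.
#' @param training_labels a [label_volume()] of the same shape; id 0 marks
#'   unlabeled voxels.
#' @param variance_to_retain PCA variance fraction (default 0.99).
#' @param eps covariance regularization factor.
#' @param max_pca_samples subsample cap for the PCA fit.
#' @param seed seed for the PCA subsampling.
#' @return an object of class `GaussianClassifierModel`.
#' @export
train_classifier <- function(features, training_labels,
                             variance_to_retain = 0.99, eps = 1e-6,
                             max_pca_samples = 1e6, seed = 1L) {
  stopifnot(inherits(features, "FeatureStack"),
            inherits(training_labels, "LabelVolume"))
  if (!identical(features$spatial_dim, dim(training_labels$labels))) {
    stop("feature stack and label volume shapes differ", call. = FALSE)
  }
  y <- as.vector(training_labels$labels)
  labs <- sort(unique(y[y != 0L]))
  if (length(labs) < 1L) stop("no labeled voxels in training volume",
                              call. = FALSE)
  counts <- vapply(labs, function(l) sum(y == l), integer(1))
  few <- labs[counts < 2L]
  if (length(few)) {
    nm <- names(training_labels$label_table)[
      match(few, training_labels$label_table)]
    stop("training error: label(s) with fewer than 2 labeled voxels: ",
         paste(ifelse(is.na(nm), few, nm), collapse = ", "), call. = FALSE)
  }
  pca <- fit_pca(features$values, variance_to_retain, max_pca_samples, seed)
  pca$center <- unname(pca$center)
  dimnames(pca$basis) <- NULL
  classes <- lapply(seq_along(labs), function(i) {
    xi <- project_pca(pca, features$values[y == labs[i], , drop = FALSE])
    mu <- unname(colMeans(xi))
    sg <- regularize_covariance(unname(stats::cov(xi)), eps)
    dimnames(sg) <- NULL
    list(label = labs[i], mu = mu, sigma = sg,
         chol = chol(sg), prior = counts[i] / sum(counts))
  })
  structure(list(pca = pca, classes = classes, labels = labs,
                 label_table = training_labels$label_table,
                 n_channels = ncol(features$values),
                 extractor = features$extractor,
                 scale_set = features$scale_set),
            class = "GaussianClassifierModel")
}

#' @export
print.GaussianClassifierModel <- function(x, ...) {
  nm <- names(x$label_table)[match(x$labels, x$label_table)]
  pri <- vapply(x$classes, `[[`, numeric(1), "prior")
  cat(sprintf(
    "GaussianClassifierModel: %d -> %d dims (PCA), labels: %s\n",
    x$n_channels, x$pca$k,
    paste(sprintf("%s (prior %.3f)", nm, pri), collapse = ", ")))
  invisible(x)
}

# log N(x | mu, Sigma) for rows of x, via the cached Cholesky factor
log_gaussian_density <- function(x, mu, chol_sigma) {
  k <- length(mu)
  centered <- sweep(x, 2L, mu)
  z <- backsolve(chol_sigma, t(centered), transpose = TRUE)
  -0.5 * (k * log(2 * pi) + 2 * sum(log(diag(chol_sigma))) + colSums(z^2))
}

#' Voxel-wise posterior probabilities
#'
#' Applies Bayes' rule per voxel: the posterior of label y is proportional to
#' the class-conditional Gaussian density times the prior, normalized over
#' labels (computed in log space with log-sum-exp).
#'
#' @param model a trained `GaussianClassifierModel`.
#' @param features a `FeatureStack` with the channel count the model was
#'   trained on.
#' @return a `ProbabilityMap`: 4D array `[x, y, z, label]` of posteriors
#'   summing to 1 over the last axis, with attribute `labels` (integer label
#'   ids) and `label_table`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "GaussianClassifierModel"),
            inherits(features, "FeatureStack"))
  if (ncol(features$values) != model$n_channels) {
    stop(sprintf("channel-count mismatch: model expects %d, features have %d",
                 model$n_channels, ncol(features$values)), call. = FALSE)
  }
  xp <- project_pca(model$pca, features$values)
  nlab <- length(model$classes)
  logpost <- matrix(NA_real_, nrow = nrow(xp), ncol = nlab)
  for (i in seq_len(nlab)) {
    cl <- model$classes[[i]]
    logpost[, i] <- log_gaussian_density(xp, cl$mu, cl$chol) + log(cl$prior)
  }
  mx <- logpost[cbind(seq_len(nrow(logpost)), max.col(logpost, "first"))]
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  probability_map(post, features$spatial_dim, model$labels,
                  model$label_table)
}

probability_map <- function(post, spatial_dim, labels, label_table) {
  arr <- array(post, dim = c(spatial_dim, length(labels)))
  structure(arr, class = "ProbabilityMap", labels = as.integer(labels),
            label_table = label_table)
}

#' @export
print.ProbabilityMap <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("ProbabilityMap %d x %d x %d voxels, %d labels (ids %s)\n",
              d[1], d[2], d[3], d[4],
              paste(attr(x, "labels"), collapse = ", ")))
  invisible(x)
}

#' Maximum-posterior labeling
#'
#' Assigns each voxel the label with the highest posterior probability; exact
#' ties are broken toward the lowest label id.
#'
#' @param probmap a `ProbabilityMap`.
#' @return a [label_volume()].
#' @export
argmax_labeling <- function(probmap) {
  stopifnot(inherits(probmap, "ProbabilityMap"))
  d <- dim(probmap)
  labels <- attr(probmap, "labels")
  m <- matrix(as.double(probmap), nrow = prod(d[1:3]), ncol = d[4])
  idx <- max.col(m, ties.method = "first")   # label ids sorted ascending
  label_volume(array(labels[idx], dim = d[1:3]),
               attr(probmap, "label_table"))
}

#' Serialize / load a trained classifier
#'
#' The model is written as a single JSON file holding the PCA center and
#' basis, per-label mean vector, covariance matrix and prior, the label
#' table, and the feature-extractor settings (tag, base scale, scale count),
#' at full double precision.
#'
#' @param model a `GaussianClassifierModel`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "GaussianClassifierModel"))
  obj <- list(
    format = "vemseg-gaussian-classifier-v1",
    pca = list(center = model$pca$center, basis = model$pca$basis,
               k = model$pca$k),
    classes = lapply(model$classes, function(cl) {
      list(label = cl$label, mu = cl$mu, sigma = cl$sigma, prior = cl$prior)
    }),
    label_table = as.list(model$label_table),
    n_channels = model$n_channels,
    extractor = model$extractor,
    scale_set = list(sigma0 = model$scale_set$sigma0, n = model$scale_set$n)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "vemseg-gaussian-classifier-v1")) {
    stop("not a vemseg classifier model file", call. = FALSE)
  }
  k <- as.integer(obj$pca$k)
  num <- function(x) as.numeric(unlist(x))
  basis <- matrix(num(obj$pca$basis), ncol = k)
  classes <- lapply(obj$classes, function(cl) {
    sg <- matrix(num(cl$sigma), nrow = k)
    list(label = as.integer(cl$label), mu = num(cl$mu), sigma = sg,
         chol = chol(sg), prior = as.numeric(cl$prior))
  })
  lt <- vapply(obj$label_table, function(v) as.integer(v), integer(1))
  structure(list(
    pca = list(center = num(obj$pca$center), basis = basis, k = k),
    classes = classes,
    labels = vapply(classes, `[[`, integer(1), "label"),
    label_table = lt,
    n_channels = as.integer(obj$n_channels),
    extractor = obj$extractor,
    scale_set = scale_set(as.numeric(obj$scale_set$sigma0),
                          as.integer(obj$scale_set$n))),
    class = "GaussianClassifierModel")
}
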