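# Voxel-wise evaluation metrics, connected-component counting with
# threshold sweeps, and slice-block cross-validation over parameter grids.

#' Voxel-wise segmentation metrics (one label vs rest)
#'
#' Computes the one-vs-rest confusion counts for `foreground` and derives
#' \deqn{TPR = TP/(TP+FN),\; FPR = FP/(FP+TN),\; ACC = (TP+TN)/total,}
#' \deqn{JAC = TP/(TP+FP+FN),\; VOE = |FP-FN|/(TP+FN).}
#' When the ground truth has no foreground voxels, TPR and VOE are undefined
#' and reported as `NA` (JAC is still defined unless the prediction is also
#' empty, in which case it is reported as `NA`).
#'
#' @param pred,gt [label_volume()]s (or integer arrays) of identical shape.
#' @param foreground label id treated as positive.
#' @return named list: `TPR`, `FPR`, `ACC`, `JAC`, `VOE`, plus the raw
#'   counts `TP`, `TN`, `FP`, `FN`.
#' @export
voxel_metrics <- function(pred, gt, foreground) {
  p <- if (inherits(pred, "LabelVolume")) pred$labels else pred
  g <- if (inherits(gt, "LabelVolume")) gt$labels else gt
  if (!all(dim(p) == dim(g))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
  pp <- p == foreground
  gp <- g == foreground
  TP <- sum(pp & gp)
  FP <- sum(pp & !gp)
  FN <- sum(!pp & gp)
  TN <- sum(!pp & !gp)
  total <- TP + TN + FP + FN
  list(
    TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_,
    ACC = (TP + TN) / total,
    JAC = if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_,
    VOE = if (TP + FN > 0) abs(FP - FN) / (TP + FN) else NA_real_,
    TP = TP, TN = TN, FP = FP, FN = FN)
}

component_sizes <- function(labels, target, connectivity = 6L) {
  lab <- if (inherits(labels, "LabelVolume")) labels$labels else labels
  mask <- array(as.integer(lab == target), dim = dim(lab))
  cc <- .label_components(as.integer(mask), as.integer(dim(lab)),
                          as.integer(connectivity))
  as.integer(attr(cc, "sizes"))
}

#' Count connected components of a label, discarding small ones
#'
#' Connected components of the target label (6-connectivity by default,
#' matching the CRF graph; 26 available) with at least `min_size` voxels.
#'
#' @param labels a [label_volume()] or integer array.
#' @param target label id to count.
#' @param min_size discard components smaller than this (voxels).
#' @param connectivity 6 or 26.
#' @return integer count.
#' @export
count_components <- function(labels, target, min_size = 0L,
                             connectivity = 6L) {
  stopifnot(min_size >= 0, connectivity %in% c(6L, 26L))
  sizes <- component_sizes(labels, target, connectivity)
  sum(sizes >= min_size)
}

#' Component-count sweep over size thresholds
#'
#' For each threshold t in `thresholds`, the number of connected components
#' of the target label with size >= t; counts are non-increasing in t.
#'
#' @inheritParams count_components
#' @param thresholds integer vector of size thresholds (default 10..2000).
#' @param gt_count reference (true) number of structures.
#' @return an object of class `CountSweep` with elements `thresholds`,
#'   `counts`, `gt_count`.
#' @export
count_sweep <- function(labels, target, gt_count,
                        thresholds = 10:2000, connectivity = 6L) {
  sizes <- sort(component_sizes(labels, target, connectivity))
  # components with size >= t, via a single pass over the sorted sizes
  counts <- length(sizes) - findInterval(thresholds - 1L, sizes)
  structure(list(thresholds = as.integer(thresholds),
                 counts = as.integer(counts),
                 gt_count = as.integer(gt_count)),
            class = "CountSweep")
}

#' Average absolute counting error over a threshold sweep
#'
#' \deqn{\frac{1}{|T|}\sum_{t\in T} |\#CC_{[size \ge t]} - GT|}
#'
#' @param sweep a [count_sweep()].
#' @return scalar mean absolute deviation from the reference count.
#' @export
count_error <- function(sweep) {
  stopifnot(inherits(sweep, "CountSweep"))
  mean(abs(sweep$counts - sweep$gt_count))
}

#' Slice-block cross-validation over parameter grids
#'
#' Splits the stack into `k` contiguous Z blocks (the remainder goes to the
#' last block) to respect the strong correlation between consecutive
#' sections.  For every combination of base scale and in-plane regularization
#' weight, each fold trains the classifier on the labeled voxels of the other
#' k-1 blocks and evaluates TPR/FPR/ACC/JAC (and VOE) on the held-out block
#' after CRF regularization, one-vs-rest per non-background label.
#'
#' @param stack an [image_stack()].
#' @param gt a [label_volume()] of dense ground truth (used both as training
#'   labels on the training blocks and as reference on the test block).
#' @param sigma0_list base scales to evaluate (pixels).
#' @param theta_list in-plane CRF weights to evaluate.
#' @param k number of folds (default 5).
#' @param n_scales scales per feature vector.
#' @param extractor `"auto"`, `"f2d"` or `"f3d"`.
#' @param train_fraction fraction of training-block voxels kept as scribbles
#'   (1 = all labeled voxels).
#' @param connectivity passed through to the distance-matrix construction.
#' @param seed seed controlling scribble subsampling.
#' @return data frame with columns `sigma0`, `theta_xy`, `fold`, `label`,
#'   `TPR`, `FPR`, `ACC`, `JAC`, `VOE`.
#' @export
crossval_grid <- function(stack, gt, sigma0_list, theta_list, k = 5L,
                          n_scales = 4L, extractor = "auto",
                          train_fraction = 1, connectivity = 6L, seed = 1L) {
  stopifnot(inherits(stack, "ImageStack"), inherits(gt, "LabelVolume"))
  d <- dim(stack$data)
  nz <- d[3]
  if (nz < k) stop("fewer Z slices than folds", call. = FALSE)
  block_of <- pmin(((seq_len(nz) - 1L) %/% (nz %/% k)) + 1L, k)
  r <- rho(stack)
  rows <- list()
  for (s0 in sigma0_list) {
    feats <- extract_features(stack, scale_set(s0, n_scales), extractor)
    for (fold in seq_len(k)) {
      test_z <- which(block_of == fold)
      train_labels <- gt$labels
      train_labels[, , test_z] <- 0L
      if (train_fraction < 1) {
        lv <- label_volume(train_labels, gt$label_table)
        train_labels <- make_training_scribbles(lv, train_fraction,
                                                seed = seed + fold)$labels
      }
      if (all(train_labels == 0L)) {
        warning(sprintf("fold %d has no labeled training voxels; skipped",
                        fold))
        next
      }
      counts <- table(train_labels[train_labels != 0L])
      if (any(counts < 2L)) {
        warning(sprintf("fold %d lacks training voxels for some label; skipped",
                        fold))
        next
      }
      model <- train_classifier(feats, label_volume(train_labels,
                                                    gt$label_table))
      for (th in theta_list) {
        probs <- predict_proba(model, feats)
        config <- crf_config(theta_xy = th, rho = r)
        pred <- regularize_tiled(probs, config)
        fg_ids <- setdiff(model$labels, 1L)
        if (length(fg_ids) == 0L) fg_ids <- model$labels
        for (fg in fg_ids) {
          mm <- voxel_metrics(pred$labels[, , test_z, drop = FALSE],
                              gt$labels[, , test_z, drop = FALSE], fg)
          rows[[length(rows) + 1L]] <- data.frame(
            sigma0 = s0, theta_xy = th, fold = fold, label = fg,
            TPR = mm$TPR, FPR = mm$FPR, ACC = mm$ACC, JAC = mm$JAC,
            VOE = mm$VOE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Fold-averaged cross-validation table
#'
#' @param cv output of [crossval_grid()].
#' @return data frame averaged over folds per (sigma0, theta_xy, label).
#' @export
crossval_summary <- function(cv) {
  agg <- stats::aggregate(cv[c("TPR", "FPR", "ACC", "JAC", "VOE")],
                          by = cv[c("sigma0", "theta_xy", "label")],
                          FUN = mean, na.rm = TRUE)
  agg[order(agg$sigma0, agg$theta_xy, agg$label), ]
}
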