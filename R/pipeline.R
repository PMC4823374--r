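# End-to-end pipeline: features -> classification -> regularization ->
# optional smoothing, with a round-trippable YAML configuration.

run_config_defaults <- function() {
  list(
    sigma0 = 2,
    n_scales = 4L,
    extractor = "auto",            # auto | f2d | f3d
    rho_threshold = 1.5,
    variance_to_retain = 0.99,
    theta_xy = 4,
    theta_z = NA_real_,            # NA -> theta_xy / rho
    forbid = list(c(2L, 3L)),      # label id pairs that may not touch
    tile = c(256L, 256L, 64L),
    margin = 10L,
    smooth = TRUE,
    smooth_tol = 1e-4,
    smooth_max_iter = 1000L,
    connectivity = 6L,
    seed = 1L
  )
}

#' Pipeline run configuration
#'
#' All stage parameters with documented defaults; unknown keys are rejected.
#' A config written with [write_run_config()] parses back to an identical
#' object.
#'
#' @param ... overrides of the defaults (see [run_config_defaults] source
#'   for keys: `sigma0`, `n_scales`, `extractor`, `rho_threshold`,
#'   `variance_to_retain`, `theta_xy`, `theta_z`, `forbid`, `tile`,
#'   `margin`, `smooth`, `smooth_tol`, `smooth_max_iter`, `connectivity`,
#'   `seed`).
#' @return an object of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  cfg$n_scales <- as.integer(cfg$n_scales)
  cfg$tile <- as.integer(cfg$tile)
  cfg$margin <- as.integer(cfg$margin)
  cfg$connectivity <- as.integer(cfg$connectivity)
  cfg$seed <- as.integer(cfg$seed)
  cfg$smooth_max_iter <- as.integer(cfg$smooth_max_iter)
  structure(cfg, class = "RunConfig")
}

#' @rdname run_config
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$forbid)) raw$forbid <- lapply(raw$forbid, as.integer)
  if (!is.null(raw$theta_z) && is.null(raw$theta_z)) raw$theta_z <- NA_real_
  do.call(run_config, raw)
}

#' Run the full segmentation pipeline
#'
#' Executes feature extraction, classification, CRF regularization (in
#' overlapping tiles) and optionally per-label surface smoothing on a stack,
#' given sparse training scribbles.
#'
#' @param stack an [image_stack()].
#' @param scribbles a [label_volume()] of training labels (0 = unlabeled).
#' @param config a [run_config()].
#' @param regularize apply the CRF step (`FALSE` returns the argmax
#'   labeling).
#' @param verbose log stage progress and timings to stderr.
#' @return list with elements `labels` (a [label_volume()]), `probmap`,
#'   `model`, `argmax` (pre-regularization labeling), `meshes` (named list
#'   of `TriangleMesh`, one per non-background label, when
#'   `config$smooth`), and `manifest` (stage timings and parameters).
#' @export
run_pipeline <- function(stack, scribbles, config = run_config(),
                         regularize = TRUE, verbose = FALSE) {
  stopifnot(inherits(stack, "ImageStack"), inherits(scribbles, "LabelVolume"),
            inherits(config, "RunConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(config = unclass(config), timings = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
    manifest$timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    say("%s: %.2f s", stage, manifest$timings[[stage]])
    res
  }
  r <- rho(stack)

  feats <- tick("features", extract_features(
    stack, scale_set(config$sigma0, config$n_scales), config$extractor,
    rho_threshold = config$rho_threshold))
  model <- tick("train", train_classifier(
    feats, scribbles, variance_to_retain = config$variance_to_retain,
    seed = config$seed))
  probs <- tick("classify", predict_proba(model, feats))
  amax <- argmax_labeling(probs)

  labels <- if (regularize) {
    tick("regularize", {
      th_z <- if (is.na(config$theta_z)) NULL else config$theta_z
      D <- default_distance_matrix(model$labels,
                                   forbid = config$forbid)
      cc <- crf_config(theta_xy = config$theta_xy, theta_z = th_z, rho = r,
                       distance_matrix = D, tile_shape = config$tile,
                       margin = config$margin)
      regularize_tiled(probs, cc)
    })
  } else amax

  meshes <- NULL
  if (isTRUE(config$smooth)) {
    meshes <- tick("smooth", {
      fg <- setdiff(model$labels, 1L)
      out <- lapply(fg, function(id) {
        smooth_label_surface(labels, id, stack$voxel_size,
                             tol = config$smooth_tol,
                             max_iter = config$smooth_max_iter)
      })
      nm <- names(model$label_table)[match(fg, model$label_table)]
      names(out) <- ifelse(is.na(nm), as.character(fg), nm)
      out
    })
  }
  list(labels = labels, probmap = probs, model = model, argmax = amax,
       meshes = meshes, manifest = manifest)
}

#' Write a machine-readable run manifest
#'
#' @param manifest the `manifest` element of a [run_pipeline()] result.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
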