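test_that("energy construction: unaries, edge split, floor", {
  d <- c(2, 1, 1)
  p <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  pm <- probmap_from_matrix(p, d)
  cfg <- crf_config(theta_xy = 1, theta_z = 1)
  en <- build_energy(pm, cfg)
  expect_equal(en$unary[1, 1], 0)                  # -log 1
  expect_equal(en$unary[2, 1], log(2))             # -log 0.5
  expect_equal(nrow(en$exy), 1L)                   # one in-plane edge
  expect_equal(nrow(en$ez), 0L)
  expect_lte(max(en$unary), -log(1e-12) + 1e-9)    # floored, finite

  # E_XY and E_Z cover the 6-neighborhood disjointly
  d <- c(3, 4, 3)
  en <- build_energy(random_probmap(d), cfg)
  expect_equal(nrow(en$exy), 2 * 4 * 3 + 3 * 3 * 3)
  expect_equal(nrow(en$ez), 3 * 4 * 2)
  keys <- c(paste(en$exy[, 1], en$exy[, 2]), paste(en$ez[, 1], en$ez[, 2]))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("labeling energy matches hand enumeration on the 2-voxel instance", {
  d <- c(2, 1, 1)
  # unaries [[1,3],[4,0]]: posteriors exp(-u)
  u <- matrix(c(1, 3, 4, 0), 2, 2, byrow = TRUE)
  pm <- probmap_from_matrix(exp(-u), d)
  cfg <- crf_config(theta_xy = 2, theta_z = 0,
                    distance_matrix = matrix(c(0, 1, 1, 0), 2))
  en <- build_energy(pm, cfg)
  # the normalization of posteriors shifts unaries by a per-voxel constant
  shift <- log(rowSums(exp(-u)))
  lab_energy <- function(l1, l2) {
    labeling_energy(array(c(l1, l2), dim = d), en, cfg)
  }
  vals <- c(`00` = lab_energy(1, 1), `01` = lab_energy(1, 2),
            `10` = lab_energy(2, 1), `11` = lab_energy(2, 2))
  hand <- c(`00` = 1 + 4, `01` = 1 + 0 + 2, `10` = 3 + 4 + 2, `11` = 3 + 0) +
    sum(shift)
  expect_equal(vals, hand)
  expect_equal(names(which.min(vals)), "01")
  expect_equal(min(vals) - sum(shift), 3)

  # zero thetas: energy is the sum of chosen unaries
  cfg0 <- crf_config(theta_xy = 0, theta_z = 0)
  en0 <- build_energy(pm, cfg0)
  expect_equal(labeling_energy(array(c(1, 2), dim = d), en0, cfg0),
               en0$unary[1, 1] + en0$unary[2, 2])
  # uniform labeling: pairwise contribution zero for any theta
  expect_equal(lab_energy(1, 1) - sum(en$unary[, 1]), 0)
})

test_that("binary graph cut attains the exhaustive global minimum", {
  cfg <- crf_config(theta_xy = 1, theta_z = 0.5)
  set.seed(13)
  d <- c(3, 3, 2)
  pm <- random_probmap(d)
  en <- build_energy(pm, cfg)
  lab <- minimize_binary(en, cfg)
  edges <- rbind(en$exy, en$ez)
  w <- c(rep(cfg$theta_xy, nrow(en$exy)), rep(cfg$theta_z, nrow(en$ez)))
  best <- enumerate_binary_min(en$unary[, 1], en$unary[, 2], edges, w)
  expect_equal(attr(lab, "energy"), best, tolerance = 1e-9)

  # theta = 0 reduces to the argmax labeling
  cfg0 <- crf_config(theta_xy = 0, theta_z = 0)
  en0 <- build_energy(pm, cfg0)
  lab0 <- minimize_binary(en0, cfg0)
  expect_identical(lab0$labels, argmax_labeling(pm)$labels)

  # huge theta: the cheaper uniform labeling wins
  cfgL <- crf_config(theta_xy = 1e4, theta_z = 1e4)
  enL <- build_energy(pm, cfgL)
  labL <- minimize_binary(enL, cfgL)
  expect_equal(length(unique(as.vector(labL$labels))), 1L)
  better <- which.min(c(sum(enL$unary[, 1]), sum(enL$unary[, 2])))
  expect_equal(unique(as.vector(labL$labels)), enL$labels[better])

  # non-submodular distance matrix is rejected
  cfgbad <- crf_config(theta_xy = 1, theta_z = 1,
                       distance_matrix = matrix(c(0, -1, -1, 0), 2))
  enb <- build_energy(pm, cfgbad)
  expect_error(minimize_binary(enb, cfgbad), "submodular")
})

test_that("binary cut is globally optimal over many random instances", {
  set.seed(17)
  for (rep in 1:40) {
    inst <- random_binary_instance()
    x1 <- vemseg:::st_mincut(inst$u0, inst$u1, inst$edges, inst$w)
    e <- binary_cut_energy(x1, inst$u0, inst$u1, inst$edges, inst$w)
    best <- enumerate_binary_min(inst$u0, inst$u1, inst$edges, inst$w)
    expect_equal(e, best, tolerance = 1e-9)
  }
})

test_that("alpha-beta swap equals the exact cut on 2-label instances", {
  set.seed(19)
  for (rep in 1:5) {
    d <- c(4, 3, 2)
    pm <- random_probmap(d)
    cfg <- crf_config(theta_xy = 0.8, theta_z = 0.4)
    en <- build_energy(pm, cfg)
    exact <- minimize_binary(en, cfg)
    swap <- minimize_multilabel(en, cfg)
    expect_equal(attr(swap, "energy"), attr(exact, "energy"),
                 tolerance = 1e-9)
  }
})

test_that("alpha-beta swap decreases energy monotonically and is idempotent", {
  set.seed(23)
  d <- c(5, 5, 2)
  pm <- random_probmap(d, n_labels = 3)
  cfg <- crf_config(theta_xy = 1, theta_z = 0.5)
  en <- build_energy(pm, cfg)
  lab <- minimize_multilabel(en, cfg)
  trace <- attr(lab, "energy_trace")
  expect_true(all(diff(trace) < 0))   # accepted moves strictly decrease
  expect_lte(attr(lab, "energy"), trace[1])
  again <- minimize_multilabel(en, cfg, init = lab)
  expect_identical(again$labels, lab$labels)
  expect_equal(attr(again, "energy"), attr(lab, "energy"))
})

test_that("forbidden label pairs are never adjacent in the minimizer", {
  set.seed(29)
  D <- default_distance_matrix(1:3, forbid = list(c(2L, 3L)))
  cfg <- crf_config(theta_xy = 0.5, theta_z = 0.25, distance_matrix = D)
  for (rep in 1:25) {
    d <- c(4, 4, 2)
    pm <- random_probmap(d, n_labels = 3)
    en <- build_energy(pm, cfg)
    lab <- minimize_multilabel(en, cfg)
    edges <- rbind(en$exy, en$ez)
    y <- as.vector(lab$labels)
    pairs <- cbind(y[edges[, 1]], y[edges[, 2]])
    expect_equal(sum((pairs[, 1] == 2 & pairs[, 2] == 3) |
                       (pairs[, 1] == 3 & pairs[, 2] == 2)), 0L)
  }
})

test_that("tiling with a margin reproduces the untiled result away from cuts", {
  # two blobs well inside their tiles: probability map built directly
  d <- c(48, 24, 8)
  n <- prod(d)
  xyz <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  blob <- function(cx, cy, cz, r) {
    (xyz$x - cx)^2 + (xyz$y - cy)^2 + ((xyz$z - cz) * 2)^2 <= r^2
  }
  inside <- blob(8, 12, 4, 4) | blob(40, 12, 4, 4)   # >= 12 voxels from the cut
  set.seed(31)
  p_fg <- ifelse(inside, 0.9, 0.15) + runif(n, -0.08, 0.08)
  p <- cbind(1 - p_fg, p_fg)
  pm <- probmap_from_matrix(p, d)
  cfg_untiled <- crf_config(theta_xy = 1.5, theta_z = 0.75)
  whole <- regularize(pm, cfg_untiled)
  cfg_tiled <- crf_config(theta_xy = 1.5, theta_z = 0.75,
                          tile_shape = c(24L, 24L, 8L), margin = 10L)
  tiled <- regularize_tiled(pm, cfg_tiled)
  expect_identical(tiled$labels, whole$labels)

  # single tile covering the volume is exactly the untiled minimization
  cfg_one <- crf_config(theta_xy = 1.5, theta_z = 0.75,
                        tile_shape = c(64L, 64L, 16L), margin = 10L)
  one <- regularize_tiled(pm, cfg_one)
  expect_identical(one$labels, whole$labels)
})

test_that("a margin preserves objects straddling the tile cut", {
  # one blob centered on the cut plane between two tiles
  d <- c(40, 20, 6)
  n <- prod(d)
  xyz <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  inside <- (xyz$x - 20)^2 + (xyz$y - 10)^2 + ((xyz$z - 3) * 2)^2 <= 36
  set.seed(37)
  p_fg <- ifelse(inside, 0.88, 0.12) + runif(n, -0.06, 0.06)
  pm <- probmap_from_matrix(cbind(1 - p_fg, p_fg), d)
  cfg <- crf_config(theta_xy = 1.5, theta_z = 0.75,
                    tile_shape = c(20L, 20L, 6L), margin = 10L)
  whole <- regularize(pm, cfg)
  tiled <- regularize_tiled(pm, cfg)
  # the object's connected structure across the cut matches the untiled oracle
  expect_equal(count_components(tiled, 2L, min_size = 0),
               count_components(whole, 2L, min_size = 0))
  expect_identical(tiled$labels, whole$labels)
})

test_that("crf config validates and applies the theta_z rule", {
  expect_equal(crf_config(4, rho = 1.36)$theta_z, 4 / 1.36)
  expect_equal(crf_config(10, rho = 5)$theta_z, 2)
  expect_equal(crf_config(3, theta_z = 7)$theta_z, 7)
  expect_error(crf_config(1), "theta_z or rho")
  expect_error(crf_config(1, theta_z = 1,
                          distance_matrix = matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
})
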