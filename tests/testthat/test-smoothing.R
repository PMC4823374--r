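test_that("constraint fields mark boundaries through the 6-neighborhood", {
  # all background
  lv <- label_volume(array(1L, dim = c(4, 4, 4)))
  cons <- build_constraints(lv, 3L)
  expect_true(all(cons$v == -1))
  expect_true(all(cons$m == 1))

  # single object voxel: margin 0 at the voxel and its 6 neighbors
  lab <- array(1L, dim = c(5, 5, 5))
  lab[3, 3, 3] <- 3L
  cons <- build_constraints(label_volume(lab), 3L)
  expect_equal(cons$v[3, 3, 3], 1)
  zero_at <- which(cons$m == 0)
  idx <- function(x, y, z) x + 5 * (y - 1) + 25 * (z - 1)
  expect_setequal(zero_at, c(idx(3, 3, 3), idx(2, 3, 3), idx(4, 3, 3),
                             idx(3, 2, 3), idx(3, 4, 3), idx(3, 3, 2),
                             idx(3, 3, 4)))

  # half-space: exactly the two layers at the interface have margin 0
  lab <- array(1L, dim = c(8, 4, 4))
  lab[5:8, , ] <- 3L
  cons <- build_constraints(label_volume(lab), 3L)
  expect_true(all(cons$m[c(4, 5), , ] == 0))
  expect_true(all(cons$m[c(1:3, 6:8), , ] == 1))
})

test_that("constant and ramp closed forms reach zero energy", {
  # all-background: f = -1 is feasible with zero energy
  lv <- label_volume(array(1L, dim = c(6, 6, 6)))
  sf <- smooth_field(build_constraints(lv, 3L))
  expect_true(all(sf$f == -1))
  expect_equal(sf$energy, 0)

  # half-space: a unit-slope ramp is feasible with zero energy
  lab <- array(1L, dim = c(9, 7, 5))
  lab[5:9, , ] <- 3L
  cons <- build_constraints(label_volume(lab), 3L)
  ramp <- array(rep((1:9) - 4.5, 7 * 5), dim = c(9, 7, 5))
  expect_true(all(cons$v * ramp >= cons$m))        # feasibility of the ramp
  expect_equal(smoothing_energy(ramp), 0)
  sf <- smooth_field(cons, tol = 1e-7, max_iter = 5000)
  expect_lt(sf$energy, 1e-6)
  expect_true(all(cons$v * sf$f >= cons$m))
})

test_that("output always satisfies the sign constraints exactly", {
  set.seed(41)
  for (rep in 1:5) {
    lab <- array(1L, dim = c(6, 5, 4))
    lab[sample(120, 15)] <- 3L
    cons <- build_constraints(label_volume(lab), 3L, rho = 2)
    sf <- smooth_field(cons, max_iter = 200)
    expect_true(all(cons$v * sf$f >= cons$m))
    expect_lte(sf$energy, smoothing_energy(cons$v, rho = 2))
  }
})

test_that("the projected solver matches a convex-QP oracle", {
  set.seed(43)
  d <- c(5, 5, 3)   # <= 200 unknowns including an anisotropic weighting
  lab <- array(1L, dim = d)
  lab[sample(prod(d), 12)] <- 3L
  cons <- build_constraints(label_volume(lab), 3L, rho = 2)
  sf <- smooth_field(cons, tol = 1e-8, max_iter = 50000)
  v <- as.vector(cons$v)
  m <- as.vector(cons$m)
  # the constraint v_i f_i >= m_i is a per-coordinate box bound
  lower <- ifelse(v > 0, m, -Inf)
  upper <- ifelse(v > 0, Inf, -m)
  fn <- function(f) smoothing_energy(array(f, dim = d), rho = 2)
  oracle <- stats::optim(v, fn, method = "L-BFGS-B", lower = lower,
                         upper = upper,
                         control = list(maxit = 5000, factr = 10))
  expect_equal(sf$energy, oracle$value, tolerance = 1e-4)
})

test_that("surface extraction yields closed, correctly scaled meshes", {
  # one-signed field: empty mesh
  empty <- extract_surface(array(-1, dim = c(4, 4, 4)))
  expect_equal(nrow(empty$vertices), 0L)
  expect_equal(nrow(empty$faces), 0L)

  # solid cube: closed surface with Euler characteristic 2
  f <- array(-1, dim = c(11, 11, 11))
  f[3:9, 3:9, 3:9] <- 1
  mesh <- extract_surface(f, c(1, 1, 1))
  expect_gt(nrow(mesh$faces), 0)
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  euler <- nrow(mesh$vertices) - nrow(edges) + nrow(mesh$faces)
  expect_equal(euler, 2L)
  # every edge borders exactly two faces (watertight)
  edge_use <- table(apply(rbind(mesh$faces[, 1:2], mesh$faces[, 2:3],
                                mesh$faces[, c(3, 1)]), 1,
                          function(e) paste(sort(e), collapse = "-")))
  expect_true(all(edge_use == 2L))

  # Z extent scales with the Z voxel size
  m1 <- extract_surface(f, c(1, 1, 1))
  m5 <- extract_surface(f, c(1, 1, 5))
  z1 <- diff(range(m1$vertices[, 3]))
  z5 <- diff(range(m5$vertices[, 3]))
  expect_equal(z5, 5 * z1)
  expect_equal(diff(range(m1$vertices[, 1])),
               diff(range(m5$vertices[, 1])))
})

test_that("outward orientation points toward the outside of the object", {
  f <- array(-1, dim = c(9, 9, 9))
  f[4:6, 4:6, 4:6] <- 1
  mesh <- extract_surface(f, c(1, 1, 1))
  centroid <- colMeans(mesh$vertices)
  ok <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    a <- mesh$vertices[mesh$faces[i, 1], ]
    b <- mesh$vertices[mesh$faces[i, 2], ]
    cc <- mesh$vertices[mesh$faces[i, 3], ]
    nrm <- c((b[2]-a[2])*(cc[3]-a[3]) - (b[3]-a[3])*(cc[2]-a[2]),
             (b[3]-a[3])*(cc[1]-a[1]) - (b[1]-a[1])*(cc[3]-a[3]),
             (b[1]-a[1])*(cc[2]-a[2]) - (b[2]-a[2])*(cc[1]-a[1]))
    mid <- (a + b + cc) / 3
    if (sum(nrm * (mid - centroid)) > 0) ok <- ok + 1
  }
  expect_equal(ok, nrow(mesh$faces))   # all normals point away from center
})

test_that("smoothing a label never modifies the label volume", {
  set.seed(47)
  lab <- array(1L, dim = c(8, 8, 6))
  lab[3:6, 3:6, 2:4] <- 3L
  lv <- label_volume(lab)
  before <- lv$labels
  mesh <- smooth_label_surface(lv, 3L, c(10, 10, 20), max_iter = 100)
  expect_identical(lv$labels, before)
  expect_gt(nrow(mesh$vertices), 0)
})

test_that("meshes are written as valid PLY and STL files", {
  f <- array(-1, dim = c(6, 6, 6))
  f[3:4, 3:4, 3:4] <- 1
  mesh <- extract_surface(f)
  ply <- tempfile(fileext = ".ply")
  write_ply(mesh, ply, binary = FALSE)
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  expect_true(any(grepl(paste("element vertex", nrow(mesh$vertices)), lines)))
  plyb <- tempfile(fileext = ".ply")
  write_ply(mesh, plyb, binary = TRUE)
  expect_gt(file.size(plyb), 0)
  stl <- tempfile(fileext = ".stl")
  write_stl(mesh, stl)
  expect_equal(sum(grepl("facet normal", readLines(stl))), nrow(mesh$faces))
})
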