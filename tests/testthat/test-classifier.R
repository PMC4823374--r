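make_feature_stack <- function(values, d) {
  vemseg:::feature_stack(values, d, scale_set(1, 1), "F2D")
}

test_that("PCA retains the smallest dimension reaching the variance target", {
  # all variance on one axis
  set.seed(1)
  x <- cbind(rnorm(100), 0)
  expect_equal(fit_pca(x)$k, 1L)
  # exact variance shares via symmetric point pairs on orthogonal axes
  shares <- sqrt(c(0.90, 0.095, 0.005))
  x <- rbind(diag(shares), -diag(shares))
  expect_equal(fit_pca(x, 0.99)$k, 2L)       # 0.995 >= 0.99 at two axes
  # isotropic cloud needs all three axes
  x <- rbind(diag(c(1, 1, 1)), -diag(c(1, 1, 1)))
  expect_equal(fit_pca(x, 0.99)$k, 3L)
  # zero-variance data degrades to a single constant axis
  x <- matrix(1, 10, 3)
  expect_equal(fit_pca(x)$k, 1L)
  # basis columns orthonormal
  set.seed(2)
  p <- fit_pca(matrix(rnorm(600), 100, 6), 0.99)
  expect_equal(unname(crossprod(p$basis)), diag(p$k), tolerance = 1e-10)
})

test_that("training estimates priors as labeled-voxel frequencies", {
  set.seed(3)
  d <- c(8, 5, 1)
  vals <- matrix(rnorm(40 * 3), 40, 3)
  lab <- array(0L, dim = d)
  lab[1:30] <- 1L
  lab[31:40] <- 2L
  fs <- make_feature_stack(vals, d)
  model <- train_classifier(fs, label_volume(lab))
  priors <- vapply(model$classes, `[[`, numeric(1), "prior")
  expect_equal(priors, c(0.75, 0.25))
})

test_that("degenerate constant-feature classes get the regularization floor", {
  d <- c(10, 2, 1)
  v <- c(1.5, -2, 0.5)
  vals <- rbind(matrix(rep(v, each = 10), 10),
                matrix(rnorm(30), 10))
  lab <- array(c(rep(1L, 10), rep(2L, 10)), dim = d)
  model <- train_classifier(make_feature_stack(vals, d), label_volume(lab))
  cl1 <- model$classes[[1]]
  proj_v <- vemseg:::project_pca(model$pca, matrix(v, 1))
  expect_equal(unname(cl1$mu), as.vector(proj_v), tolerance = 1e-10)
  expect_equal(cl1$sigma, diag(1e-6, model$pca$k), tolerance = 1e-12)
})

test_that("labels with fewer than two voxels abort training with the name", {
  d <- c(5, 2, 1)
  vals <- matrix(rnorm(30), 10, 3)
  lab <- array(c(rep(1L, 9), 2L), dim = d)
  expect_error(train_classifier(make_feature_stack(vals, d),
                                label_volume(lab)),
               "fewer than 2.*syn")
})

test_that("parameters are recovered from a two-class Gaussian sample", {
  set.seed(4)
  n <- 1e4
  vals <- matrix(c(rnorm(n, 0, 1), rnorm(n, 10, 1)), ncol = 1)
  d <- c(2 * n, 1, 1)
  lab <- array(rep(c(1L, 2L), each = n), dim = d)
  model <- train_classifier(make_feature_stack(vals, d), label_volume(lab))
  # PCA for 1D data is a sign flip at most
  mu <- vapply(model$classes, function(cl) cl$mu[1], numeric(1))
  sgn <- sign(model$pca$basis[1, 1])
  centered <- (mu * sgn) + model$pca$center
  expect_lt(abs(centered[1] - 0), 0.1)
  expect_lt(abs(centered[2] - 10), 0.1)
  sd1 <- sqrt(model$classes[[1]]$sigma[1, 1])
  expect_lt(abs(sd1 - 1), 0.05)
  expect_equal(vapply(model$classes, `[[`, numeric(1), "prior"),
               c(0.5, 0.5), tolerance = 5e-2)
})

test_that("posteriors are normalized and follow Bayes' rule", {
  set.seed(5)
  n <- 200
  vals <- matrix(rnorm(n * 2), n, 2)
  d <- c(n, 1, 1)
  lab <- array(rep(c(1L, 0L, 2L, 3L), length.out = n), dim = d)
  fs <- make_feature_stack(vals, d)
  model <- train_classifier(fs, label_volume(lab))
  pm <- predict_proba(model, fs)
  sums <- apply(pm, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)

  # two labels with identical conditionals: posterior equals the prior
  model2 <- model
  model2$classes <- model$classes[c(1, 1)]
  model2$classes[[1]]$prior <- 0.9
  model2$classes[[2]]$prior <- 0.1
  model2$classes[[2]]$label <- 2L
  model2$labels <- c(1L, 2L)
  pm2 <- predict_proba(model2, fs)
  expect_equal(max(abs(pm2[, , , 1] - 0.9)), 0, tolerance = 1e-9)
})

test_that("the equidistant point of two unit Gaussians splits 50/50", {
  # 1D model built directly: N(0,1) vs N(10,1), equal priors, x = 5
  mk_class <- function(label, mu) list(label = label, mu = mu,
                                       sigma = matrix(1), chol = chol(matrix(1)),
                                       prior = 0.5)
  model <- structure(list(
    pca = list(center = 0, basis = matrix(1), k = 1L),
    classes = list(mk_class(1L, 0), mk_class(2L, 10)),
    labels = c(1L, 2L),
    label_table = c(bg = 1L, syn = 2L),
    n_channels = 1L, extractor = "F2D", scale_set = scale_set(1, 1)),
    class = "GaussianClassifierModel")
  fs <- make_feature_stack(matrix(5), c(1, 1, 1))
  pm <- predict_proba(model, fs)
  expect_equal(as.vector(pm[1, 1, 1, ]), c(0.5, 0.5), tolerance = 1e-9)
  # no underflow 1000 sigma away from both means
  fs2 <- make_feature_stack(matrix(1000), c(1, 1, 1))
  pm2 <- predict_proba(model, fs2)
  expect_false(anyNA(pm2))
  expect_equal(sum(pm2[1, 1, 1, ]), 1, tolerance = 1e-12)
})

test_that("argmax labeling picks the max posterior with low-id ties", {
  p <- matrix(c(0.2, 0.7, 0.1), 1)
  pm <- probmap_from_matrix(p, c(1, 1, 1), labels = 1:3)
  expect_equal(as.vector(argmax_labeling(pm)$labels), 2L)
  pm <- probmap_from_matrix(matrix(c(0.5, 0.5), 1), c(1, 1, 1), labels = 1:2)
  expect_equal(as.vector(argmax_labeling(pm)$labels), 1L)
  set.seed(6)
  d <- c(8, 8, 2)
  p <- matrix(runif(prod(d) * 3), prod(d), 3)
  pm <- probmap_from_matrix(p, d, labels = 1:3)
  lab <- argmax_labeling(pm)
  oracle <- apply(p / rowSums(p), 1, which.max)
  expect_equal(as.vector(lab$labels), oracle)
})

test_that("channel-count mismatches are rejected", {
  set.seed(7)
  d <- c(10, 1, 1)
  vals <- matrix(rnorm(20), 10, 2)
  lab <- array(rep(1:2, 5), dim = d)
  model <- train_classifier(make_feature_stack(vals, d), label_volume(lab))
  bad <- make_feature_stack(matrix(rnorm(30), 10, 3), d)
  expect_error(predict_proba(model, bad), "channel-count mismatch")
})

test_that("models round-trip through the JSON serialization", {
  set.seed(8)
  d <- c(30, 1, 1)
  vals <- matrix(rnorm(90), 30, 3)
  lab <- array(rep(c(1L, 2L, 3L), 10), dim = d)
  fs <- make_feature_stack(vals, d)
  model <- train_classifier(fs, label_volume(lab))
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$pca$basis, model$pca$basis)
  expect_equal(back$classes, model$classes, tolerance = 1e-12)
  pm1 <- predict_proba(model, fs)
  pm2 <- predict_proba(back, fs)
  expect_equal(as.array(pm1), as.array(pm2), tolerance = 1e-12)
})
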