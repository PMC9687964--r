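test_that("similarity alignment recovers exact transforms", {
  src <- ceph_template(200)
  id <- align_similarity(src, src)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$rotation, 0, tolerance = 1e-12)
  expect_equal(c(id$tx, id$ty), c(0, 0), tolerance = 1e-9)
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  dst <- landmark_set(t(1.5 * R %*% t(unclass(src))) + rep(c(10, -4), each = 26))
  tr <- align_similarity(src, dst)
  expect_equal(tr$scale, 1.5, tolerance = 1e-6)
  expect_equal(tr$rotation, 25, tolerance = 1e-6)
  expect_equal(c(tr$tx, tr$ty), c(10, -4), tolerance = 1e-6)
  expect_error(align_similarity(landmark_set(matrix(1, 26, 2)), dst), "coincide")
})

test_that("similarity alignment matches a linear-model Procrustes oracle", {
  # independent oracle: the similarity is linear in (a, b, tx, ty), so
  # stack x and y equations and solve by least squares with lm()
  set.seed(12)
  src <- unclass(ceph_template(200))
  dst <- src %*% matrix(c(0.9, 0.3, -0.3, 0.9), 2, 2) +
    rep(c(5, 7), each = 26) + matrix(rnorm(52, 0, 2), 26, 2)
  X <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
             cbind(src[, 2], src[, 1], 0, 1))
  beta <- coef(lm(c(dst[, 1], dst[, 2]) ~ X - 1))
  tr <- align_similarity(landmark_set(src), landmark_set(dst))
  expect_equal(unname(c(tr$a, tr$b, tr$tx, tr$ty)), unname(beta),
               tolerance = 1e-9)
})

test_that("shape-indexed features sample anchor + offset at identity placement", {
  set.seed(13)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  ms <- unclass(ceph_template(64))
  C <- matrix(c(ms[, 1], ms[, 2]), 1, 52)
  pool <- list(anchor = sample(1:26, 30, replace = TRUE),
               dx = runif(30, -6, 6), dy = runif(30, -6, 6))
  fv <- cephert:::stage_features(list(img), 1L, C, ms, pool)[1, ]
  oracle <- cephert:::sample_nearest(img, ms[pool$anchor, 1] + pool$dx,
                                     ms[pool$anchor, 2] + pool$dy)
  expect_equal(fv, oracle)
  # constant image: every pixel difference is zero
  flat <- matrix(100, 64, 64)
  fv2 <- cephert:::stage_features(list(flat), 1L, C, ms, pool)[1, ]
  expect_true(all(fv2 == 100))
  # under a similarity of the current shape, sampling follows the shape
  th <- 10 * pi / 180; s <- 1.2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- t(s * R %*% t(ms)) + rep(c(3, -2), each = 26)
  C2 <- matrix(c(moved[, 1], moved[, 2]), 1, 52)
  fv3 <- cephert:::stage_features(list(img), 1L, C2, ms, pool)[1, ]
  off <- t(s * R %*% rbind(pool$dx, pool$dy))
  oracle3 <- cephert:::sample_nearest(img, moved[pool$anchor, 1] + off[, 1],
                                      moved[pool$anchor, 2] + off[, 2])
  expect_equal(fv3, oracle3, tolerance = 1e-9)
})

test_that("an empty cascade and a vanishing learning rate return the mean shape", {
  ds <- small_dataset()[1:8]
  m0 <- ert_train(ds, tiny_control(cascade_depth = 0))
  placed <- cephert:::place_mean_shape(m0, 128, 128)
  p <- predict(m0, ds[[1]])
  expect_equal(unclass(p), placed, tolerance = 1e-12, ignore_attr = TRUE)
  mnu <- ert_train(ds, tiny_control(nu = 1e-12, cascade_depth = 2,
                                    trees_per_stage = 10))
  pn <- predict(mnu, ds[[1]])
  placed_nu <- cephert:::place_mean_shape(mnu, 128, 128)
  expect_equal(unclass(pn), placed_nu, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(ert_train(list(), tiny_control()), "empty")
})

test_that("a single image is overfit to sub-pixel training error", {
  ds <- small_dataset()[1]
  m <- ert_train(ds, ert_control(nu = 0.2, cascade_depth = 10, tree_depth = 2,
                                 oversampling = 1, trees_per_stage = 50,
                                 feature_pool_size = 100, seed = 3))
  pred <- predict(m, ds[[1]])
  err <- mean(sqrt(rowSums((unclass(pred) - unclass(ds[[1]]$landmarks))^2)))
  expect_lte(err, 1)
})

test_that("boosting never increases the training residual", {
  sp <- small_split()
  m <- ert_train(sp$train[1:12], tiny_control())
  expect_true(all(diff(m$history$sse) <= 1e-6))
  expect_true(all(diff(m$history$stage_error) <= 1e-9))
})

test_that("training is deterministic and counts its work", {
  ds <- small_dataset()[1:6]
  ctl <- tiny_control(cascade_depth = 3, trees_per_stage = 15, oversampling = 5)
  m1 <- ert_train(ds, ctl)
  m2 <- ert_train(ds, ctl)
  expect_identical(m1, m2)
  expect_identical(m1$counters$total_trees, 3L * 15L)
  expect_identical(m1$counters$examples_per_stage, 6L * 5L)
  expect_identical(m1$counters$leaves_per_tree, 2L)
  expect_length(m1$stages, 3)
  for (st in m1$stages) {
    expect_length(st$trees, 15)
    for (tr in st$trees) {
      expect_length(tr$a, 1)  # depth-1 tree: one split
      expect_identical(dim(tr$leaves), c(2L, 52L))
      expect_true(all(tr$a != tr$b))
      expect_true(all(tr$a >= 1 & tr$a <= length(st$anchor)))
    }
  }
  p1 <- predict(m1, ds[[2]]); p2 <- predict(m1, ds[[2]])
  expect_identical(p1, p2)
})

test_that("a trained model beats the placed-mean-shape baseline on held-out images", {
  sp <- small_split()
  m <- ert_train(sp$train, tiny_control(cascade_depth = 8))
  err <- evaluate_model(m, sp$test)$mean_error
  expect_lt(err, mean_shape_baseline(m, sp$test))
})

test_that("model JSON round-trips to bit-identical predictions", {
  sp <- small_split()
  m <- ert_train(sp$train[1:8], tiny_control(cascade_depth = 2,
                                             trees_per_stage = 8))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_ert_model(m, path)
  m2 <- load_ert_model(path)
  for (d in sp$test)
    expect_identical(predict(m, d), predict(m2, d))
})

test_that("malformed model files are rejected with clear errors", {
  sp <- small_split()
  m <- ert_train(sp$train[1:4], tiny_control(cascade_depth = 1,
                                             trees_per_stage = 4))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_ert_model(m, path)
  txt <- readChar(path, file.size(path))
  writeChar(substr(txt, 1, nchar(txt) %/% 2), path, eos = NULL)
  expect_error(load_ert_model(path), "parse")
  writeChar(sub('"version":"1.0"', '"version":"9.9"', txt, fixed = TRUE),
            path, eos = NULL)
  expect_error(load_ert_model(path), "version")
  expect_error(load_ert_model(tempfile()), "not found")
})
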