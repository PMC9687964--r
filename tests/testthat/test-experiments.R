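test_that("error reports are self-consistent with their per-image parts", {
  sp <- small_split()
  m <- ert_train(sp$train[1:10], tiny_control())
  rep <- evaluate_model(m, sp$test[1:6])
  expect_identical(rownames(rep$feature_errors), feature_names())
  expect_identical(dim(rep$magnitudes), c(26L, 6L))
  expect_equal(rep$mean_error, mean(rep$magnitudes))
  # oracle recomputation from direct per-image predictions
  le <- landmark_errors(predict(m, sp$test[[1]]), sp$test[[1]]$landmarks)
  expect_equal(rep$magnitudes[, 1], setNames(le$magnitude, le$landmark))
  fe <- feature_errors(predict(m, sp$test[[1]]), sp$test[[1]]$landmarks)
  expect_equal(rep$feature_errors[, 1], fe)
  expect_error(evaluate_model(m, list()), "empty")
})

test_that("an overfit model evaluates to near-zero error on its own image", {
  ds <- small_dataset()[2]
  m <- ert_train(ds, ert_control(nu = 0.2, cascade_depth = 10, tree_depth = 2,
                                 oversampling = 1, trees_per_stage = 50,
                                 feature_pool_size = 100, seed = 5))
  expect_lt(evaluate_model(m, ds)$mean_error, 1)
})

test_that("the parameter sweep emits one row per grid point with work counters", {
  sp <- small_split()
  train <- sp$train[1:10]; test <- sp$test[1:5]
  grid <- list(nu_values = 0.2, cascade_depths = c(1, 3, 6),
               tree_depths = 1, oversampling_values = 4)
  tab <- run_parameter_sweep(train, test, grid,
                             tiny_control(cascade_depth = 4, oversampling = 4,
                                          trees_per_stage = 20))
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$trees_total, tab$cascade_depth * 20L)
  expect_identical(tab$examples_per_stage, rep(10L * 4L, 6))
  expect_identical(tab$leaves_per_tree, rep(2L, 6))
  # training prediction error decreases with cascade depth
  cd <- tab[tab$param == "cascade_depth", ]
  expect_true(all(diff(cd$train_error[order(cd$value)]) <= 1e-9))
  # every run's stage-wise training residual is non-increasing
  for (hseq in attr(tab, "stage_histories"))
    expect_true(all(diff(hseq) <= 1e-9))
  single <- run_parameter_sweep(train, test,
                                list(nu_values = 0.2, cascade_depths = 2,
                                     tree_depths = 1, oversampling_values = 2),
                                tiny_control(cascade_depth = 2,
                                             trees_per_stage = 10))
  expect_identical(nrow(single), 4L)
})

test_that("novelty assessment emits one row per set and condition", {
  sp <- small_split()
  specs <- standard_transform_specs(seed = 3)[c("zoom", "rotate", "elastic")]
  tab <- run_novelty_assessment(sp$train[1:10], sp$test[1:5], specs,
                                tiny_control())
  expect_identical(nrow(tab), 2L * (1L + 3L))
  expect_setequal(unique(tab$set), c("train", "test"))
  expect_setequal(unique(tab$condition),
                  c("untransformed", "zoom", "rotate", "elastic"))
  expect_true(all(is.finite(tab$mean_error)))
  expect_identical(tab$n_images,
                   ifelse(tab$set == "train", 10L, 5L))
})

test_that("the gain curve baseline is shared by both arms at increment zero", {
  sp <- small_split()
  gc <- run_gain_curve(sp$train, sp$test[1:5], base_n = 8,
                       increments = c(0, 6),
                       policy = augmentation_policy(seed = 3),
                       cfg = tiny_control(cascade_depth = 3,
                                          trees_per_stage = 10,
                                          oversampling = 4),
                       replicates = 2)
  expect_identical(nrow(gc), 8L)
  base_rows <- gc[gc$increment == 0, ]
  for (s in unique(base_rows$replicate_seed)) {
    v <- base_rows$mean_test_error[base_rows$replicate_seed == s]
    expect_identical(v[1], v[2])
  }
  expect_identical(gc$train_size, ifelse(gc$increment == 0, 8L, 14L))
  expect_error(run_gain_curve(sp$train[1:5], sp$test, base_n = 8,
                              increments = c(0, 6)),
               "needs")
})

test_that("directionality summaries match the trigonometric-sum oracle", {
  sp <- small_split()
  m <- ert_train(sp$train[1:8], tiny_control(cascade_depth = 2,
                                             trees_per_stage = 10))
  rep <- evaluate_model(m, sp$test)
  ds <- summarize_directionality(rep)
  expect_identical(ds$landmark, cephalometric_landmarks())
  expect_true(all(ds$resultant_length >= 0 & ds$resultant_length <= 1,
                  na.rm = TRUE))
  th <- rep$directions["S", ] * pi / 180
  expect_equal(ds$resultant_length[1],
               sqrt(mean(cos(th))^2 + mean(sin(th))^2), tolerance = 1e-12)
  expect_equal(ds$mean_direction[1],
               (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360,
               tolerance = 1e-12)
  # synthetic circular laws on a hand-built report
  fake <- rep
  fake$directions[] <- NA
  fake$directions["S", ] <- 90
  set.seed(3)
  fake$directions["P", ] <- runif(ncol(fake$directions), 0, 360)
  fs <- summarize_directionality(fake)
  expect_equal(fs$resultant_length[fs$landmark == "S"], 1, tolerance = 1e-12)
  expect_equal(fs$mean_direction[fs$landmark == "S"], 90, tolerance = 1e-9)
  expect_lt(fs$resultant_length[fs$landmark == "P"], 0.5)
  expect_identical(fs$n[fs$landmark == "Go"], 0L)
  expect_true(is.na(fs$mean_direction[fs$landmark == "Go"]))
})
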