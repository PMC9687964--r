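# Shared fixtures, generated lazily once per test run. The small fixtures
# use a 128 px frame with jitters scaled to it (half the 256 px defaults);
# the study-scale fixture uses the generator defaults.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(value)
  .fixtures[[key]]
}

small_config <- function(n = 24, seed = 301) {
  synth_config(n_images = n, image_size = 128, seed = seed,
               placement_jitter = 7.5, scale_jitter = 0.05,
               rotation_jitter = 3, shape_jitter = 1.5,
               blur_sigma = 1, noise_sd = 8, margin = 8)
}

small_dataset <- function() {
  memo("small", synth_cephalograms(small_config()))
}

small_split <- function() {
  memo("small_split", split_dataset(small_dataset(), 0.75, seed = 9))
}

# Quick-training control for unit tests (seconds, not minutes).
tiny_control <- function(...) {
  args <- list(nu = 0.2, cascade_depth = 6, tree_depth = 1, oversampling = 8,
               trees_per_stage = 40, feature_pool_size = 150,
               candidate_splits_per_node = 20, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(ert_control, args)
}

# Study-conditions fixture: 200 default-configuration cephalograms,
# split 150 train / 50 test. Used by the scaled-down analogs of the
# quantitative claims.
study_dataset <- function() {
  memo("study", synth_cephalograms(synth_config(n_images = 200, seed = 1103)))
}

study_split <- function() {
  memo("study_split", split_dataset(study_dataset(), 0.75, seed = 17))
}

study_model <- function() {
  memo("study_model",
       ert_train(study_split()$train,
                 ert_control(nu = 0.2, cascade_depth = 10, tree_depth = 1,
                             oversampling = 20, trees_per_stage = 50,
                             seed = 23)))
}

# Mean landmark error of predicting the placed mean shape (zero-training
# baseline), computed directly.
mean_shape_baseline <- function(model, ds) {
  placed <- unclass(coef(model))
  mean(vapply(ds, function(d)
    mean(sqrt(rowSums((placed - unclass(d$landmarks))^2))), numeric(1)))
}
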