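#' Evaluate a model on an annotated dataset
#'
#' Predicts every image and assembles per-landmark error magnitudes and
#' directions, per-feature signed angular errors, and the grand mean
#' error in pixels (averaged over all 26 landmarks over all images).
#'
#' @param model An `ert_model`.
#' @param ds Non-empty list of [ceph_image()]s.
#' @return A `ceph_error_report`: list with `magnitudes` and `directions`
#'   (26 x n matrices, landmarks in rows), `feature_errors` (7 x n
#'   matrix, signed degrees), `mean_error` (pixels) and `ids`.
#' @export
evaluate_model <- function(model, ds) {
  if (!length(ds)) stop("cannot evaluate on an empty dataset")
  n <- length(ds)
  mags <- matrix(NA_real_, 26, n, dimnames = list(cephalometric_landmarks(), NULL))
  dirs <- mags
  ferr <- matrix(NA_real_, 7, n, dimnames = list(feature_names(), NULL))
  for (i in seq_len(n)) {
    pred <- predict(model, ds[[i]])
    le <- landmark_errors(pred, ds[[i]]$landmarks)
    mags[, i] <- le$magnitude
    dirs[, i] <- le$direction
    ferr[, i] <- feature_errors(pred, ds[[i]]$landmarks)
  }
  structure(list(magnitudes = mags, directions = dirs,
                 feature_errors = ferr, mean_error = mean(mags),
                 ids = vapply(ds, `[[`, character(1), "id")),
            class = "ceph_error_report")
}

#' @export
print.ceph_error_report <- function(x, ...) {
  cat(sprintf("Error report over %d images\n", ncol(x$magnitudes)))
  cat(sprintf("  mean landmark error: %.3f px\n", x$mean_error))
  cat("  per-feature error s.d. (degrees):\n")
  print(round(apply(x$feature_errors, 1, stats::sd), 3))
  invisible(x)
}

modify_control <- function(base, param, value) {
  args <- unclass(base)
  args$feature_locality_lambda <- base$feature_locality_lambda
  args[[param]] <- value
  do.call(ert_control, args)
}

#' One-dimensional parameter sweep
#'
#' Varies one learning parameter at a time around `base_cfg` (matching
#' per-parameter sweep panels rather than a full factorial design),
#' training one model per grid point and recording training error, test
#' error and the work counters that training cost is proportional to
#' (trees = T x K, examples per stage = n x R, leaves per tree = 2^F).
#'
#' @param train,test Non-empty lists of [ceph_image()]s.
#' @param grid List with elements `nu_values`, `cascade_depths`,
#'   `tree_depths`, `oversampling_values` (all non-empty).
#' @param base_cfg An [ert_control()].
#' @return Data frame with one row per grid point; attribute
#'   `stage_histories` holds each run's per-stage training error for
#'   monotonicity checks.
#' @export
run_parameter_sweep <- function(train, test, grid, base_cfg = ert_control()) {
  stopifnot(length(train) > 0, length(test) > 0)
  axes <- c(nu_values = "nu", cascade_depths = "cascade_depth",
            tree_depths = "tree_depth", oversampling_values = "oversampling")
  if (!all(names(axes) %in% names(grid)) ||
      any(!vapply(grid[names(axes)], length, integer(1))))
    stop("grid needs non-empty nu_values, cascade_depths, tree_depths, oversampling_values")
  rows <- list(); hist <- list()
  for (ax in names(axes)) {
    for (v in grid[[ax]]) {
      cfg <- modify_control(base_cfg, axes[[ax]], v)
      model <- ert_train(train, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        param = axes[[ax]], value = v, nu = cfg$nu,
        cascade_depth = cfg$cascade_depth, tree_depth = cfg$tree_depth,
        oversampling = cfg$oversampling,
        train_error = evaluate_model(model, train)$mean_error,
        test_error = evaluate_model(model, test)$mean_error,
        trees_total = model$counters$total_trees,
        examples_per_stage = model$counters$examples_per_stage,
        leaves_per_tree = model$counters$leaves_per_tree,
        stringsAsFactors = FALSE)
      hist[[length(hist) + 1L]] <- model$history$stage_error
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stage_histories") <- hist
  out
}

#' Transform-novelty assessment
#'
#' Trains a single model on the untransformed training set, then measures
#' its mean error on: the untransformed training images, each transform
#' of the training images, the untransformed test images, and each
#' transform of the test images. A transform is "novel" to the extent
#' that the model's error on transformed training images approaches (or
#' exceeds) its error on genuinely unseen images; the elastic transform
#' typically stands far above every affine transform.
#'
#' @param train,test Non-empty lists of [ceph_image()]s.
#' @param specs List of [transform_spec()]s (default: the standard
#'   battery at reference magnitudes).
#' @param cfg An [ert_control()].
#' @return Data frame with `2 * (1 + length(specs))` rows: columns `set`,
#'   `condition`, `mean_error`, `n_images`, `n_flagged`.
#' @export
run_novelty_assessment <- function(train, test,
                                   specs = standard_transform_specs(),
                                   cfg = ert_control()) {
  stopifnot(length(train) > 0, length(test) > 0)
  model <- ert_train(train, cfg)
  one <- function(set_name, ds) {
    transform_all <- function(sp) {
      lapply(seq_along(ds), function(i) {
        if (sp$kind == "elastic")  # fresh elastic realization per image
          sp$seed <- derive_seed(sp$seed, i)
        apply_transform(ds[[i]], sp)
      })
    }
    conds <- c(list(untransformed = ds),
               stats::setNames(lapply(specs, transform_all), names(specs)))
    do.call(rbind, lapply(names(conds), function(nm) {
      dset <- conds[[nm]]
      data.frame(set = set_name, condition = nm,
                 mean_error = evaluate_model(model, dset)$mean_error,
                 n_images = length(dset),
                 n_flagged = sum(vapply(dset, `[[`, logical(1), "flagged")),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one("train", train), one("test", test))
}

#' Augmentation gain curve
#'
#' Starting from `base_n` untransformed images, grows the training set by
#' each increment in two arms — adding unseen original images from the
#' pool, or adding randomly transformed copies of the same `base_n`
#' images — training and evaluating each point, repeated over replicate
#' seeds. With increment 0 both arms coincide with the baseline model.
#'
#' @param pool List of [ceph_image()]s; must hold at least
#'   `base_n + max(increments)` images for the originals arm.
#' @param test Held-out evaluation set.
#' @param base_n Baseline training-set size.
#' @param increments Integer vector of added-image counts (may include 0).
#' @param policy An [augmentation_policy()] for the augmented arm.
#' @param cfg An [ert_control()].
#' @param replicates Number of replicate seeds (averaging makes the
#'   stochastic arms assertable).
#' @return Data frame with columns `train_size`, `increment`, `source`
#'   (`original` / `augmented`), `mean_test_error`, `replicate_seed`.
#' @export
run_gain_curve <- function(pool, test, base_n = 50,
                           increments = c(0, 50, 100),
                           policy = augmentation_policy(),
                           cfg = ert_control(), replicates = 3) {
  need <- base_n + max(increments)
  if (length(pool) < need)
    stop(sprintf("pool has %d images; the originals arm needs %d",
                 length(pool), need))
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    rseed <- derive_seed(cfg$seed, 101, rep_i)
    perm <- local_seed(rseed, sample.int(length(pool)))
    base <- pool[perm[seq_len(base_n)]]
    extra <- pool[perm[base_n + seq_len(max(increments))]]
    for (m in increments) {
      rcfg <- modify_control(cfg, "seed", derive_seed(rseed, m))
      if (m == 0) {
        err <- evaluate_model(ert_train(base, rcfg), test)$mean_error
        for (src in c("original", "augmented"))
          rows[[length(rows) + 1L]] <- data.frame(
            train_size = as.integer(base_n), increment = 0L, source = src,
            mean_test_error = err, replicate_seed = rseed)
        next
      }
      err_o <- evaluate_model(
        ert_train(c(base, extra[seq_len(m)]), rcfg), test)$mean_error
      pol <- policy
      pol$copies_per_image <- as.integer(ceiling(m / base_n))
      pol$seed <- derive_seed(rseed, m, 7)
      aug_all <- augment_dataset(base, pol)
      copies <- aug_all[-seq_len(base_n)][seq_len(m)]
      err_a <- evaluate_model(
        ert_train(c(base, copies), rcfg), test)$mean_error
      rows[[length(rows) + 1L]] <- data.frame(
        train_size = as.integer(base_n + m), increment = as.integer(m),
        source = "original", mean_test_error = err_o, replicate_seed = rseed)
      rows[[length(rows) + 1L]] <- data.frame(
        train_size = as.integer(base_n + m), increment = as.integer(m),
        source = "augmented", mean_test_error = err_a, replicate_seed = rseed)
    }
  }
  do.call(rbind, rows)
}

#' Circular statistics of error directionality
#'
#' Per landmark: circular mean direction and mean resultant length
#' `Rbar` in \[0, 1\] of the prediction-error directions, excluding
#' zero-magnitude errors (whose direction is undefined). `Rbar` near 0
#' indicates errors spread symmetrically in all directions; `Rbar` of 1,
#' a fixed directional bias.
#'
#' @param report A `ceph_error_report` from [evaluate_model()].
#' @return Data frame with columns `landmark`, `n`, `mean_direction`
#'   (degrees in \[0, 360), `NA` when undefined) and `resultant_length`.
#' @export
summarize_directionality <- function(report) {
  stopifnot(inherits(report, "ceph_error_report"))
  out <- lapply(rownames(report$directions), function(lm) {
    th <- report$directions[lm, ]
    th <- th[!is.na(th)] * pi / 180
    if (!length(th))
      return(data.frame(landmark = lm, n = 0L, mean_direction = NA_real_,
                        resultant_length = NA_real_))
    cs <- mean(cos(th)); sn <- mean(sin(th))
    data.frame(landmark = lm, n = length(th),
               mean_direction = (atan2(sn, cs) * 180 / pi) %% 360,
               resultant_length = sqrt(cs^2 + sn^2))
  })
  do.call(rbind, out)
}
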