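#' Training configuration for the cascaded tree ensemble
#'
#' The four parameters the method is usually tuned by are `nu` (shrinkage
#' weight given to each new tree), `cascade_depth` (number of successive
#' boosted ensembles, each re-indexing its features against the current
#' shape estimate), `tree_depth` (depth of each binary regression tree,
#' giving `2^tree_depth` leaves) and `oversampling` (number of training
#' examples generated per image, each with a different initial shape).
#' The remaining knobs control the shape-indexed feature machinery:
#' `trees_per_stage` boosted trees per cascade stage, `feature_pool_size`
#' sampled pixel locations per stage, `candidate_splits_per_node` random
#' split proposals per tree node, and `feature_locality_lambda`, the scale
#' (pixels) of the exponential prior `exp(-d / lambda)` favouring nearby
#' pixel pairs as split features (default 0.1 x image width, resolved at
#' training time).
#'
#' @param nu Shrinkage in (0, 1].
#' @param cascade_depth Number of cascade stages (>= 0).
#' @param tree_depth Depth of each regression tree (>= 0).
#' @param oversampling Initial shapes per training image (>= 1).
#' @param trees_per_stage Trees per cascade stage.
#' @param feature_pool_size Pixel locations sampled per stage.
#' @param candidate_splits_per_node Random split proposals per node.
#' @param feature_locality_lambda Pixels; `NULL` for 0.1 x image width.
#' @param seed Integer seed; training is deterministic given it.
#' @return An `ert_control` list.
#' @export
ert_control <- function(nu = 0.2, cascade_depth = 10, tree_depth = 1,
                        oversampling = 20, trees_per_stage = 500,
                        feature_pool_size = 400,
                        candidate_splits_per_node = 20,
                        feature_locality_lambda = NULL, seed = 1) {
  if (!(nu > 0 && nu <= 1)) stop("nu must be in (0, 1]")
  if (cascade_depth < 0) stop("cascade_depth must be >= 0")
  if (tree_depth < 0) stop("tree_depth must be >= 0")
  if (oversampling < 1) stop("oversampling must be >= 1")
  if (trees_per_stage < 1 || feature_pool_size < 2 ||
      candidate_splits_per_node < 1)
    stop("trees_per_stage, feature_pool_size and candidate_splits_per_node must be positive")
  structure(list(nu = nu, cascade_depth = as.integer(cascade_depth),
                 tree_depth = as.integer(tree_depth),
                 oversampling = as.integer(oversampling),
                 trees_per_stage = as.integer(trees_per_stage),
                 feature_pool_size = as.integer(feature_pool_size),
                 candidate_splits_per_node = as.integer(candidate_splits_per_node),
                 feature_locality_lambda = feature_locality_lambda,
                 seed = as.integer(seed)),
            class = "ert_control")
}

#' Least-squares similarity alignment of two landmark sets
#'
#' Closed-form Procrustes fit of the similarity transform (uniform scale,
#' rotation, translation) minimizing the sum of squared distances from the
#' transformed `src` to `dst`. The transform maps `p` to
#' `[a, -b; b, a] p + (tx, ty)`.
#'
#' @param src,dst [landmark_set()]s (or plain 26 x 2 matrices).
#' @return List with `a`, `b`, `tx`, `ty`, and the derived `scale` and
#'   `rotation` (degrees).
#' @export
align_similarity <- function(src, dst) {
  s <- unclass(src); d <- unclass(dst)
  ms <- colMeans(s); md <- colMeans(d)
  sc <- sweep(s, 2, ms); dc <- sweep(d, 2, md)
  den <- sum(sc^2)
  if (den == 0) stop("cannot align: all source points coincide")
  a <- sum(sc[, 1] * dc[, 1] + sc[, 2] * dc[, 2]) / den
  b <- sum(sc[, 1] * dc[, 2] - sc[, 2] * dc[, 1]) / den
  list(a = a, b = b,
       tx = unname(md[1] - (a * ms[1] - b * ms[2])),
       ty = unname(md[2] - (b * ms[1] + a * ms[2])),
       scale = sqrt(a^2 + b^2), rotation = atan2(b, a) * 180 / pi)
}

# --- internal shape algebra ----------------------------------------------
# Shapes are rows of an n x 52 matrix, columns [x1..x26, y1..y26].

shape_to_row <- function(ls) c(unclass(ls)[, 1], unclass(ls)[, 2])
row_to_shape <- function(v) landmark_set(matrix(v, 26, 2))

# Vectorized Procrustes linear part aligning the (fixed) mean shape to
# each row of C. Returns list of per-row a, b.
align_linear_to_rows <- function(mean_shape, C) {
  x0 <- mean_shape[, 1] - mean(mean_shape[, 1])
  y0 <- mean_shape[, 2] - mean(mean_shape[, 2])
  den <- sum(x0^2 + y0^2)
  Cx <- C[, 1:26, drop = FALSE]; Cy <- C[, 27:52, drop = FALSE]
  Cx <- Cx - rowMeans(Cx); Cy <- Cy - rowMeans(Cy)
  list(a = as.numeric(Cx %*% x0 + Cy %*% y0) / den,
       b = as.numeric(Cy %*% x0 - Cx %*% y0) / den)
}

# Mean shape: two rounds of align-to-reference averaging (generalized
# Procrustes, fixed at the scale of the data).
mean_shape_of <- function(shape_rows) {
  ref <- matrix(shape_rows[1, ], 26, 2)
  for (pass in 1:2) {
    acc <- matrix(0, 26, 2)
    for (i in seq_len(nrow(shape_rows))) {
      s <- matrix(shape_rows[i, ], 26, 2)
      tr <- align_similarity(s, ref)
      A <- matrix(c(tr$a, tr$b, -tr$b, tr$a), 2, 2)
      acc <- acc + t(A %*% t(s)) + rep(c(tr$tx, tr$ty), each = 26)
    }
    ref <- acc / nrow(shape_rows)
  }
  ref
}

# Place the model's mean shape into an image frame by scaling from the
# reference size (whole-image framing; no detector box exists for
# cephalograms).
place_mean_shape <- function(model, h, w) {
  ms <- model$mean_shape
  sx <- (w - 1) / (model$ref_size[2] - 1)
  sy <- (h - 1) / (model$ref_size[1] - 1)
  cbind(ms[, 1] * sx, ms[, 2] * sy)
}

# Stage feature extraction for all examples (rows of C): map each pool
# offset through the similarity linear part, add the anchor's current
# position, and read nearest-pixel intensities (out of bounds -> 0).
stage_features <- function(images, image_of, C, mean_shape, pool) {
  al <- align_linear_to_rows(mean_shape, C)
  X <- C[, pool$anchor, drop = FALSE] +
    outer(al$a, pool$dx) - outer(al$b, pool$dy)
  Y <- C[, pool$anchor + 26L, drop = FALSE] +
    outer(al$b, pool$dx) + outer(al$a, pool$dy)
  Fv <- matrix(0, nrow(C), length(pool$anchor))
  for (i in unique(image_of)) {
    rows <- which(image_of == i)
    Fv[rows, ] <- sample_nearest(images[[i]], X[rows, ], Y[rows, ])
  }
  Fv
}

# Sample a stage's feature-point pool uniformly over the mean-shape
# bounding box (padded 15%), anchored to the nearest landmark.
sample_pool <- function(mean_shape, size) {
  rx <- range(mean_shape[, 1]); ry <- range(mean_shape[, 2])
  px <- stats::runif(size, rx[1] - 0.15 * diff(rx), rx[2] + 0.15 * diff(rx))
  py <- stats::runif(size, ry[1] - 0.15 * diff(ry), ry[2] + 0.15 * diff(ry))
  anchor <- integer(size)
  for (k in seq_len(size))
    anchor[k] <- which.min((mean_shape[, 1] - px[k])^2 + (mean_shape[, 2] - py[k])^2)
  list(anchor = anchor, dx = px - mean_shape[anchor, 1],
       dy = py - mean_shape[anchor, 2], x = px, y = py)
}

# Draw split candidates: pixel pairs accepted with probability
# exp(-d / lambda) (rejection sampling, uniform fallback), thresholds
# uniform in +/- 80 intensity units.
sample_split_candidates <- function(pool, n_cand, lambda) {
  P <- length(pool$x)
  got_a <- integer(0); got_b <- integer(0)
  for (batch in 1:8) {
    i <- sample.int(P, 8 * n_cand, replace = TRUE)
    j <- sample.int(P, 8 * n_cand, replace = TRUE)
    ok <- i != j
    d <- sqrt((pool$x[i] - pool$x[j])^2 + (pool$y[i] - pool$y[j])^2)
    acc <- ok & stats::runif(length(i)) < exp(-d / lambda)
    got_a <- c(got_a, i[acc]); got_b <- c(got_b, j[acc])
    if (length(got_a) >= n_cand) break
  }
  short <- n_cand - length(got_a)
  if (short > 0) {  # pathological lambda; fall back to uniform pairs
    i <- sample.int(P, short, replace = TRUE)
    j <- ((i + sample.int(P - 1, short, replace = TRUE)) %% P) + 1L
    got_a <- c(got_a, i); got_b <- c(got_b, j)
  }
  list(a = got_a[seq_len(n_cand)], b = got_b[seq_len(n_cand)],
       thr = stats::runif(n_cand, -80, 80))
}

# Fit one complete binary regression tree of depth F by greedy
# sum-of-squares reduction. Returns split arrays (length 2^F - 1),
# a 2^F x 52 leaf matrix of mean residuals, and per-example leaf index.
fit_tree <- function(Fv, Rm, pool, depth, n_cand, lambda) {
  n <- nrow(Rm)
  n_internal <- 2L^depth - 1L
  sa <- integer(n_internal); sb <- integer(n_internal); st <- numeric(n_internal)
  node_of <- rep(1L, n)
  if (depth > 0) {
    for (m in seq_len(n_internal)) {
      cand <- sample_split_candidates(pool, n_cand, lambda)
      idx <- which(node_of == m)
      best <- 1L; best_gain <- -Inf
      if (length(idx) > 1) {
        Rsub <- Rm[idx, , drop = FALSE]
        Stot <- colSums(Rsub); ntot <- length(idx)
        base <- sum(Stot^2) / ntot
        for (cc in seq_len(n_cand)) {
          f <- Fv[idx, cand$a[cc]] - Fv[idx, cand$b[cc]]
          left <- f < cand$thr[cc]
          nl <- sum(left)
          if (nl == 0 || nl == ntot) next
          SL <- crossprod(left, Rsub)
          gain <- sum(SL^2) / nl + sum((Stot - SL)^2) / (ntot - nl) - base
          if (gain > best_gain + 1e-12) { best_gain <- gain; best <- cc }
        }
      }
      sa[m] <- cand$a[best]; sb[m] <- cand$b[best]; st[m] <- cand$thr[best]
      if (length(idx)) {
        f <- Fv[idx, sa[m]] - Fv[idx, sb[m]]
        node_of[idx] <- 2L * m + as.integer(f >= st[m])
      }
    }
    leaf_of <- node_of - n_internal
  } else {
    leaf_of <- rep(1L, n)
  }
  n_leaves <- 2L^depth
  leaves <- matrix(0, n_leaves, 52)
  for (l in seq_len(n_leaves)) {
    rows <- which(leaf_of == l)
    if (length(rows)) leaves[l, ] <- colMeans(Rm[rows, , drop = FALSE])
  }
  list(a = sa, b = sb, thr = st, leaves = leaves, leaf_of = leaf_of)
}

# Vectorized leaf lookup for one example's feature vector.
tree_leaf_index <- function(tree, fv, depth) {
  if (depth == 0) return(1L)
  node <- 1L
  while (node <= length(tree$a)) {
    f <- fv[tree$a[node]] - fv[tree$b[node]]
    node <- 2L * node + as.integer(f >= tree$thr[node])
  }
  node - length(tree$a)
}

#' Fit a cascaded ensemble of regression trees for landmark localization
#'
#' Trains the cascaded shape regressor: the mean shape is the similarity-
#' normalized average of the training shapes; each training image yields
#' `oversampling` examples with distinct initial shapes (the placed mean
#' shape, then ground-truth shapes of other randomly chosen training
#' images); each of the `cascade_depth` stages samples a fresh pool of
#' shape-indexed pixel locations and fits `trees_per_stage` regression
#' trees by greedy gradient boosting under a sum-of-squares loss. Each
#' node picks, among random pixel-difference split proposals drawn with an
#' exponential locality prior, the one minimizing the summed squared
#' residual; leaf values are mean residuals of the examples reaching the
#' leaf, added with weight `nu`. Residuals therefore never increase during
#' a stage, and the whole fit is deterministic given `config$seed`.
#'
#' @param data List of [ceph_image()] training images (non-empty).
#' @param config An [ert_control()].
#' @return An object of class `ert_model`; see [predict.ert_model()].
#' @export
ert_train <- function(data, config = ert_control()) {
  if (!length(data)) stop("cannot train on an empty training set")
  stopifnot(inherits(config, "ert_control"))
  n_img <- length(data)
  images <- lapply(data, `[[`, "image")
  shape_rows <- t(vapply(data, function(d) shape_to_row(d$landmarks),
                         numeric(52)))
  sizes <- vapply(data, function(d) dim(d$image), integer(2))
  ref_size <- sizes[, 1]
  lambda <- config$feature_locality_lambda
  if (is.null(lambda)) lambda <- 0.1 * ref_size[2]

  mean_shape <- mean_shape_of(shape_rows)
  R <- config$oversampling
  n_ex <- n_img * R
  image_of <- rep(seq_len(n_img), each = R)

  model <- structure(list(
    format = "cephert-ert-model", version = "1.0",
    config = config, ref_size = as.integer(ref_size),
    lambda = lambda, mean_shape = mean_shape, stages = list(),
    history = list(stage_error = numeric(0), sse = numeric(0)),
    counters = list(total_trees = config$cascade_depth * config$trees_per_stage,
                    leaves_per_tree = as.integer(2^config$tree_depth),
                    examples_per_stage = as.integer(n_ex))), class = "ert_model")

  local_seed(derive_seed(config$seed, 11), {
    # initial shapes: replicate 1 = placed mean shape, others = ground
    # truths of other images (rescaled if sizes differ)
    C <- matrix(0, n_ex, 52)
    Tr <- matrix(0, n_ex, 52)
    for (i in seq_len(n_img)) {
      rows <- (i - 1L) * R + seq_len(R)
      h <- sizes[1, i]; w <- sizes[2, i]
      placed <- cbind(mean_shape[, 1] * (w - 1) / (ref_size[2] - 1),
                      mean_shape[, 2] * (h - 1) / (ref_size[1] - 1))
      C[rows[1], ] <- c(placed[, 1], placed[, 2])
      if (R > 1) {
        others <- if (n_img > 1) setdiff(seq_len(n_img), i) else i
        pick <- others[sample.int(length(others), R - 1, replace = TRUE)]
        for (r in 2:R) {
          s <- shape_rows[pick[r - 1L], ]
          C[rows[r], ] <- c(s[1:26] * (w - 1) / (sizes[2, pick[r - 1L]] - 1),
                            s[27:52] * (h - 1) / (sizes[1, pick[r - 1L]] - 1))
        }
      }
      Tr[rows, ] <- matrix(shape_rows[i, ], R, 52, byrow = TRUE)
    }

    for (t in seq_len(config$cascade_depth)) {
      pool <- sample_pool(mean_shape, config$feature_pool_size)
      Fv <- stage_features(images, image_of, C, mean_shape, pool)
      Rm <- Tr - C
      trees <- vector("list", config$trees_per_stage)
      for (k in seq_len(config$trees_per_stage)) {
        tr <- fit_tree(Fv, Rm, pool, config$tree_depth,
                       config$candidate_splits_per_node, lambda)
        upd <- config$nu * tr$leaves[tr$leaf_of, , drop = FALSE]
        C <- C + upd
        Rm <- Rm - upd
        tr$leaf_of <- NULL
        trees[[k]] <- tr
        model$history$sse <- c(model$history$sse, sum(Rm^2))
      }
      model$stages[[t]] <- list(anchor = pool$anchor, dx = pool$dx,
                                dy = pool$dy, trees = trees)
      D <- Tr - C
      model$history$stage_error <-
        c(model$history$stage_error,
          mean(sqrt(D[, 1:26]^2 + D[, 27:52]^2)))
    }
    model$fitted_rows <- C[seq(1, n_ex, by = R), , drop = FALSE]
    model$truth_rows <- shape_rows
  })
  model
}

#' Predict landmark positions on new images
#'
#' Initializes with the mean shape scaled into the full image frame, then
#' applies every cascade stage: features are re-indexed against the
#' current estimate through a similarity alignment to the mean shape, and
#' each tree's leaf vector is added with weight `nu`.
#'
#' @param object An `ert_model`.
#' @param newdata A [ceph_image()], a list of them, or a numeric image
#'   matrix.
#' @param ... Unused.
#' @return A [landmark_set()] (or a list of them for list input).
#' @export
predict.ert_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "ceph_image"))
    return(lapply(newdata, function(d) predict.ert_model(object, d)))
  img <- if (inherits(newdata, "ceph_image")) newdata$image else newdata
  if (!is.matrix(img) || nrow(img) < 2 || ncol(img) < 2)
    stop("image must be a numeric matrix of at least 2 x 2 pixels")
  placed <- place_mean_shape(object, nrow(img), ncol(img))
  C <- matrix(c(placed[, 1], placed[, 2]), 1, 52)
  nu <- object$config$nu
  for (stage in object$stages) {
    pool <- list(anchor = stage$anchor, dx = stage$dx, dy = stage$dy)
    fv <- stage_features(list(img), 1L, C, object$mean_shape, pool)[1, ]
    for (tr in stage$trees) {
      l <- tree_leaf_index(tr, fv, object$config$tree_depth)
      C <- C + nu * tr$leaves[l, , drop = FALSE]
    }
  }
  row_to_shape(C[1, ])
}

#' @export
print.ert_model <- function(x, ...) {
  cfg <- x$config
  cat("Cascaded ensemble-of-regression-trees landmark model\n")
  cat(sprintf("  stages: %d x %d trees (depth %d, %d leaves), nu = %g\n",
              cfg$cascade_depth, cfg$trees_per_stage, cfg$tree_depth,
              x$counters$leaves_per_tree, cfg$nu))
  cat(sprintf("  trained on %d examples (pool %d, lambda %.1f px)\n",
              x$counters$examples_per_stage, cfg$feature_pool_size, x$lambda))
  if (length(x$history$stage_error))
    cat(sprintf("  final training error: %.3f px/landmark\n",
                utils::tail(x$history$stage_error, 1)))
  invisible(x)
}

#' @export
summary.ert_model <- function(object, ...) {
  structure(list(config = object$config, counters = object$counters,
                 stage_error = object$history$stage_error),
            class = "summary.ert_model")
}

#' @export
print.summary.ert_model <- function(x, ...) {
  cat("Cascade training summary\n")
  cat(sprintf("  total trees: %d; leaves per tree: %d; examples per stage: %d\n",
              x$counters$total_trees, x$counters$leaves_per_tree,
              x$counters$examples_per_stage))
  if (length(x$stage_error)) {
    cat("  mean training error (px/landmark) by stage:\n")
    print(round(x$stage_error, 4))
  }
  invisible(x)
}

#' @export
plot.ert_model <- function(x, ...) {
  if (!length(x$history$stage_error))
    stop("model has no cascade stages to plot")
  graphics::plot(seq_along(x$history$stage_error), x$history$stage_error,
                 type = "b", xlab = "cascade stage",
                 ylab = "mean training error (px/landmark)",
                 main = "Training error across the cascade", ...)
  invisible(x)
}

#' @export
coef.ert_model <- function(object, ...) {
  landmark_set(object$mean_shape)
}

#' @export
fitted.ert_model <- function(object, ...) {
  lapply(seq_len(nrow(object$fitted_rows)),
         function(i) row_to_shape(object$fitted_rows[i, ]))
}

#' @export
residuals.ert_model <- function(object, ...) {
  D <- object$truth_rows - object$fitted_rows
  sqrt(D[, 1:26]^2 + D[, 27:52]^2)
}
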