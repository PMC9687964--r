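#' Specify one landmark-consistent image transform
#'
#' Six transform kinds are supported, matching the augmentation battery:
#' `zoom` (uniform scale about the image centre), `h_shift` (shift along
#' the height axis, i.e. vertically), `w_shift` (shift along the width
#' axis), `shear` (horizontal shear about the centre: x displaced in
#' proportion to y), `rotate` (about the centre), and `elastic` (random
#' affine with corner displacements up to `alpha_affine` pixels, composed
#' with a Gaussian-smoothed random displacement field of smoothness
#' `sigma` pixels scaled by `alpha`). Only the parameters meaningful for
#' the chosen kind are used. The reference magnitudes used in the
#' novelty assessment are 10\% zoom, 50 px shifts, 10 degree shear and
#' rotation, and elastic alpha = 100, sigma = 5, alpha_affine = 50.
#'
#' @param kind One of `"zoom"`, `"h_shift"`, `"w_shift"`, `"shear"`,
#'   `"rotate"`, `"elastic"`.
#' @param zoom_fraction Scale factor is `1 + zoom_fraction`.
#' @param shift_pixels Translation for the shift kinds.
#' @param shear_degrees,rotate_degrees Angles in degrees.
#' @param elastic_alpha Displacement field scale (pixels).
#' @param elastic_sigma Field smoothness (pixels, > 0).
#' @param elastic_alpha_affine Max corner displacement of the random
#'   affine (pixels).
#' @param seed Seed for the elastic randomness.
#' @return A `transform_spec` list.
#' @export
transform_spec <- function(kind, zoom_fraction = 0.10, shift_pixels = 50,
                           shear_degrees = 10, rotate_degrees = 10,
                           elastic_alpha = 100, elastic_sigma = 5,
                           elastic_alpha_affine = 50, seed = 1) {
  kind <- match.arg(kind, c("zoom", "h_shift", "w_shift", "shear",
                            "rotate", "elastic"))
  if (kind == "elastic" && elastic_sigma <= 0)
    stop("elastic_sigma must be > 0")
  structure(list(kind = kind, zoom_fraction = zoom_fraction,
                 shift_pixels = shift_pixels, shear_degrees = shear_degrees,
                 rotate_degrees = rotate_degrees,
                 elastic_alpha = elastic_alpha, elastic_sigma = elastic_sigma,
                 elastic_alpha_affine = elastic_alpha_affine,
                 seed = as.integer(seed)),
            class = "transform_spec")
}

#' The standard transform battery at reference magnitudes
#'
#' @param seed Seed used by the elastic member.
#' @return Named list of six [transform_spec()]s: zoom 10\%, height and
#'   width shifts of 50 px, shear 10 degrees, rotation 10 degrees, and
#'   elastic (alpha 100, sigma 5, alpha_affine 50).
#' @export
standard_transform_specs <- function(seed = 1) {
  list(zoom = transform_spec("zoom", zoom_fraction = 0.10),
       h_shift = transform_spec("h_shift", shift_pixels = 50),
       w_shift = transform_spec("w_shift", shift_pixels = 50),
       shear = transform_spec("shear", shear_degrees = 10),
       rotate = transform_spec("rotate", rotate_degrees = 10),
       elastic = transform_spec("elastic", seed = seed))
}

# 2x3 affine matrix (rows: x', y') for a spec, about the image centre
# (0-based pixel coordinates).
affine_matrix <- function(spec, h, w) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  lin <- diag(2); tr <- c(0, 0)
  if (spec$kind == "zoom") {
    lin <- diag(2) * (1 + spec$zoom_fraction)
  } else if (spec$kind == "h_shift") {
    tr <- c(0, spec$shift_pixels)
  } else if (spec$kind == "w_shift") {
    tr <- c(spec$shift_pixels, 0)
  } else if (spec$kind == "shear") {
    lin <- matrix(c(1, 0, tan(spec$shear_degrees * pi / 180), 1), 2, 2)
  } else if (spec$kind == "rotate") {
    th <- spec$rotate_degrees * pi / 180
    lin <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  } else stop("no affine matrix for kind ", spec$kind)
  centre <- c(cx, cy)
  cbind(lin, centre - lin %*% centre + tr)
}

apply_matrix_to_points <- function(M, pts) {
  sweep(unclass(pts) %*% t(M[, 1:2]), 2, M[, 3], `+`)
}

flag_out_of_bounds <- function(pts, h, w) {
  any(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)
}

#' Apply an affine transform to an annotated image
#'
#' The image is warped by backward mapping with bilinear interpolation
#' and constant zero fill; landmarks are mapped through the same matrix
#' exactly (no interpolation error on coordinates). Output dimensions are
#' unchanged. Landmarks leaving the frame are flagged on the result, not
#' clipped.
#'
#' @param img A [ceph_image()].
#' @param spec A non-elastic [transform_spec()].
#' @return A [ceph_image()] with a provenance-suffixed id.
#' @export
apply_affine <- function(img, spec) {
  stopifnot(inherits(img, "ceph_image"), inherits(spec, "transform_spec"))
  if (spec$kind == "elastic") stop("use apply_elastic() for elastic specs")
  h <- nrow(img$image); w <- ncol(img$image)
  M <- affine_matrix(spec, h, w)
  Minv <- cbind(solve(M[, 1:2]), -solve(M[, 1:2]) %*% M[, 3])
  out <- warp_image(img$image, function(xs, ys) {
    list(x = Minv[1, 1] * xs + Minv[1, 2] * ys + Minv[1, 3],
         y = Minv[2, 1] * xs + Minv[2, 2] * ys + Minv[2, 3])
  })
  pts <- apply_matrix_to_points(M, img$landmarks)
  ceph_image(round(clip8(out)), landmark_set(pts),
             paste0(img$id, "_", transform_label(spec)),
             flagged = flag_out_of_bounds(pts, h, w))
}

#' Apply an elastic transform to an annotated image
#'
#' Draws a random affine whose three control-corner displacements are
#' uniform in `+/- alpha_affine`, and per-pixel uniform `[-1, 1]`
#' displacement fields smoothed with a Gaussian of s.d. `sigma` and
#' scaled by `alpha`. The image is warped by the composed backward map;
#' each landmark is mapped through the forward affine and then displaced
#' by the (negated) field evaluated at its position — an approximation to
#' the exact warp inverse whose error is of the order of the field
#' gradient, small at the reference smoothness. Deterministic given
#' `spec$seed`.
#'
#' @param img A [ceph_image()].
#' @param spec An elastic [transform_spec()].
#' @return A [ceph_image()].
#' @export
apply_elastic <- function(img, spec) {
  stopifnot(inherits(img, "ceph_image"), inherits(spec, "transform_spec"))
  if (spec$kind != "elastic") stop("apply_elastic() needs an elastic spec")
  h <- nrow(img$image); w <- ncol(img$image)
  local_seed(spec$seed, {
    # random affine from three displaced control corners
    third <- min(h, w) / 3
    ctr <- c((w - 1) / 2, (h - 1) / 2)
    src <- rbind(ctr + c(-third, -third), ctr + c(third, -third),
                 ctr + c(-third, third))
    dst <- src + matrix(stats::runif(6, -spec$elastic_alpha_affine,
                                     spec$elastic_alpha_affine), 3, 2)
    # solve [x y 1] beta = dst for the forward affine
    A <- cbind(src, 1)
    beta <- solve(A, dst)            # 3 x 2; forward map p' = t(beta) %*% (x,y,1)
    M <- t(beta)                     # 2 x 3
    if (spec$elastic_alpha > 0) {
      dx <- blur_image(matrix(stats::runif(h * w, -1, 1), h, w),
                       spec$elastic_sigma) * spec$elastic_alpha
      dy <- blur_image(matrix(stats::runif(h * w, -1, 1), h, w),
                       spec$elastic_sigma) * spec$elastic_alpha
    } else {
      dx <- matrix(0, h, w); dy <- matrix(0, h, w)
    }
    Minv <- cbind(solve(M[, 1:2]), -solve(M[, 1:2]) %*% M[, 3])
    out <- warp_image(img$image, function(xs, ys) {
      # backward: displace sample position by the field, then un-affine
      sx <- xs + sample_bilinear(dx, xs, ys)
      sy <- ys + sample_bilinear(dy, xs, ys)
      list(x = Minv[1, 1] * sx + Minv[1, 2] * sy + Minv[1, 3],
           y = Minv[2, 1] * sx + Minv[2, 2] * sy + Minv[2, 3])
    })
    p1 <- apply_matrix_to_points(M, img$landmarks)
    pts <- cbind(p1[, 1] - sample_bilinear(dx, p1[, 1], p1[, 2]),
                 p1[, 2] - sample_bilinear(dy, p1[, 1], p1[, 2]))
    ceph_image(round(clip8(out)), landmark_set(pts),
               paste0(img$id, "_", transform_label(spec)),
               flagged = flag_out_of_bounds(pts, h, w))
  })
}

#' Apply any transform spec
#'
#' Dispatches to [apply_affine()] or [apply_elastic()] on `spec$kind`.
#' @inheritParams apply_affine
#' @export
apply_transform <- function(img, spec) {
  if (spec$kind == "elastic") apply_elastic(img, spec) else apply_affine(img, spec)
}

transform_label <- function(spec) {
  switch(spec$kind,
         zoom = sprintf("zoom%+.3g", spec$zoom_fraction),
         h_shift = sprintf("hshift%+.4g", spec$shift_pixels),
         w_shift = sprintf("wshift%+.4g", spec$shift_pixels),
         shear = sprintf("shear%+.3g", spec$shear_degrees),
         rotate = sprintf("rot%+.3g", spec$rotate_degrees),
         elastic = sprintf("elastic_a%g_s%g_aa%g_seed%d", spec$elastic_alpha,
                           spec$elastic_sigma, spec$elastic_alpha_affine,
                           spec$seed))
}

#' Random-augmentation policy
#'
#' For each source image, `copies_per_image` transforms are drawn: the
#' kind uniformly from `kinds`, and its parameter uniformly from the
#' symmetric range (`+/- zoom_range`, `+/- shift_range`, `+/-
#' shear_range`, `+/- rotate_range`). The gain-curve experiments use
#' ranges of 20\%, 70 px and 15 degrees. Elastic members use the
#' reference elastic parameters with per-copy seeds.
#'
#' @param kinds Subset of the transform kinds.
#' @param zoom_range,shift_range,shear_range,rotate_range Symmetric
#'   sampling half-ranges (>= 0).
#' @param copies_per_image Number of transformed copies per source image.
#' @param seed Policy seed; the augmented dataset is deterministic in it.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(kinds = c("zoom", "h_shift", "w_shift",
                                          "shear", "rotate"),
                                zoom_range = 0.20, shift_range = 70,
                                shear_range = 15, rotate_range = 15,
                                copies_per_image = 1, seed = 1) {
  if (!length(kinds)) stop("policy needs at least one transform kind")
  kinds <- vapply(kinds, function(k)
    match.arg(k, c("zoom", "h_shift", "w_shift", "shear", "rotate",
                   "elastic")), character(1))
  if (copies_per_image < 1) stop("copies_per_image must be >= 1")
  if (any(c(zoom_range, shift_range, shear_range, rotate_range) < 0))
    stop("ranges must be >= 0")
  structure(list(kinds = unname(kinds), zoom_range = zoom_range,
                 shift_range = shift_range, shear_range = shear_range,
                 rotate_range = rotate_range,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

#' Augment a dataset with randomly drawn transforms
#'
#' Returns the original images followed by `copies_per_image` transformed
#' copies of each, with transform provenance recorded in the copy ids.
#' Copies whose landmarks leave the frame are kept and flagged (content
#' loss at large shifts is part of what augmentation introduces), never
#' silently clipped.
#'
#' @param ds Non-empty list of [ceph_image()]s.
#' @param policy An [augmentation_policy()].
#' @return List of length `length(ds) * (1 + copies_per_image)`.
#' @export
augment_dataset <- function(ds, policy) {
  if (!length(ds)) stop("cannot augment an empty dataset")
  stopifnot(inherits(policy, "augmentation_policy"))
  copies <- list()
  for (i in seq_along(ds)) {
    for (cpy in seq_len(policy$copies_per_image)) {
      sp <- local_seed(derive_seed(policy$seed, i, cpy), {
        kind <- policy$kinds[sample.int(length(policy$kinds), 1)]
        switch(kind,
          zoom = transform_spec("zoom",
            zoom_fraction = stats::runif(1, -policy$zoom_range, policy$zoom_range)),
          h_shift = transform_spec("h_shift",
            shift_pixels = stats::runif(1, -policy$shift_range, policy$shift_range)),
          w_shift = transform_spec("w_shift",
            shift_pixels = stats::runif(1, -policy$shift_range, policy$shift_range)),
          shear = transform_spec("shear",
            shear_degrees = stats::runif(1, -policy$shear_range, policy$shear_range)),
          rotate = transform_spec("rotate",
            rotate_degrees = stats::runif(1, -policy$rotate_range, policy$rotate_range)),
          elastic = transform_spec("elastic",
            seed = derive_seed(policy$seed, i, cpy, 13)))
      })
      copies[[length(copies) + 1L]] <- apply_transform(ds[[i]], sp)
    }
  }
  c(ds, copies)
}
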