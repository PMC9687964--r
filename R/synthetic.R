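#' Canonical landmark template for the synthetic generator
#'
#' A fixed 26-point configuration laid out like a lateral cephalogram in
#' standard orientation (profile facing image right): posterior cranial
#' structures (S, P, Co, Go) on the left, the facial profile and
#' soft-tissue points on the right, Menton most inferior. The coordinates
#' are implementation constants chosen so that the seven angular features
#' are finite and fall in clinically plausible ranges (ANB small and
#' positive); they are not measurements from any radiograph.
#'
#' @param image_size Side length in pixels of the square target image
#'   (minimum 64); the unit-square template is scaled to it.
#' @return A [landmark_set()] in 0-based pixel coordinates.
#' @export
ceph_template <- function(image_size = 256) {
  if (image_size < 64) stop("image_size must be at least 64")
  u <- matrix(c(
    0.42, 0.30,  # S
    0.28, 0.38,  # P
    0.33, 0.72,  # Go
    0.72, 0.28,  # N
    0.62, 0.40,  # O
    0.73, 0.56,  # A
    0.72, 0.72,  # B
    0.70, 0.85,  # Me
    0.76, 0.22,  # G
    0.82, 0.55,  # Sn
    0.84, 0.62,  # Ls
    0.83, 0.68,  # Li
    0.79, 0.80,  # PgS
    0.74, 0.58,  # Ur
    0.76, 0.66,  # Uc
    0.74, 0.67,  # Lc
    0.71, 0.74,  # Lr
    0.78, 0.52,  # ANS
    0.55, 0.53,  # PNS
    0.64, 0.64,  # U6M
    0.61, 0.63,  # U6D
    0.63, 0.67,  # L6M
    0.60, 0.68,  # L6D
    0.52, 0.24,  # SEM
    0.88, 0.47,  # Pn
    0.30, 0.42   # Co
  ), ncol = 2, byrow = TRUE)
  landmark_set(u * (image_size - 1))
}

# Soft-tissue point -> skeletal counterpart, used by the anatomy checks.
soft_tissue_counterparts <- function() {
  c(G = "N", Pn = "ANS", Sn = "A", Ls = "Uc", Li = "Lc", PgS = "B")
}

#' Synthetic cephalogram generator configuration
#'
#' Defaults emulate a study-scale dataset of lateral cephalograms with
#' realistic inter-radiograph variability: head framing varies between
#' acquisitions by a few percent of the frame (translation, scale,
#' rotation), individual anatomy varies smoothly (correlated per-landmark
#' deformation), and films carry blur and noise.
#'
#' @param n_images Number of images (default 362, the study scale).
#' @param image_size Square image side, pixels (>= 64).
#' @param seed Integer master seed; the dataset is a pure function of the
#'   configuration.
#' @param placement_jitter S.d. (pixels) of the global translation of the
#'   template in each axis.
#' @param scale_jitter S.d. (fraction) of the global scale factor.
#' @param rotation_jitter S.d. (degrees) of the global rotation.
#' @param shape_jitter S.d. (pixels) of the correlated per-landmark
#'   deformation; offsets are smoothed across neighbouring landmarks so
#'   nearby points move coherently.
#' @param blur_sigma Gaussian blur s.d., pixels.
#' @param noise_sd Additive Gaussian noise s.d., 8-bit intensity units.
#' @param margin Minimum distance (pixels) of every landmark from the
#'   image border; placements violating it are redrawn (bounded retries).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_images = 362, image_size = 256, seed = 1,
                         placement_jitter = 15, scale_jitter = 0.05,
                         rotation_jitter = 3, shape_jitter = 3,
                         blur_sigma = 1.2, noise_sd = 8, margin = 12) {
  if (n_images < 0) stop("n_images must be >= 0")
  if (image_size < 64) stop("image_size must be at least 64")
  jit <- c(placement_jitter, scale_jitter, rotation_jitter, shape_jitter,
           blur_sigma, noise_sd)
  if (any(jit < 0)) stop("jitter, blur and noise parameters must be >= 0")
  if (margin < 0) stop("margin must be >= 0")
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 placement_jitter = placement_jitter,
                 scale_jitter = scale_jitter, rotation_jitter = rotation_jitter,
                 shape_jitter = shape_jitter, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, margin = margin),
            class = "synth_config")
}

#' Annotated image container
#'
#' @param image Numeric matrix, intensities in \[0, 255\] (rows = y).
#' @param landmarks A [landmark_set()].
#' @param id Character identifier.
#' @param flagged `TRUE` when some landmark lies outside the image bounds
#'   (possible after aggressive augmentation); never silently clipped.
#' @return A `ceph_image` list.
#' @export
ceph_image <- function(image, landmarks, id, flagged = FALSE) {
  stopifnot(is.matrix(image), is.character(id))
  stopifnot_landmarks(landmarks)
  structure(list(image = image, landmarks = landmarks, id = id,
                 flagged = isTRUE(flagged)),
            class = "ceph_image")
}

#' @export
print.ceph_image <- function(x, ...) {
  cat(sprintf("<ceph_image %s: %dx%d px, 26 landmarks%s>\n", x$id,
              nrow(x$image), ncol(x$image),
              if (x$flagged) ", FLAGGED out-of-bounds" else ""))
  invisible(x)
}

#' Render a cephalogram-like image from landmarks
#'
#' Draws smooth curves through anatomically grouped landmark subsets —
#' cranial base (S, SEM, N, G), mandibular border (Co, Go, Me, B), maxilla
#' (PNS, A, ANS), incisor axes (Ur-Uc, Lr-Lc), molar cusp marks, the
#' soft-tissue profile (G, Pn, Sn, Ls, Li, PgS) and rings at Sella,
#' Porion and Orbitale — over a background intensity gradient, then
#' applies Gaussian blur and additive Gaussian noise, clipped to the
#' 8-bit range and rounded to whole intensity levels. Every landmark sits
#' on rendered structure, so local image evidence exists at each point.
#'
#' @param landmarks A [landmark_set()]; must lie within the image.
#' @param cfg A [synth_config()] (supplies image size, blur and noise).
#' @param noise_seed Integer seed for the noise draw.
#' @return Numeric matrix `image_size x image_size` with integer values in
#'   \[0, 255\].
#' @export
render_cephalogram <- function(landmarks, cfg, noise_seed = 0L) {
  stopifnot_landmarks(landmarks)
  n <- cfg$image_size
  if (any(landmarks < 0) || any(landmarks > n - 1))
    stop("landmarks out of image bounds; cannot render")
  sc <- n / 256  # stroke widths tuned at 256 px
  xu <- matrix(0:(n - 1), n, n, byrow = TRUE) / (n - 1)
  yu <- matrix(0:(n - 1), n, n) / (n - 1)
  img <- 35 + 45 * xu + 15 * yu
  p <- function(nm) landmarks[nm, ]
  poly <- function(nms) landmarks[nms, , drop = FALSE]
  img <- draw_curve(img, poly(c("S", "SEM", "N", "G")), 1.3 * sc, 205)
  img <- draw_curve(img, poly(c("Co", "Go", "Me", "B")), 1.5 * sc, 220)
  img <- draw_curve(img, poly(c("PNS", "A", "ANS")), 1.1 * sc, 210)
  img <- draw_segment(img, p("Ur"), p("Uc"), 1.0 * sc, 235)
  img <- draw_segment(img, p("Lr"), p("Lc"), 1.0 * sc, 235)
  for (m in c("U6M", "U6D", "L6M", "L6D")) {
    q <- p(m)
    img <- draw_segment(img, q - c(2.5 * sc, 0), q + c(2.5 * sc, 0), 0.9 * sc, 215)
    img <- draw_segment(img, q - c(0, 2.5 * sc), q + c(0, 2.5 * sc), 0.9 * sc, 215)
  }
  img <- draw_curve(img, poly(c("G", "Pn", "Sn", "Ls", "Li", "PgS")), 1.2 * sc, 185)
  img <- draw_ring(img, p("S"), 3.5 * sc, 1.0 * sc, 200)
  img <- draw_ring(img, p("P"), 4.0 * sc, 1.0 * sc, 195)
  img <- draw_ring(img, p("O"), 5.0 * sc, 1.0 * sc, 195)
  img <- blur_image(img, cfg$blur_sigma)
  if (cfg$noise_sd > 0) {
    noise <- local_seed(noise_seed,
                        matrix(stats::rnorm(n * n, 0, cfg$noise_sd), n, n))
    img <- img + noise
  }
  round(clip8(img))
}

# Draw one subject's landmark placement: global similarity jitter of the
# template plus smoothed per-landmark deformation. Pure function of seed.
place_landmarks <- function(template, cfg, seed) {
  local_seed(seed, {
    n <- cfg$image_size
    ctr <- c((n - 1) / 2, (n - 1) / 2)
    th <- stats::rnorm(1, 0, cfg$rotation_jitter) * pi / 180
    s <- max(0.5, 1 + stats::rnorm(1, 0, cfg$scale_jitter))
    tr <- stats::rnorm(2, 0, cfg$placement_jitter)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    pts <- t(s * R %*% t(sweep(unclass(template), 2, ctr))) +
      rep(ctr + tr, each = 26)
    if (cfg$shape_jitter > 0) {
      d <- as.matrix(stats::dist(unclass(template)))
      rho <- 0.15 * n
      W <- exp(-d^2 / (2 * rho^2))
      W <- W / rowSums(W)
      raw <- matrix(stats::rnorm(52), 26, 2)
      sm <- W %*% raw
      # restore unit variance per landmark, then scale to shape_jitter
      sm <- sm / sqrt(rowSums(W^2))
      pts <- pts + cfg$shape_jitter * sm
    }
    landmark_set(pts)
  })
}

#' Generate a synthetic annotated dataset
#'
#' For each image, draws a global similarity placement of the template
#' (translation, scale and rotation jitters) plus a spatially coherent
#' per-landmark deformation, renders the image, and pairs it with its
#' exact landmark annotations. Placements whose landmarks violate the
#' border margin are redrawn up to 100 times, then an error is raised.
#' The whole dataset is a deterministic function of `cfg`.
#'
#' @param cfg A [synth_config()].
#' @return List of [ceph_image()] objects (length `cfg$n_images`).
#' @export
#' @examples
#' ds <- synth_cephalograms(synth_config(n_images = 2, image_size = 64,
#'                                       margin = 4, seed = 7))
#' ds[[1]]
synth_cephalograms <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  template <- ceph_template(cfg$image_size)
  lo <- cfg$margin; hi <- cfg$image_size - 1 - cfg$margin
  lapply(seq_len(cfg$n_images), function(i) {
    lm <- NULL
    for (try in 0:100) {
      cand <- place_landmarks(template, cfg, derive_seed(cfg$seed, i, try))
      if (all(cand >= lo) && all(cand <= hi)) { lm <- cand; break }
    }
    if (is.null(lm))
      stop(sprintf("image %d: could not satisfy margin %g after 100 retries; ",
                   i, cfg$margin),
           "reduce jitters or the margin")
    img <- render_cephalogram(lm, cfg, derive_seed(cfg$seed, i, 7919))
    ceph_image(img, lm, sprintf("synth%04d", i))
  })
}

#' Shuffle-split a dataset into training and test sets
#'
#' Shuffles with the given seed and takes the first
#' `floor(train_fraction * n)` items for training; the partition is
#' disjoint and exhaustive. At the study scale (362 images, 70/30) this
#' yields 253 training and 109 test images.
#'
#' @param ds List of [ceph_image()] objects.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer shuffle seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1) {
  n <- length(ds)
  if (n == 0) stop("cannot split an empty dataset")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be strictly between 0 and 1")
  perm <- local_seed(seed, sample.int(n))
  k <- floor(train_fraction * n)
  list(train = ds[perm[seq_len(k)]],
       test = ds[perm[setdiff(seq_len(n), seq_len(k))]])
}
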