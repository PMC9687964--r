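# Internal raster utilities. Images are plain numeric matrices with values
# in [0, 255], rows = y (downward), cols = x (rightward). A landmark at
# 0-based position (x, y) sits at img[y + 1, x + 1].

# Run code with a private RNG stream, restoring the caller's state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic seed derivation; keeps results in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  h <- 0
  for (v in ix) h <- (h * 69069 + (as.numeric(v) %% 2147483647) * 2654435761) %% 2147483629
  as.integer(h %% 2147483646) + 1L
}

# One-dimensional truncated Gaussian convolution matrix (n x n), rows
# renormalized so borders keep their mean level.
conv_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  m <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n) + j
    ok <- idx >= 1L & idx <= n
    m[cbind(which(ok), idx[ok])] <- m[cbind(which(ok), idx[ok])] + k[j + r + 1L]
  }
  m / rowSums(m)
}

# Separable Gaussian blur; sigma in pixels, sigma = 0 is the identity.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  cy <- conv_matrix(nrow(img), sigma)
  cx <- conv_matrix(ncol(img), sigma)
  cy %*% img %*% t(cx)
}

# Nearest-pixel sampling at 0-based positions; out of bounds reads 0.
sample_nearest <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  ix <- round(xs); iy <- round(ys)
  ok <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
  idx <- ix * h + iy + 1  # linear column-major index
  idx[!ok] <- 1
  v <- img[idx]
  v[!ok] <- 0
  v
}

# Bilinear sampling at 0-based positions; out of bounds reads 0.
sample_bilinear <- function(img, xs, ys) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  pick <- function(ix, iy) {
    ok <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    idx <- ix * h + iy + 1
    idx[!ok] <- 1
    v <- img[idx]
    v[!ok] <- 0
    v
  }
  (1 - fx) * (1 - fy) * pick(x0, y0) +
    fx * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy * pick(x0, y0 + 1) +
    fx * fy * pick(x0 + 1, y0 + 1)
}

# Warp an image through a backward map: out(x, y) = in(map(x, y)).
# `map` takes 0-based x/y vectors and returns list(x=, y=).
warp_image <- function(img, map) {
  h <- nrow(img); w <- ncol(img)
  g <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  src <- map(g$x, g$y)
  matrix(sample_bilinear(img, src$x, src$y), nrow = h, ncol = w, byrow = TRUE)
}

clip8 <- function(img) pmin(pmax(img, 0), 255)

# --- drawing primitives (max blending keeps overlaps uniform) ------------

stamp_max <- function(img, rows, cols, values) {
  idx <- cbind(rows, cols)
  img[idx] <- pmax(img[idx], values)
  img
}

# Soft stroke from p0 to p1 with Gaussian cross-profile of width w pixels.
draw_segment <- function(img, p0, p1, width = 1.2, intensity = 200) {
  h <- nrow(img); wd <- ncol(img)
  r <- ceiling(3 * width) + 1
  x0 <- max(0, floor(min(p0[1], p1[1]) - r)); x1 <- min(wd - 1, ceiling(max(p0[1], p1[1]) + r))
  y0 <- max(0, floor(min(p0[2], p1[2]) - r)); y1 <- min(h - 1, ceiling(max(p0[2], p1[2]) + r))
  if (x0 > x1 || y0 > y1) return(img)
  gx <- x0:x1; gy <- y0:y1
  px <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  py <- matrix(gy, length(gy), length(gx))
  d <- p1 - p0
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist2 <- (px - p0[1])^2 + (py - p0[2])^2
  } else {
    t <- ((px - p0[1]) * d[1] + (py - p0[2]) * d[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist2 <- (px - (p0[1] + t * d[1]))^2 + (py - (p0[2] + t * d[2]))^2
  }
  val <- intensity * exp(-dist2 / (2 * width^2))
  stamp_max(img, as.vector(py) + 1, as.vector(px) + 1, as.vector(val))
}

# Smooth open curve through control points (natural parametric spline),
# rasterized as dense short segments.
draw_curve <- function(img, pts, width = 1.2, intensity = 200) {
  n <- nrow(pts)
  if (n >= 3) {
    s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    tt <- seq(0, s[n], length.out = max(8L, ceiling(s[n])))
    xs <- stats::spline(s, pts[, 1], xout = tt)$y
    ys <- stats::spline(s, pts[, 2], xout = tt)$y
  } else {
    xs <- pts[, 1]; ys <- pts[, 2]
  }
  for (i in seq_len(length(xs) - 1))
    img <- draw_segment(img, c(xs[i], ys[i]), c(xs[i + 1], ys[i + 1]), width, intensity)
  img
}

draw_ring <- function(img, centre, radius, width = 1.0, intensity = 190) {
  h <- nrow(img); wd <- ncol(img)
  r <- ceiling(radius + 3 * width) + 1
  x0 <- max(0, floor(centre[1] - r)); x1 <- min(wd - 1, ceiling(centre[1] + r))
  y0 <- max(0, floor(centre[2] - r)); y1 <- min(h - 1, ceiling(centre[2] + r))
  if (x0 > x1 || y0 > y1) return(img)
  gx <- x0:x1; gy <- y0:y1
  px <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  py <- matrix(gy, length(gy), length(gx))
  d <- sqrt((px - centre[1])^2 + (py - centre[2])^2) - radius
  val <- intensity * exp(-d^2 / (2 * width^2))
  stamp_max(img, as.vector(py) + 1, as.vector(px) + 1, as.vector(val))
}
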