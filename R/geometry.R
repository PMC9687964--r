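#' Unsigned angle at a vertex
#'
#' Angle in degrees, in \[0, 180\], between the rays `v -> a` and `v -> b`.
#' This is the construction behind SNA (angle at Nasion between rays to
#' Sella and to A point), SNB, and the soft-tissue convexity G-Sn-Pg'.
#' Angles are invariant under translation, rotation and uniform scaling of
#' the point configuration, so the image coordinate frame (y pointing down)
#' does not affect them.
#'
#' @param a,v,b Numeric length-2 vectors `c(x, y)` (pixels); `v` is the
#'   vertex.
#' @return Angle in degrees.
#' @export
#' @examples
#' angle_at_vertex(c(1, 0), c(0, 0), c(0, 1)) # 90
angle_at_vertex <- function(a, v, b) {
  u <- as.numeric(a) - as.numeric(v)
  w <- as.numeric(b) - as.numeric(v)
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0)
    stop("degenerate angle: ray endpoint coincides with the vertex")
  # atan2 of cross/dot is numerically stable near 0 and 180 degrees
  cr <- u[1] * w[2] - u[2] * w[1]
  dt <- sum(u * w)
  atan2(abs(cr), dt) * 180 / pi
}

#' Unsigned angle between two directed lines
#'
#' Angle in degrees, in \[0, 180\], between the direction vectors
#' `p_to - p_from` and `q_to - q_from`. Used for the incisor inclinations
#' (incisor axis vs the sella-nasion line or the mandibular plane) and the
#' mandibular plane angle S-N/Go-Me. Direction conventions are fixed by the
#' caller: incisor axes run root to crown, SN runs S to N, the mandibular
#' plane runs Go to Me.
#'
#' @param p_from,p_to First directed segment endpoints, `c(x, y)`.
#' @param q_from,q_to Second directed segment endpoints.
#' @return Angle in degrees.
#' @export
line_angle <- function(p_from, p_to, q_from, q_to) {
  u <- as.numeric(p_to) - as.numeric(p_from)
  w <- as.numeric(q_to) - as.numeric(q_from)
  if (all(u == 0) || all(w == 0))
    stop("degenerate line: zero-length segment")
  cr <- u[1] * w[2] - u[2] * w[1]
  dt <- sum(u * w)
  atan2(abs(cr), dt) * 180 / pi
}

#' Compute the seven angular diagnostic features
#'
#' From a full landmark set, computes:
#' \describe{
#'   \item{sna}{angle at N between rays to S and to A (maxilla vs cranial base)}
#'   \item{snb}{angle at N between rays to S and to B (mandible vs cranial base)}
#'   \item{anb}{`sna - snb`, signed; the sagittal maxillo-mandibular discrepancy}
#'   \item{uc_ur_sn}{upper incisor axis (root Ur to crown Uc) vs the S-N line}
#'   \item{lc_lr_gome}{lower incisor axis (root Lr to crown Lc) vs the
#'     mandibular plane Go-Me}
#'   \item{sn_gome}{S-N line vs mandibular plane Go-Me}
#'   \item{g_sn_pgs}{soft-tissue convexity: angle at Sn between rays to G
#'     and to PgS}
#' }
#' All except `anb` lie in \[0, 180\]; `anb` is signed and may be negative.
#'
#' @param ls A [landmark_set()].
#' @return Named numeric vector of length 7 (degrees), names as
#'   [feature_names()].
#' @export
ceph_features <- function(ls) {
  stopifnot_landmarks(ls, "ls")
  p <- function(n) ls[n, ]
  sna <- angle_at_vertex(p("S"), p("N"), p("A"))
  snb <- angle_at_vertex(p("S"), p("N"), p("B"))
  c(sna = sna,
    snb = snb,
    anb = sna - snb,
    uc_ur_sn = line_angle(p("Ur"), p("Uc"), p("S"), p("N")),
    lc_lr_gome = line_angle(p("Lr"), p("Lc"), p("Go"), p("Me")),
    sn_gome = line_angle(p("S"), p("N"), p("Go"), p("Me")),
    g_sn_pgs = angle_at_vertex(p("G"), p("Sn"), p("PgS")))
}

#' Per-landmark prediction errors
#'
#' Error magnitude is the Euclidean distance between predicted and true
#' position of each landmark, in pixels. Error direction is the angle of
#' the displacement `pred - truth`, with 0 degrees pointing toward +x
#' (image right), increasing toward +y (image down), mapped to \[0, 360).
#' The direction of a zero-magnitude error is undefined and reported `NA`.
#'
#' @param pred,truth [landmark_set()]s.
#' @return Data frame with columns `landmark`, `magnitude`, `direction`.
#' @export
landmark_errors <- function(pred, truth) {
  stopifnot_landmarks(pred, "pred")
  stopifnot_landmarks(truth, "truth")
  d <- unclass(pred) - unclass(truth)
  mag <- sqrt(rowSums(d^2))
  dir <- (atan2(d[, "y"], d[, "x"]) * 180 / pi) %% 360
  dir[mag == 0] <- NA_real_
  data.frame(landmark = rownames(pred), magnitude = unname(mag),
             direction = unname(dir), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Signed per-feature prediction errors
#'
#' For each of the seven angular features, the signed difference
#' `feature(pred) - feature(truth)` in degrees. Because `anb = sna - snb`
#' by construction, the ANB error always equals the SNA error minus the
#' SNB error; when only A-point and B-point placement errors are correlated
#' the two can cancel, which is why ANB is typically predicted more
#' accurately than SNA or SNB individually.
#'
#' @param pred,truth [landmark_set()]s.
#' @return Named numeric vector (degrees), names as [feature_names()].
#' @export
feature_errors <- function(pred, truth) {
  ceph_features(pred) - ceph_features(truth)
}
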