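#' Canonical cephalometric landmark names
#'
#' The 26 anatomical landmarks used throughout the package, in the fixed
#' canonical order used for every landmark set, points file and model.
#' The set spans skeletal points (Sella, Porion, Gonion, Nasion, Orbitale,
#' A point, B point, Menton, ANS, PNS, Condylion, the sphenoethmoidal
#' point), dental points (incisor root/crown tips, first-molar cusp tips)
#' and the soft-tissue profile (Glabella, Pronasale, Subnasale, the lips,
#' soft-tissue Pogonion).
#'
#' @return Character vector of length 26.
#' @export
#' @examples
#' cephalometric_landmarks()
cephalometric_landmarks <- function() {
  c("S", "P", "Go", "N", "O", "A", "B", "Me", "G", "Sn", "Ls", "Li",
    "PgS", "Ur", "Uc", "Lc", "Lr", "ANS", "PNS", "U6M", "U6D", "L6M",
    "L6D", "SEM", "Pn", "Co")
}

#' Construct a landmark set
#'
#' A landmark set is a 26 x 2 numeric matrix of pixel coordinates, one row
#' per canonical landmark (see [cephalometric_landmarks()]), columns `x`
#' (column index, rightward) and `y` (row index, downward). Coordinates are
#' 0-based: (0, 0) is the centre of the top-left pixel.
#'
#' @param x Numeric vector of 26 x coordinates, or a 26 x 2 matrix (in
#'   which case `y` must be missing). A matrix with rownames in canonical
#'   order is accepted; rownames in any other order are an error, never
#'   silently reordered.
#' @param y Numeric vector of 26 y coordinates.
#' @return A `landmark_set`: numeric matrix with canonical rownames.
#' @export
landmark_set <- function(x, y = NULL) {
  nms <- cephalometric_landmarks()
  if (is.matrix(x)) {
    stopifnot(is.null(y))
    m <- x
    if (ncol(m) != 2L || nrow(m) != 26L)
      stop("landmark set must be a 26 x 2 matrix")
    if (!is.null(rownames(m)) && !identical(rownames(m), nms))
      stop("landmark rownames must be the 26 canonical names in canonical order")
  } else {
    if (length(x) != 26L || length(y) != 26L)
      stop("landmark set needs exactly 26 x and 26 y coordinates")
    m <- cbind(x, y)
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("landmark coordinates must be finite")
  dimnames(m) <- list(nms, c("x", "y"))
  class(m) <- c("landmark_set", "matrix", "array")
  m
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("Cephalometric landmark set (26 points, pixels)\n")
  print(format(round(unclass(x), 2)), quote = FALSE)
  invisible(x)
}

is_landmark_set <- function(x) inherits(x, "landmark_set")

stopifnot_landmarks <- function(ls, arg = "landmarks") {
  if (!is_landmark_set(ls))
    stop(sprintf("`%s` must be a landmark_set (see landmark_set())", arg))
  invisible(ls)
}

#' Read / write a landmark points file
#'
#' Points files are CSV with header `name,x,y` and exactly 26 rows whose
#' names and order match [cephalometric_landmarks()]. Coordinates are
#' written at full double precision.
#'
#' @param path File path.
#' @return `read_points()` returns a [landmark_set()]; `write_points()`
#'   returns `path` invisibly.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("points file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("name", "x", "y")))
    stop("points file must have header name,x,y: ", path)
  nms <- cephalometric_landmarks()
  if (nrow(df) != 26L) {
    missing <- setdiff(nms, df$name)
    extra <- setdiff(df$name, nms)
    stop(sprintf(
      "points file %s has %d rows (expected 26)%s%s", path, nrow(df),
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""))
  }
  if (!identical(df$name, nms)) {
    bad <- which(df$name != nms)[1L]
    stop(sprintf("points file %s row %d: expected landmark %s, found %s",
                 path, bad, nms[bad], df$name[bad]))
  }
  if (!is.numeric(df$x) || !is.numeric(df$y) || any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$x))) |
                 !is.finite(suppressWarnings(as.numeric(df$y))))[1L]
    stop(sprintf("points file %s row %d (%s): non-numeric coordinate",
                 path, bad, df$name[bad]))
  }
  landmark_set(df$x, df$y)
}

#' @rdname read_points
#' @param ls A [landmark_set()].
#' @export
write_points <- function(ls, path) {
  stopifnot_landmarks(ls, "ls")
  df <- data.frame(name = rownames(ls),
                   x = format(ls[, "x"], digits = 17, trim = TRUE, scientific = FALSE),
                   y = format(ls[, "y"], digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Names of the seven angular diagnostic features
#'
#' @return Character vector: `sna`, `snb`, `anb`, `uc_ur_sn`, `lc_lr_gome`,
#'   `sn_gome`, `g_sn_pgs`.
#' @export
feature_names <- function() {
  c("sna", "snb", "anb", "uc_ur_sn", "lc_lr_gome", "sn_gome", "g_sn_pgs")
}
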