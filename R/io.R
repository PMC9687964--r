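#' Write an annotated dataset to disk
#'
#' Writes each image as an 8-bit grayscale PNG, each landmark set as a
#' points CSV (see [read_points()]), and a manifest CSV with header
#' `id,image_path,points_path` (paths relative to the manifest).
#'
#' @param ds List of [ceph_image()]s.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(ds, function(d) {
    ipath <- paste0(d$id, ".png")
    ppath <- paste0(d$id, ".csv")
    png::writePNG(d$image / 255, file.path(dir, ipath))
    write_points(d$landmarks, file.path(dir, ppath))
    data.frame(id = d$id, image_path = ipath, points_path = ppath,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest)
}

#' Read an annotated dataset from a manifest
#'
#' Loads every image/points pair listed in the manifest CSV, validating
#' landmark names, order and coordinates; errors name the offending
#' manifest row and file.
#'
#' @param path Manifest CSV path (`id,image_path,points_path`; paths
#'   relative to the manifest).
#' @return List of [ceph_image()]s.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("id", "image_path", "points_path")))
    stop("manifest must have header id,image_path,points_path: ", path)
  base <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    ipath <- file.path(base, df$image_path[i])
    if (!file.exists(ipath))
      stop(sprintf("manifest row %d (%s): image file missing: %s",
                   i, df$id[i], ipath))
    arr <- png::readPNG(ipath)
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    lm <- tryCatch(read_points(file.path(base, df$points_path[i])),
                   error = function(e)
                     stop(sprintf("manifest row %d (%s): %s", i, df$id[i],
                                  conditionMessage(e)), call. = FALSE))
    ceph_image(round(arr * 255), lm, df$id[i])
  })
}

#' Write an error report as CSV files
#'
#' Writes `<prefix>_landmarks.csv` (long form: image id, landmark,
#' magnitude, direction) and `<prefix>_features.csv`
#' (`image_id,sna,snb,anb,uc_ur_sn,lc_lr_gome,sn_gome,g_sn_pgs`, signed
#' errors in degrees).
#'
#' @param report A `ceph_error_report`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_error_report <- function(report, prefix) {
  lm_df <- data.frame(
    image_id = rep(report$ids, each = 26),
    landmark = rep(rownames(report$magnitudes), length(report$ids)),
    magnitude = as.vector(report$magnitudes),
    direction = as.vector(report$directions))
  f1 <- paste0(prefix, "_landmarks.csv")
  utils::write.csv(lm_df, f1, row.names = FALSE)
  fe <- as.data.frame(t(report$feature_errors))
  fe <- cbind(image_id = report$ids, fe)
  f2 <- paste0(prefix, "_features.csv")
  utils::write.csv(fe, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Write a feature report (absolute angle values) as CSV
#'
#' Header `image_id,sna,snb,anb,uc_ur_sn,lc_lr_gome,sn_gome,g_sn_pgs`.
#'
#' @param ds List of [ceph_image()]s (features of their annotations), or
#'   a named list of [landmark_set()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(ds, path) {
  rows <- lapply(ds, function(d) {
    if (inherits(d, "ceph_image")) {
      c(list(image_id = d$id), as.list(ceph_features(d$landmarks)))
    } else c(list(image_id = ""), as.list(ceph_features(d)))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (!inherits(ds[[1]], "ceph_image") && !is.null(names(ds)))
    df$image_id <- names(ds)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Write the reproducibility metadata record every run emits.
write_run_metadata <- function(dir, command, config, seed) {
  meta <- list(command = command, seed = seed, config = config,
               package_version = as.character(utils::packageVersion("cephert")),
               model_format_version = "1.0",
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(meta)
}
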