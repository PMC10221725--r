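# Scan image I/O: float32 TIFF payload plus a JSON sidecar holding the axes
# and metadata, and a CSV export for spreadsheet inspection.

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a scan image (float32 TIFF + JSON sidecar)
#'
#' The intensity grid is stored as a 32-bit float TIFF (one sample per
#' pixel); the axis vectors and metadata go into `<path>.json`.  The round
#' trip is lossless to float32 precision.  `read_image` requires the sidecar
#' and errors without it.
#'
#' @param image A [scan_image()].
#' @param path TIFF file path.
#' @return `write_image` returns `path` invisibly; `read_image` a
#'   `scan_image`.
# drop S3 classes so the metadata serialises as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  # TIFF payload is scaled to [0, 1]; the scale factor goes to the sidecar
  scale <- max(image$data)
  if (scale <= 0) scale <- 1
  tiff::writeTIFF(image$data / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(axis_y = image$axis_y, axis_z = image$axis_z, scale = scale,
         meta = strip_classes(image$meta)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing axis sidecar: ", sp)
  d <- tiff::readTIFF(path)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  scale <- if (is.null(side$scale)) 1 else side$scale
  scan_image(d * scale, side$axis_y, side$axis_z,
             meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Export a scan image as CSV
#'
#' Long-format CSV with columns `y`, `z`, `intensity`.
#'
#' @param image A [scan_image()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_image_csv <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  df <- expand.grid(y = image$axis_y, z = image$axis_z)
  df$intensity <- as.vector(image$data)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
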