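#' Construct a labelled image pair
#'
#' Carrier for a segmented 2-D projection: an integer label image (0 =
#' background, positive integers = cells) plus one or more aligned intensity
#' channels. Rasters are plain matrices, row-major and y-down: row index is
#' the y pixel coordinate, column index the x pixel coordinate, pixel centers
#' at integer coordinates. All physical measurements convert through
#' `pixel_size_um`.
#'
#' @param label_image Integer matrix of non-negative labels.
#' @param channels Named list of numeric matrices, each the same shape as
#'   `label_image`.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @return An object of class `"image_pair"`.
#' @export
image_pair <- function(label_image, channels, pixel_size_um = 1) {
  if (!is.matrix(label_image))
    stop_format("label_image must be a matrix")
  if (is.double(label_image)) {
    if (any(label_image != round(label_image)))
      stop_format("label image contains non-integer values")
    storage.mode(label_image) <- "integer"
  }
  if (any(label_image < 0L))
    stop_validation("labels must be non-negative integers")
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_validation("channels must be a named list of matrices")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !identical(dim(ch), dim(label_image)))
      stop_validation(
        "channel '%s' shape (%s) does not match label image shape (%s)",
        nm, paste(dim(ch), collapse = "x"),
        paste(dim(label_image), collapse = "x"))
    if (any(!is.finite(ch)))
      stop_validation("channel '%s' contains non-finite values", nm)
  }
  check_number(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  structure(list(label_image = label_image, channels = channels,
                 pixel_size_um = pixel_size_um),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("Labelled image pair: %d x %d px (%g um/px), %d cells, channels: %s\n",
              nrow(x$label_image), ncol(x$label_image), x$pixel_size_um,
              length(setdiff(unique(as.vector(x$label_image)), 0L)),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a labelled image pair from TIFF files
#'
#' Label and intensity rasters are 16-bit unsigned integer TIFFs, the native
#' microscopy camera format. Channel names come from the names of
#' `channel_paths` (or file basenames when unnamed).
#'
#' @param label_path Path to the integer label TIFF.
#' @param channel_paths Character vector of intensity TIFF paths, ideally
#'   named by channel.
#' @param pixel_size_um Pixel size, micrometres.
#' @return An [image_pair()].
#' @export
read_image_pair <- function(label_path, channel_paths, pixel_size_um = 1) {
  read_one <- function(p) {
    if (!file.exists(p)) stop_format("image not found: %s", p)
    img <- tiff::readTIFF(p, as.is = TRUE)
    if (!is.matrix(img)) stop_format("expected a single-plane 2-D TIFF: %s", p)
    img
  }
  lab <- read_one(label_path)
  nms <- names(channel_paths)
  if (is.null(nms)) nms <- rep("", length(channel_paths))
  nms[!nzchar(nms)] <- tools::file_path_sans_ext(
    basename(channel_paths[!nzchar(nms)]))
  chans <- lapply(channel_paths, read_one)
  names(chans) <- nms
  image_pair(lab, chans, pixel_size_um = pixel_size_um)
}

#' Write a labelled image pair to TIFF files
#'
#' Writes the label image and every channel as 16-bit unsigned TIFFs under
#' `dir`, as `label.tif` and `<channel>.tif`. All rasters must be
#' integer-valued in [0, 65535]; synthetic intensities are quantized to
#' integer grey levels at generation time, so the round trip is bit-exact.
#'
#' @param pair An [image_pair()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_image_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "image_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(img, p) {
    if (any(img != round(img)) || any(img < 0) || any(img > 65535))
      stop_validation("raster for '%s' is not integer-valued in [0, 65535]",
                      basename(p))
    tiff::writeTIFF(img / 65535, p, bits.per.sample = 16L)
    p
  }
  paths <- c(label = write_one(pair$label_image, file.path(dir, "label.tif")))
  for (nm in names(pair$channels))
    paths[nm] <- write_one(pair$channels[[nm]],
                           file.path(dir, paste0(nm, ".tif")))
  invisible(paths)
}
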