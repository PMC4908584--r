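#' Strip image container
#'
#' A `strip_image` wraps an 8-bit pixel array together with the physical
#' scale and the flow-axis convention. Pixels are stored on the 0--255
#' scale as a numeric matrix (grayscale) or a height x width x 3 array
#' (RGB). Rows run along the direction of flow and **row 1 is the
#' sample-inlet end** of the strip: on a competitive-format strip the
#' test line is therefore the upstream (lower row index) of the two
#' lines.
#'
#' @param pixels numeric matrix (H x W) or array (H x W x 3), values in
#'   \[0, 255\].
#' @param px_per_mm pixels per millimetre along both axes.
#' @return A `strip_image` object.
#' @seealso [read_strip_image()], [render_strip()], [analyze_strip()]
#' @export
strip_image <- function(pixels, px_per_mm) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    abort_input("`pixels` must be a numeric matrix or 3-channel array")
  d <- dim(pixels)
  if (length(d) == 3L && d[3] != 3L)
    abort_input(sprintf("channel count must be 1 or 3, got %d", d[3]))
  if (any(pixels < 0 | pixels > 255, na.rm = TRUE))
    abort_input("pixel values must lie in [0, 255]")
  if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0)
    abort_input("`px_per_mm` must be a positive scalar")
  structure(
    list(pixels = pixels, px_per_mm = as.numeric(px_per_mm)),
    class = "strip_image"
  )
}

n_channels <- function(image) {
  d <- dim(image$pixels)
  if (length(d) == 2L) 1L else d[3]
}

image_height <- function(image) dim(image$pixels)[1]
image_width  <- function(image) dim(image$pixels)[2]

#' @export
print.strip_image <- function(x, ...) {
  cat(sprintf(
    "<strip_image> %d x %d px, %d channel(s), %.1f px/mm (row 1 = sample inlet)\n",
    image_height(x), image_width(x), n_channels(x), x$px_per_mm
  ))
  invisible(x)
}

#' Read and write strip images
#'
#' PNG and TIFF files (8-bit, 1 or 3 channels) are supported. An alpha
#' channel, if present, is dropped. Pixels are rescaled from the unit
#' interval used by the readers to 0--255.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param px_per_mm physical scale to attach to the image.
#' @return `read_strip_image()` returns a [strip_image()];
#'   `write_strip_image()` returns `path` invisibly.
#' @export
read_strip_image <- function(path, px_per_mm) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort_input(sprintf("unsupported image format: .%s", ext))
  )
  d <- dim(raw)
  if (length(d) == 3L) {
    if (d[3] == 2L) raw <- raw[, , 1]                 # gray + alpha
    else if (d[3] >= 3L) raw <- raw[, , 1:3, drop = FALSE]
    if (length(dim(raw)) == 3L && dim(raw)[3] == 1L) raw <- raw[, , 1]
  }
  strip_image(raw * 255, px_per_mm = px_per_mm)
}

#' @rdname read_strip_image
#' @param image a [strip_image()].
#' @export
write_strip_image <- function(image, path) {
  stopifnot(inherits(image, "strip_image"))
  px <- pmin(pmax(round(image$pixels), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(px, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(px, where = path, bits.per.sample = 8L),
    abort_input(sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}
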