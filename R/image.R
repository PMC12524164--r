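#' Two-channel multiphoton image
#'
#' Container for a registered SHG (collagen-specific) and TPEF (tissue
#' autofluorescence) channel pair. Both channels are numeric matrices with
#' intensities in \[0, 1\] sharing the same shape; `pixel_pitch_um` is the
#' physical side length of one pixel in micrometres.
#'
#' @param shg Numeric matrix, SHG channel, values in \[0, 1\].
#' @param tpef Numeric matrix, TPEF channel, same shape as `shg`.
#' @param pixel_pitch_um Positive scalar, micrometres per pixel
#'   (default 0.390625, i.e. 200 um imaged over 512 px).
#' @return An object of class `multiphoton_image` with elements `shg`,
#'   `tpef`, `pixel_pitch_um`.
#' @examples
#' img <- multiphoton_image(matrix(0, 8, 8), matrix(0.5, 8, 8))
#' pixel_area_um2(img)
#' @export
multiphoton_image <- function(shg, tpef, pixel_pitch_um = 0.390625) {
  stopifnot(is.matrix(shg), is.matrix(tpef))
  if (!all(dim(shg) == dim(tpef))) {
    stop("shg and tpef channels must share shape", call. = FALSE)
  }
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1 ||
      pixel_pitch_um <= 0) {
    stop("pixel_pitch_um must be a positive scalar", call. = FALSE)
  }
  rng <- range(c(shg, tpef), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("channel intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(shg = shg, tpef = tpef, pixel_pitch_um = as.numeric(pixel_pitch_um)),
    class = "multiphoton_image"
  )
}

#' @export
print.multiphoton_image <- function(x, ...) {
  d <- dim(x$shg)
  cat(sprintf(
    "<multiphoton_image> %d x %d px at %.6f um/px (%.1f x %.1f um)\n",
    d[1], d[2], x$pixel_pitch_um, d[1] * x$pixel_pitch_um,
    d[2] * x$pixel_pitch_um
  ))
  invisible(x)
}

#' Physical area of one pixel in square micrometres
#' @param img A `multiphoton_image`, or a numeric pixel pitch in um.
#' @return Pixel area in um^2.
#' @export
pixel_area_um2 <- function(img) {
  pitch <- if (inherits(img, "multiphoton_image")) img$pixel_pitch_um else img
  pitch^2
}

#' Write a multiphoton image as a two-page grayscale TIFF
#'
#' Page 1 is the SHG channel, page 2 the TPEF channel, stored as 16-bit
#' grayscale. The physical pixel pitch travels in a JSON sidecar
#' (`<path>.json`) next to the image.
#'
#' @param img A `multiphoton_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multiphoton_tiff <- function(img, path) {
  stopifnot(inherits(img, "multiphoton_image"))
  tiff::writeTIFF(
    list(img$shg, img$tpef), path,
    bits.per.sample = 16L,
    compression = "none",
    reduce = TRUE
  )
  jsonlite::write_json(
    list(pixel_pitch_um = img$pixel_pitch_um,
         pages = c("shg", "tpef")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a two-page grayscale TIFF as a multiphoton image
#'
#' @param path TIFF written by [write_multiphoton_tiff()] (page 1 = SHG,
#'   page 2 = TPEF).
#' @param pixel_pitch_um Pixel pitch override; if `NULL` it is recovered
#'   from the `<path>.json` sidecar.
#' @return A `multiphoton_image`.
#' @export
read_multiphoton_tiff <- function(path, pixel_pitch_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) {
    stop("expected a two-page TIFF (SHG, TPEF)", call. = FALSE)
  }
  if (is.null(pixel_pitch_um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      pixel_pitch_um <- jsonlite::read_json(sidecar)$pixel_pitch_um
    } else {
      stop("no pitch sidecar found; supply pixel_pitch_um", call. = FALSE)
    }
  }
  multiphoton_image(pages[[1]], pages[[2]], pixel_pitch_um)
}
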