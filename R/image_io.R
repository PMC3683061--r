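#' Read a fundus photograph
#'
#' Reads PNG (always) or JPEG (when the suggested `jpeg` package is
#' installed) into a fundus image object: an H x W x 3 array with channels in
#' red-green-blue order and intensities in \[0, 1\].
#'
#' @param path image path.
#' @param subject_id identifier attached to the image (default: file stem).
#' @return object of class `"fundus_image"`: list with `pixels` and
#'   `subject_id`.
#' @export
read_fundus <- function(path, subject_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      pm_stop("the jpeg package is required for JPEG input", "missing_dep")
    jpeg::readJPEG(path)
  } else png::readPNG(path)
  fundus_image(px, subject_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a fundus image object from a pixel array
#'
#' @param pixels H x W x 3 array (or H x W matrix, expanded to gray RGB) with
#'   values in \[0, 1\]; H and W must be at least 32.
#' @param subject_id identifier.
#' @return `"fundus_image"` object.
#' @export
fundus_image <- function(pixels, subject_id = "subject") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) == 3 && dim(pixels)[3] == 4)
    pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) pm_stop("expected an H x W x 3 raster", "bad_image")
  if (d[1] < 32 || d[2] < 32) pm_stop("image must be at least 32 x 32", "bad_image")
  if (!all(is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 1)
    pm_stop("pixel intensities must be finite in [0, 1]", "bad_image")
  structure(list(pixels = pixels, subject_id = subject_id), class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("Fundus image", x$subject_id, ":", d[1], "x", d[2], "RGB\n")
  invisible(x)
}

#' Write a fundus image to PNG
#'
#' @param img a `"fundus_image"`.
#' @param path output path.
#' @export
write_fundus <- function(img, path) {
  png::writePNG(img$pixels, path)
  invisible(path)
}
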