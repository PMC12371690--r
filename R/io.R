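#' Construct a grayscale image
#'
#' The basic raster consumed by every pipeline stage: a numeric matrix of
#' intensities in \[0, 1\] with optional physical pixel size.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param pixel_size optional physical pixel size in nm per pixel (> 0).
#' @param provenance free-text note on where the raster came from.
#' @return a `grayscale_image`: the matrix with `pixel_size` and
#'   `provenance` attributes.
#' @export
grayscale_image <- function(pixels, pixel_size = NULL, provenance = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("intensities must lie in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
      stop("`pixel_size` must be a single positive number (nm/px)")
  }
  structure(clamp(pixels),
            pixel_size = pixel_size, provenance = provenance,
            class = c("grayscale_image", "matrix", "array"))
}

#' @export
print.grayscale_image <- function(x, ...) {
  ps <- attr(x, "pixel_size")
  cat(sprintf("grayscale_image %d x %d px%s, intensity [%.3f, %.3f]\n",
              nrow(x), ncol(x),
              if (is.null(ps)) "" else sprintf(" (%g nm/px)", ps),
              min(x), max(x)))
  invisible(x)
}

pixel_size_of <- function(image) attr(image, "pixel_size")

#' Read a grayscale micrograph from TIFF or PNG
#'
#' 8- and 16-bit grayscale rasters are normalized to \[0, 1\] (16-bit full
#' scale maps to 1.0). RGB images are converted to single-channel luminance
#' (Rec. 709 weights); an alpha channel, if present, is dropped.
#'
#' @param path path to a `.tif`, `.tiff` or `.png` file.
#' @param pixel_size optional nm per pixel to attach to the image.
#' @return a [grayscale_image].
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' for file ", path,
         " (TIFF or PNG expected)"))
  if (is.list(arr)) arr <- arr[[1]]
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    if (nch %in% c(2L, 4L)) arr <- arr[, , -nch, drop = FALSE]  # drop alpha
    if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1]
    } else if (dim(arr)[3] == 3L) {
      arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      stop("unsupported channel count (", nch, ") in ", path)
    }
  }
  if (length(dim(arr)) != 2) stop("could not interpret ", path, " as a 2-D raster")
  grayscale_image(clamp(arr), pixel_size = pixel_size,
                  provenance = normalizePath(path))
}

#' Write a grayscale image or RGB overlay to PNG or TIFF
#'
#' @param image a [grayscale_image], plain matrix, or H x W x 3 RGB array
#'   with values in \[0, 1\].
#' @param path destination file; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  arr <- unclass(image)
  attributes(arr) <- list(dim = dim(arr))
  arr <- clamp(arr)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = , tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported output format '.", ext, "'"))
  invisible(path)
}

#' Write a table with full numeric precision
#'
#' Numeric columns are serialized with 17 significant digits so that a
#' write-then-read round trip reproduces every double exactly.
#'
#' @param df a data frame.
#' @param path destination for the tab-separated file.
#' @return `path`, invisibly.
#' @export
write_fm_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_fm_table()]
#' @param path tab-separated file path.
#' @return a data frame.
#' @export
read_fm_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
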