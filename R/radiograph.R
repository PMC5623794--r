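#' Radiograph image objects
#'
#' A `radiograph` holds a single-channel radiographic image as a numeric
#' matrix of non-negative integers, together with its bit depth (8 or 16),
#' an optional position label and an optional source path. It is the unit
#' every stage of the pipeline consumes and produces.
#'
#' @param pixels Numeric matrix (rows x cols) of non-negative integers.
#' @param bit_depth Either 8 or 16. All values must fit in
#'   `[0, 2^bit_depth - 1]`.
#' @param label Optional position name (e.g. `"lungs"`).
#' @param source Optional path the image was read from.
#' @param meta Optional list of extra metadata (e.g. the true crop box of a
#'   synthetic image).
#'
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, bit_depth = 16L, label = NULL, source = NULL,
                       meta = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    rp_stop("pixels must be a numeric matrix")
  if (!bit_depth %in% c(8L, 16L))
    rp_stop("bit_depth must be 8 or 16, got ", bit_depth)
  if (nrow(pixels) < 5L || ncol(pixels) < 5L)
    rp_stop("image must be at least 5x5 (got ",
            nrow(pixels), "x", ncol(pixels),
            "); the 5x5 median window must fit")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    rp_stop("pixels contain NA or non-finite values")
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxval))
    rp_stop("pixel values outside [0, ", maxval, "]")
  if (any(pixels != floor(pixels)))
    rp_stop("pixel values must be integers")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         label = label, source = source, meta = meta),
    class = "radiograph"
  )
}

#' @rdname radiograph
#' @param x Object to test or convert.
#' @export
is_radiograph <- function(x) inherits(x, "radiograph")

#' @export
dim.radiograph <- function(x) dim(x$pixels)

#' @export
#' @rdname radiograph
#' @param ... Unused.
as.matrix.radiograph <- function(x, ...) x$pixels

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %dx%d, %d-bit, range [%d, %d]%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

# Bit depth of a PNG file, from byte 25 of the IHDR chunk.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L) rp_stop("file too short to be a PNG: ", path)
  as.integer(hdr[25])
}

#' Read a radiograph from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale raster. Multi-channel inputs are
#' collapsed to gray by the unweighted mean of the channels, then rounded.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param bit_depth_policy `"preserve"` keeps the file's bit depth;
#'   `"force16"` rescales 8-bit data onto the 16-bit range (factor 257, so
#'   255 maps to 65535).
#' @param label,... Passed to [radiograph()].
#' @return A [radiograph()].
#' @export
read_radiograph <- function(path, bit_depth_policy = c("preserve", "force16"),
                            label = NULL, ...) {
  bit_depth_policy <- match.arg(bit_depth_policy)
  if (!file.exists(path)) rp_stop("file not found: ", path,
                                  class = "radiopos_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    bits <- png_bit_depth(path)
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) rp_stop("cannot read PNG ", path, ": ",
                                                conditionMessage(e),
                                                class = "radiopos_io_error"))
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                    error = function(e) rp_stop("cannot read TIFF ", path, ": ",
                                                conditionMessage(e),
                                                class = "radiopos_io_error"))
    bits <- attr(arr, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else {
    rp_stop("unsupported image format: .", ext, class = "radiopos_io_error")
  }
  if (length(dim(arr)) == 0L || length(arr) == 0L)
    rp_stop("zero-sized raster: ", path)
  bits <- if (bits <= 8) 8L else 16L
  maxval <- 2^bits - 1
  if (length(dim(arr)) == 3L) {
    # unweighted channel mean, dropping a pure-opaque alpha channel first
    nc <- dim(arr)[3]
    if (nc %in% c(2L, 4L) && all(arr[, , nc] == 1)) {
      arr <- arr[, , -nc, drop = FALSE]
    }
    arr <- apply(arr, c(1, 2), mean)
  }
  px <- matrix(round_half_up(arr * maxval), nrow(arr), ncol(arr))
  if (bit_depth_policy == "force16" && bits == 8L) {
    px <- px * 257
    bits <- 16L
  }
  radiograph(px, bit_depth = bits, label = label, source = path, ...)
}

#' Write a radiograph to disk
#'
#' 16-bit images are written as 16-bit TIFF (`.tif`/`.tiff`); PNG output
#' (`.png`) is 8-bit, down-quantizing 16-bit data.
#'
#' @param img A [radiograph()].
#' @param path Output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(img, path) {
  if (!is_radiograph(img)) rp_stop("img must be a radiograph")
  ext <- tolower(tools::file_ext(path))
  maxval <- 2^img$bit_depth - 1
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels / maxval, path,
                    bits.per.sample = img$bit_depth, compression = "none")
  } else if (ext == "png") {
    png::writePNG(img$pixels / maxval, path)
  } else {
    rp_stop("unsupported output format: .", ext, class = "radiopos_io_error")
  }
  invisible(path)
}
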