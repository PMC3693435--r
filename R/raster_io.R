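#' Read a grayscale PNG mammogram
#'
#' Reads an 8- or 16-bit single-channel (or channel-collapsible) PNG and
#' returns intensities scaled to `[0, 1]` by dividing stored values by
#' `2^bit_depth - 1`. Multi-channel files are accepted only when all colour
#' channels are identical (grayscale stored as RGB); an alpha channel, if
#' present, is ignored.
#'
#' @param path path to the PNG file.
#' @inheritParams mammogram
#' @return a [mammogram].
#' @seealso [write_mammogram_png()], [read_mammogram_dicom()]
#' @export
read_mammogram_png <- function(path, view = "CC", laterality = "L",
                               chest_side = NULL) {
  if (!file.exists(path)) stop("cannot read PNG: '", path, "' does not exist",
                               call. = FALSE)
  px <- tryCatch(png::readPNG(path),
                 error = function(e) stop("cannot read PNG '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  depth <- png_bit_depth(path)
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    colour <- if (nch %in% c(2L, 4L)) nch - 1L else nch   # drop alpha channel
    ch <- lapply(seq_len(colour), function(k) px[, , k])
    for (k in seq_along(ch)[-1])
      if (!identical(ch[[1L]], ch[[k]]))
        stop("PNG '", path, "' has unequal colour channels; ",
             "not a grayscale image", call. = FALSE)
    px <- ch[[1L]]
  }
  # readPNG already divides by 2^depth - 1
  mammogram(px, view = view, laterality = laterality, chest_side = chest_side,
            bit_depth = depth)
}

# Bit depth straight from the IHDR chunk (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26L)
  if (length(hdr) < 26L ||
      !identical(hdr[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("'", path, "' is not a PNG file", call. = FALSE)
  as.integer(hdr[25L])
}

#' Write a mammogram to PNG
#'
#' Writes the intensity grid as an 8-bit grayscale PNG (values quantized to
#' 256 levels). Reading the file back reproduces the grid up to that
#' quantization.
#'
#' @param img a [mammogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mammogram_png <- function(img, path) {
  stopifnot(is_mammogram(img))
  png::writePNG(img$pixels, target = path)
  invisible(path)
}

#' Read and write binary region masks as PNG
#'
#' Masks are stored as 8-bit grayscale PNGs with values 0 and 255; the
#' round trip is bit-exact.
#'
#' @param mask logical matrix, at least 16 x 16 (the minimum image size).
#' @param path file path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_region_mask(mask)
  if (nrow(mask) < 16L || ncol(mask) < 16L)
    stop("mask must be at least 16 x 16 (got ",
         nrow(mask), " x ", ncol(mask), ")", call. = FALSE)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: '", path, "' does not exist",
                               call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0.5
}
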