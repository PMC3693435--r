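#' Construct a mammogram object
#'
#' A `mammogram` holds a 2-D grid of intensities scaled to `[0, 1]` together
#' with the acquisition metadata the density pipeline needs: the mammographic
#' view, laterality, which image border is adjacent to the chest wall, and the
#' bit depth of the source raster. Throughout the package the intensity
#' convention is *higher value = radiographically denser tissue*; inputs using
#' the opposite convention (DICOM MONOCHROME1) are inverted at ingest.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`, row-major image
#'   layout (row 1 = top of the image). Must be at least 16 x 16.
#' @param view mammographic view, `"CC"` (craniocaudal) or `"MLO"`
#'   (mediolateral oblique).
#' @param laterality `"L"` or `"R"`; which breast was imaged.
#' @param chest_side which image column border is adjacent to the chest wall,
#'   `"left"` or `"right"`. Defaults from laterality (`L -> "left"`,
#'   `R -> "right"`), the usual display convention; override per image when
#'   the source uses another layout.
#' @param bit_depth integer bit depth of the source raster (8 or 16 for PNG).
#'
#' @return an object of class `mammogram`: a list with elements `pixels`,
#'   `view`, `laterality`, `chest_side`, `bit_depth`.
#' @examples
#' img <- mammogram(matrix(runif(32 * 32), 32), view = "CC", laterality = "L")
#' dim(img$pixels)
#' @export
mammogram <- function(pixels, view = c("CC", "MLO"), laterality = c("L", "R"),
                      chest_side = NULL, bit_depth = 8L) {
  view <- match.arg(view)
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("mammogram must be at least 16 x 16 pixels (got ",
         nrow(pixels), " x ", ncol(pixels), ")", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("all intensities must lie in [0, 1]", call. = FALSE)
  if (is.null(chest_side))
    chest_side <- if (laterality == "L") "left" else "right"
  chest_side <- match.arg(chest_side, c("left", "right"))
  structure(
    list(pixels = pixels, view = view, laterality = laterality,
         chest_side = chest_side, bit_depth = as.integer(bit_depth)),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %d x %d px, view %s, laterality %s, chest side %s, %d-bit source\n",
              nrow(x$pixels), ncol(x$pixels), x$view, x$laterality,
              x$chest_side, x$bit_depth))
  cat(sprintf("  intensity range [%.4f, %.4f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.mammogram <- function(x) dim(x$pixels)

is_mammogram <- function(x) inherits(x, "mammogram")

#' Validate a region mask against an image
#'
#' Region masks (breast mask, user invalidation regions, phantom ground truth)
#' are plain logical matrices with the same shape as the image they annotate.
#'
#' @param mask logical matrix (or 0/1 numeric matrix, which is coerced).
#' @param reference optional `mammogram` or matrix the mask must match in shape.
#' @return the mask as a logical matrix.
#' @export
as_region_mask <- function(mask, reference = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop("numeric mask must contain only 0/1", call. = FALSE)
    mask <- mask > 0
  }
  if (!is.logical(mask)) stop("mask must be logical or 0/1", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!is.null(reference)) {
    ref_dim <- if (is_mammogram(reference)) dim(reference$pixels) else dim(reference)
    if (!identical(dim(mask), ref_dim))
      stop("mask shape ", paste(dim(mask), collapse = " x "),
           " does not match image shape ", paste(ref_dim, collapse = " x "),
           call. = FALSE)
  }
  mask
}
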