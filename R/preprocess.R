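#' Contrast and brightness normalization by histogram stretching
#'
#' X-ray brightness depends on the acquisition chain as well as on tissue
#' density. Assuming the least and most attenuating tissues (subcutaneous fat,
#' connective tissue) are present in every mammogram, a linear histogram
#' stretch maps a low and a high intensity percentile to 0 and 1 so that the
#' remaining variation reflects density. Percentiles are computed over
#' foreground-candidate pixels (intensity > 0) so the black background and
#' dead pixels do not anchor the map; the defaults (1st/99th) are robust to
#' isolated outliers and can be set to 0/100 for a strict min/max stretch.
#'
#' @param img a [mammogram].
#' @param low_pct,high_pct percentiles (0-100) mapped to 0 and 1;
#'   `low_pct < high_pct`.
#' @return the normalized [mammogram]; a degenerate (constant-foreground)
#'   image is returned unchanged with a warning.
#' @export
normalize_contrast <- function(img, low_pct = 1, high_pct = 99) {
  stopifnot(is_mammogram(img))
  if (!(low_pct < high_pct))
    stop("low_pct must be smaller than high_pct", call. = FALSE)
  fg <- img$pixels[img$pixels > 0]
  if (length(fg) == 0L) fg <- as.vector(img$pixels)
  q <- stats::quantile(fg, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[2L] <= q[1L]) {
    warning("degenerate histogram (constant foreground); image left unchanged")
    return(img)
  }
  img$pixels <- pmin(pmax((img$pixels - q[1L]) / (q[2L] - q[1L]), 0), 1)
  img
}

#' Manual brightness/contrast adjustment
#'
#' Pixelwise `clip(gain * x + offset, 0, 1)`, the non-interactive equivalent
#' of the manual brightness/contrast controls of interactive density tools.
#'
#' @param img a [mammogram].
#' @param gain positive multiplicative contrast gain.
#' @param offset additive brightness offset.
#' @return the adjusted [mammogram].
#' @export
adjust_brightness <- function(img, gain = 1, offset = 0) {
  stopifnot(is_mammogram(img))
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0)
    stop("gain must be a positive number", call. = FALSE)
  img$pixels <- pmin(pmax(gain * img$pixels + offset, 0), 1)
  img
}

#' Chest-to-edge horizontal distance map
#'
#' For each row `i` of the breast mask, `d[i, j]` is the horizontal distance
#' from pixel `(i, j)` to the chest-side reference column, divided by the
#' total distance between that reference and the outermost breast pixel of the
#' row. The reference is the image border column on `chest_side` for
#' craniocaudal views, or the per-row pectoral-muscle boundary when one is
#' supplied (mediolateral oblique views). Thus `d = 0` at the reference,
#' `d = 1` at the breast edge, and `d` is a within-row linear ramp in between
#' - the proxy for compressed-breast thickness that drives
#' [brightness_correction()]. Rows whose edge coincides with the reference get
#' `d = 1`. Pixels outside the mask are `NA`.
#'
#' @param breast logical breast mask (see [segment_breast()]).
#' @param chest_side `"left"` or `"right"`: image border adjacent to the chest.
#' @param pectoral_boundary optional integer vector, one column index per
#'   image row, giving the pectoral boundary to use as the reference instead
#'   of the image border (NA for rows without pectoral muscle).
#' @return numeric matrix of `d` values in `[0, 1]` on breast pixels, `NA`
#'   elsewhere.
#' @export
edge_distance_map <- function(breast, chest_side = c("left", "right"),
                              pectoral_boundary = NULL) {
  chest_side <- match.arg(chest_side)
  breast <- as_region_mask(breast)
  if (!any(breast))
    stop("breast mask is empty; run segmentation before computing distances",
         call. = FALSE)
  nr <- nrow(breast); nc <- ncol(breast)
  if (!is.null(pectoral_boundary) && length(pectoral_boundary) != nr)
    stop("pectoral_boundary must have one entry per image row", call. = FALSE)
  d <- matrix(NA_real_, nr, nc)
  border <- if (chest_side == "left") 1L else nc
  for (i in seq_len(nr)) {
    cols <- which(breast[i, ])
    if (length(cols) == 0L) next
    r_i <- border
    if (!is.null(pectoral_boundary) && !is.na(pectoral_boundary[i]))
      r_i <- as.integer(pectoral_boundary[i])
    e_i <- if (chest_side == "left") max(cols) else min(cols)
    denom <- abs(e_i - r_i)
    if (denom == 0L) d[i, cols] <- 1
    else d[i, cols] <- pmin(pmax(abs(cols - r_i) / denom, 0), 1)
  }
  d
}

#' Breast-thickness brightness correction
#'
#' Compressed-breast thickness is roughly constant between the plates but
#' falls off toward the breast edge, so thicker (interior) regions look
#' brighter than their density warrants and can be mistaken for dense tissue.
#' Each breast pixel is multiplied by
#' \deqn{K_{ij} = \alpha + (1 - \alpha)\, d_{ij},}
#' where `d` is the chest-to-edge distance map and `alpha` is user-set in
#' `[0, 1]`. `alpha = 1` leaves the image unchanged (bit-exact); `alpha < 1`
#' attenuates brightness increasingly toward the chest side (`K = alpha` at
#' the reference, `K = 1` at the breast edge), flattening the thickness
#' gradient. Pixels where `d` is undefined (outside the breast) are untouched.
#'
#' @param img a [mammogram].
#' @param dmap distance map from [edge_distance_map()].
#' @param alpha correction strength in `[0, 1]`; lower = stronger attenuation.
#' @return the corrected [mammogram].
#' @export
brightness_correction <- function(img, dmap, alpha) {
  stopifnot(is_mammogram(img))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  if (!identical(dim(dmap), dim(img$pixels)))
    stop("distance map shape does not match the image", call. = FALSE)
  if (alpha == 1) return(img)
  idx <- which(!is.na(dmap))
  k <- alpha + (1 - alpha) * dmap[idx]
  img$pixels[idx] <- img$pixels[idx] * k
  img
}
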