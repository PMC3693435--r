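#' Boyd semiquantitative category labels, in scale order
#' @export
BOYD_LEVELS <- c("0%", "<10%", "10-25%", "25-50%", "50-75%", ">75%")

#' Compute percent density from a tissue segmentation
#'
#' Percent density is the dense-tissue share of the segmented breast,
#' `PD = 100 * DT / (DT + FT)`, with DT and FT the dense and fat pixel counts.
#' Background and invalidated pixels enter neither count.
#'
#' @param seg a `tissue_segmentation` from [classify_tissue()].
#' @return an object of class `density_result`: list with `dt_pixels`,
#'   `ft_pixels`, `pd_percent`, `boyd_category` (factor on [BOYD_LEVELS]),
#'   `t1`, `t2`.
#' @examples
#' px <- matrix(0.05, 32, 32); px[8:24, 8:24] <- 0.5; px[10:13, 10:13] <- 0.9
#' img <- mammogram(px)
#' breast <- segment_breast(img, t1 = 0.3)
#' seg <- classify_tissue(img, breast, t1 = 0.3, t2 = 0.7)
#' compute_pd(seg)
#' @export
compute_pd <- function(seg) {
  if (!inherits(seg, "tissue_segmentation"))
    stop("'seg' must come from classify_tissue()", call. = FALSE)
  dt <- sum(seg$labels == 2L)
  ft <- sum(seg$labels == 1L)
  if (dt + ft == 0L)
    stop("density undefined: the segmentation contains no breast pixels",
         call. = FALSE)
  pd <- 100 * dt / (dt + ft)
  structure(
    list(dt_pixels = dt, ft_pixels = ft, pd_percent = pd,
         boyd_category = categorize_boyd(pd), t1 = seg$t1, t2 = seg$t2),
    class = "density_result"
  )
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Percent mammographic density: %.1f%% (Boyd category %s)\n",
              x$pd_percent, as.character(x$boyd_category)))
  cat(sprintf("  dense %d px | fat %d px | t1 = %.4f | t2 = %.4f\n",
              x$dt_pixels, x$ft_pixels, x$t1, x$t2))
  invisible(x)
}

#' Assign PD to a Boyd semiquantitative category
#'
#' The Boyd scale has six categories: 0%, <10%, 10-25%, 25-50%, 50-75% and
#' >75%. Printed range labels overlap at their boundaries, so a convention is
#' required; this implementation uses: exactly 0 -> "0%"; (0,10) -> "<10%";
#' \[10,25) -> "10-25%"; \[25,50) -> "25-50%"; \[50,75\] -> "50-75%";
#' (75,100\] -> ">75%". The dedicated "0%" category and the strict ">75%"
#' label fix the two outer boundaries; interior boundaries are left-closed.
#'
#' @param pd percent density value(s) in `[0, 100]`.
#' @return factor with levels [BOYD_LEVELS].
#' @export
categorize_boyd <- function(pd) {
  if (any(is.na(pd)) || any(pd < 0 | pd > 100))
    stop("pd must lie in [0, 100]", call. = FALSE)
  idx <- ifelse(pd == 0, 1L,
         ifelse(pd < 10, 2L,
         ifelse(pd < 25, 3L,
         ifelse(pd < 50, 4L,
         ifelse(pd <= 75, 5L, 6L)))))
  factor(BOYD_LEVELS[idx], levels = BOYD_LEVELS)
}

#' Bin PD values at arbitrary cut-offs
#'
#' Generic left-closed binning used to categorize continuous PD readings, e.g.
#' at the Boyd cut-offs (0, 10, 25, 50, 75) for weighted-kappa comparison with
#' visual reading, or at control-group quartiles in risk analyses. Bin `b`
#' (1-based) covers `[cutoffs[b-1], cutoffs[b])`, the first bin everything
#' below the first cut-off, the last bin everything at or above the last, so
#' `n` cut-offs give `n + 1` bins.
#'
#' Note the Boyd scale itself closes two boundaries differently (exact 0 is
#' its own category and 75 belongs to "50-75%", see [categorize_boyd()]);
#' left-closed binning at (0, 10, 25, 50, 75) agrees with the Boyd assignment
#' at every other PD value.
#'
#' @param pd percent density value(s) in `[0, 100]`.
#' @param cutoffs strictly increasing cut-offs within `[0, 100)`.
#' @return integer bin indices in `1..(length(cutoffs) + 1)`.
#' @export
categorize_cutoffs <- function(pd, cutoffs) {
  if (any(is.na(pd)) || any(pd < 0 | pd > 100))
    stop("pd must lie in [0, 100]", call. = FALSE)
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing", call. = FALSE)
  findInterval(pd, cutoffs) + 1L
}

#' Measure percent density in one mammogram
#'
#' Runs the full semi-automated measurement on a single image: optional
#' histogram stretching, T1 proposal (unless overridden), breast segmentation
#' by largest connected component, removal of invalidated regions and the
#' pectoral area, thickness brightness correction, dense/fat classification at
#' T2, and the PD computation. This is the programmatic equivalent of one
#' interactive reading; T2 must always be supplied (it is the manually set
#' threshold), while T1 and alpha have working defaults.
#'
#' @param img a [mammogram].
#' @param t2 dense/fat threshold in `[0, 1]` (required).
#' @param t1 background/object threshold; `NULL` (default) to use the Otsu
#'   proposal from [propose_t1()].
#' @param alpha thickness-correction strength in `[0, 1]`; 1 (default) = no
#'   correction.
#' @param normalize apply [normalize_contrast()] first?
#' @param stretch length-2 vector of stretch percentiles.
#' @param invalid_regions list of logical masks to exclude (see
#'   [invalidate()]).
#' @param pectoral_boundary optional per-row pectoral boundary column (see
#'   [edge_distance_map()]); pixels on the chest side of the boundary are
#'   also invalidated.
#' @param connectivity component connectivity for [segment_breast()].
#' @return an object of class `pd_measurement` bundling the `density_result`,
#'   the segmentation, the breast mask, the thresholds actually used, and the
#'   preprocessed image.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' m <- measure_pd(ph$image, t2 = 0.675, t1 = 0.28, normalize = FALSE)
#' m
#' @export
measure_pd <- function(img, t2, t1 = NULL, alpha = 1, normalize = TRUE,
                       stretch = c(1, 99), invalid_regions = list(),
                       pectoral_boundary = NULL, connectivity = 8L) {
  stopifnot(is_mammogram(img))
  if (missing(t2)) stop("t2 must be set manually", call. = FALSE)
  work <- if (normalize) normalize_contrast(img, stretch[1L], stretch[2L]) else img
  if (is.null(t1)) t1 <- propose_t1(work)
  breast <- segment_breast(work, t1, connectivity = connectivity)

  invalid <- matrix(FALSE, nrow(work$pixels), ncol(work$pixels))
  for (reg in invalid_regions)
    invalid <- invalid | as_region_mask(reg, reference = work)
  if (!is.null(pectoral_boundary)) {
    pect <- pectoral_region(dim(work$pixels), work$chest_side, pectoral_boundary)
    invalid <- invalid | pect
  }

  dmap <- edge_distance_map(breast, work$chest_side, pectoral_boundary)
  work <- brightness_correction(work, dmap, alpha)
  seg <- classify_tissue(work, breast, t1 = t1, t2 = t2, invalidated = invalid)
  res <- compute_pd(seg)
  structure(
    list(density = res, segmentation = seg, breast = breast, image = work,
         t1 = t1, t2 = t2, alpha = alpha),
    class = "pd_measurement"
  )
}

# Pixels strictly on the chest side of the per-row pectoral boundary.
pectoral_region <- function(shape, chest_side, boundary) {
  out <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(shape[1L])) {
    b <- boundary[i]
    if (is.na(b) || b < 1) next
    if (chest_side == "left") out[i, seq_len(min(b, shape[2L]))] <- TRUE
    else out[i, seq.int(max(1L, b), shape[2L])] <- TRUE
  }
  out
}

#' @export
print.pd_measurement <- function(x, ...) {
  print(x$density)
  cat(sprintf("  breast %d px | alpha = %.2f\n", sum(x$breast), x$alpha))
  invisible(x)
}

#' @export
summary.pd_measurement <- function(object, ...) {
  x <- object
  cat("Semi-automated percent-density measurement\n")
  print(x$density)
  cat(sprintf("  breast area: %d px (%.1f%% of frame)\n", sum(x$breast),
              100 * mean(x$breast)))
  cat(sprintf("  invalidated: %d px\n", sum(x$segmentation$invalidated)))
  invisible(x)
}

#' Plot a PD measurement
#'
#' Shows the preprocessed image with the dense-tissue pixels and the breast
#' outline overlaid.
#'
#' @param x a `pd_measurement`.
#' @param ... ignored.
#' @export
plot.pd_measurement <- function(x, ...) {
  px <- x$image$pixels
  nr <- nrow(px); nc <- ncol(px)
  # image() draws column-major from bottom-left; transpose and flip rows
  graphics::image(seq_len(nc), seq_len(nr), t(px[nr:1, ]),
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "column", ylab = "row", useRaster = TRUE,
                  main = sprintf("PD = %.1f%%", x$density$pd_percent))
  dense <- which(x$segmentation$labels == 2L, arr.ind = TRUE)
  if (nrow(dense))
    graphics::points(dense[, 2L], nr + 1L - dense[, 1L], pch = ".",
                     col = grDevices::adjustcolor("red", 0.5))
  invisible(x)
}
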