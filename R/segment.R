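#' Propose the background/breast threshold T1
#'
#' Proposes the first of the pipeline's two thresholds: T1, separating
#' background from object pixels. The proposal uses Otsu's criterion (the
#' threshold maximizing between-class intensity variance) over a 256-bin
#' histogram of the full image; it is a *proposal* - the measurement functions
#' accept a user override, mirroring the semi-automatic workflow.
#'
#' @param img a [mammogram].
#' @param levels number of histogram bins.
#' @return proposed threshold intensity in `[0, 1]`; 0 with a warning for a
#'   constant image.
#' @export
propose_t1 <- function(img, levels = 256L) {
  stopifnot(is_mammogram(img))
  otsu_threshold(as.vector(img$pixels), levels = levels)
}

# Otsu's method on intensities in [0,1]: exhaustive search of the histogram
# cut maximizing w0*w1*(mu0-mu1)^2; returns the upper edge of the chosen bin
# so that `>= t` separates the classes.
otsu_threshold <- function(x, levels = 256L) {
  if (max(x) == min(x)) {
    warning("constant image: no bimodal structure, returning threshold 0")
    return(0)
  }
  breaks <- seq(0, 1, length.out = levels + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = levels)
  p <- counts / sum(counts)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[levels]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, levels)
  between[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  breaks[k + 1L]
}

# Connected-component labelling of a logical mask via the pixel adjacency
# graph (igraph handles the transitive closure). connectivity 4 or 8.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L)
    offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  row_i <- ((idx - 1L) %% nr) + 1L
  col_i <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (off in offsets) {
    r2 <- row_i + off[1L]; c2 <- col_i + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- idx[ok]
    hit <- mask[nb]
    edges <- c(edges, rbind(src[hit], nb[hit]))
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  lab[idx] <- match(memb[idx], unique(memb[idx]))
  lab
}

#' Segment the breast as the largest connected foreground object
#'
#' Thresholds the image at T1 (foreground = intensity `>= t1`), labels
#' connected components, and keeps only the largest one: mammograms usually
#' contain other bright objects (labels, markers) besides the breast, and the
#' biggest object is taken to be the breast while the rest are regions of
#' non-interest and are removed. Objects touching the breast cannot be
#' discarded this way; pass them to [invalidate()] instead.
#'
#' Ties on component size are broken deterministically in favour of the
#' component containing the smallest `(row, column)` pixel in lexicographic
#' order.
#'
#' @param img a [mammogram].
#' @param t1 background/object threshold in `[0, 1]`.
#' @param connectivity pixel adjacency, 8 (default, robust to thin skin-line
#'   connections) or 4.
#' @return logical breast mask (one connected component).
#' @export
segment_breast <- function(img, t1, connectivity = 8L) {
  stopifnot(is_mammogram(img))
  if (!is.numeric(t1) || length(t1) != 1L || t1 < 0 || t1 > 1)
    stop("t1 must be a single intensity in [0, 1]", call. = FALSE)
  fg <- img$pixels >= t1
  if (!any(fg))
    stop("no foreground pixels at t1 = ", format(t1),
         "; lower the threshold", call. = FALSE)
  lab <- label_components(fg, connectivity = as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  biggest <- max(sizes)
  tied <- which(sizes == biggest)
  if (length(tied) > 1L) {
    # smallest (row, col) lexicographically among pixels of tied components
    idx <- which(lab %in% tied)
    r <- ((idx - 1L) %% nrow(fg)) + 1L
    c <- ((idx - 1L) %/% nrow(fg)) + 1L
    first <- idx[order(r, c)][1L]
    keep <- lab[first]
  } else keep <- tied
  lab == keep
}

#' Remove user-invalidated regions from a mask
#'
#' Subtracts the union of user-supplied regions (labels touching the breast,
#' pectoral muscle, artifacts) from a mask. Invalidated pixels count as
#' neither dense nor fat tissue.
#'
#' @param mask logical mask.
#' @param user_regions a list of logical masks of the same shape (or a single
#'   mask).
#' @return the mask with all user regions removed.
#' @export
invalidate <- function(mask, user_regions = list()) {
  mask <- as_region_mask(mask)
  if (is.matrix(user_regions)) user_regions <- list(user_regions)
  for (reg in user_regions)
    mask <- mask & !as_region_mask(reg, reference = mask)
  mask
}

#' Classify breast pixels as dense or fat tissue
#'
#' Within the segmented breast (minus any invalidated pixels), pixels with
#' intensity `>= t2` are dense tissue (DT) and the rest fat tissue (FT);
#' everything outside is background. T2 is the manually set second threshold
#' of the pipeline; `t1 <= t2` is required so that every dense pixel is also a
#' breast pixel.
#'
#' @param img a [mammogram] (after any preprocessing).
#' @param breast logical breast mask from [segment_breast()].
#' @param t1,t2 the thresholds that produced the segmentation; `t1 <= t2`.
#' @param invalidated optional logical mask of pixels to exclude from both
#'   tissue classes.
#' @return an object of class `tissue_segmentation`: list with `labels`
#'   (integer matrix: 0 background, 1 fat, 2 dense), `t1`, `t2`,
#'   `invalidated`.
#' @export
classify_tissue <- function(img, breast, t1, t2, invalidated = NULL) {
  stopifnot(is_mammogram(img))
  breast <- as_region_mask(breast, reference = img)
  if (!any(breast)) stop("breast mask is empty", call. = FALSE)
  for (t in list(t1, t2))
    if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1)
      stop("thresholds must be single intensities in [0, 1]", call. = FALSE)
  if (t2 < t1)
    stop("t2 (", format(t2), ") must be >= t1 (", format(t1),
         "): a dense pixel must also be a breast pixel", call. = FALSE)
  if (is.null(invalidated))
    invalidated <- matrix(FALSE, nrow(img$pixels), ncol(img$pixels))
  invalidated <- as_region_mask(invalidated, reference = img)
  eligible <- breast & !invalidated
  labels <- matrix(0L, nrow(img$pixels), ncol(img$pixels))
  labels[eligible] <- 1L
  labels[eligible & img$pixels >= t2] <- 2L
  structure(list(labels = labels, t1 = t1, t2 = t2, invalidated = invalidated),
            class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<tissue_segmentation> t1 = %.4f, t2 = %.4f\n", x$t1, x$t2))
  cat(sprintf("  background %d | fat %d | dense %d | invalidated %d\n",
              n[1L], n[2L], n[3L], sum(x$invalidated)))
  invisible(x)
}
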