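# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic mammogram phantom
#'
#' Phantoms emulate the image properties the density pipeline relies on - a
#' breast-shaped bright object against a dark background, embedded dense
#' regions of *exactly* known area fraction, intensity falloff toward the
#' breast edge (the compressed-thickness effect), off-breast label artifacts,
#' and an optional pectoral wedge for MLO views - while providing exact
#' ground-truth masks. They are test instruments, not realistic X-ray
#' simulations.
#'
#' The default intensity levels (background 0.06, fat 0.50, dense 0.85) mimic
#' a processed digital mammogram: near-black background, mid-grey fat, bright
#' fibroglandular tissue, with gaps wide enough that midway thresholds
#' separate the classes exactly in the noiseless case.
#'
#' @param rows,cols image size in pixels.
#' @param view `"CC"` or `"MLO"`; MLO phantoms include a pectoral wedge.
#' @param background_level,fat_level,dense_level intensity levels, strictly
#'   increasing.
#' @param true_dense_fraction target dense share of the breast area, in
#'   `[0, 1)`; achieved exactly up to one pixel.
#' @param edge_falloff_alpha simulated thickness falloff in `(0, 1]`: breast
#'   intensities are multiplied by `a / (a + (1-a) d)` with `d` the
#'   chest-to-edge distance, i.e. unchanged at the chest side and dimmed by a
#'   factor `a` at the breast edge. This is the reciprocal of the correction
#'   profile of [brightness_correction()], so correcting with `alpha = a`
#'   restores a flat field exactly (uniformly scaled by `a`). `1` disables the
#'   falloff.
#' @param n_labels number of off-breast label artifacts (0-5).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian pixel noise
#'   (clipped to `[0, 1]`); 0 for a noiseless phantom.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   phantom.
#' @return an object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(rows = 256L, cols = 192L, view = c("CC", "MLO"),
                         background_level = 0.06, fat_level = 0.50,
                         dense_level = 0.85, true_dense_fraction = 0.20,
                         edge_falloff_alpha = 1, n_labels = 2L,
                         noise_sd = 0, seed = NULL) {
  view <- match.arg(view)
  if (rows < 32L || cols < 32L)
    stop("phantom must be at least 32 x 32", call. = FALSE)
  if (!(background_level < fat_level && fat_level < dense_level))
    stop("levels must satisfy background < fat < dense", call. = FALSE)
  if (true_dense_fraction < 0 || true_dense_fraction >= 1)
    stop("true_dense_fraction must lie in [0, 1)", call. = FALSE)
  if (edge_falloff_alpha <= 0 || edge_falloff_alpha > 1)
    stop("edge_falloff_alpha must lie in (0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_labels < 0L || n_labels > 5L)
    stop("n_labels must be between 0 and 5", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols), view = view,
                 background_level = background_level, fat_level = fat_level,
                 dense_level = dense_level,
                 true_dense_fraction = true_dense_fraction,
                 edge_falloff_alpha = edge_falloff_alpha,
                 n_labels = as.integer(n_labels), noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_spec")
}

#' Thresholds midway between a phantom's intensity levels
#'
#' T1 midway between background and fat, T2 midway between fat and dense -
#' the separating thresholds for a noiseless phantom.
#'
#' @param spec a [phantom_spec].
#' @return list with elements `t1`, `t2`.
#' @export
phantom_thresholds <- function(spec) {
  list(t1 = (spec$background_level + spec$fat_level) / 2,
       t2 = (spec$fat_level + spec$dense_level) / 2)
}

#' Generate a synthetic mammogram phantom with exact ground truth
#'
#' Renders a half-elliptical breast against the chest-side border (plus a
#' pectoral wedge for MLO), places dense tissue as random disks clipped
#' pixel-wise so the dense fraction of the breast hits the target exactly (up
#' to one pixel), applies the simulated edge falloff, adds clipped Gaussian
#' noise, and draws label artifacts fully outside the breast.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom`: list with
#'   \describe{
#'     \item{image}{the rendered [mammogram] (CC view, chest side left);}
#'     \item{breast}{ground-truth breast mask (pectoral wedge excluded);}
#'     \item{truth}{integer label matrix (0 background, 1 fat, 2 dense);}
#'     \item{label_mask}{mask of the off-breast label artifacts;}
#'     \item{pectoral_boundary}{per-row boundary column for MLO phantoms,
#'       otherwise `NULL`;}
#'     \item{dense_fraction}{achieved dense fraction of the breast;}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' ph <- generate_phantom(phantom_spec(true_dense_fraction = 0.3, seed = 1))
#' ph$dense_fraction
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("'spec' must come from phantom_spec()", call. = FALSE)
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  nr <- spec$rows; nc <- spec$cols
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  # half-ellipse against the left (chest) border
  r0 <- (nr + 1) / 2
  a <- 0.42 * nr
  b <- 0.75 * nc
  ellipse <- ((ii - r0) / a)^2 + ((jj - 1) / b)^2 <= 1

  pect_boundary <- NULL
  wedge <- matrix(FALSE, nr, nc)
  if (spec$view == "MLO") {
    ph <- round(0.45 * nr); pw <- round(0.35 * nc)
    pect_boundary <- rep(NA_integer_, nr)
    for (i in seq_len(ph)) {
      bnd <- round(pw * (1 - (i - 1) / (ph - 1)))
      pect_boundary[i] <- as.integer(bnd)
      if (bnd >= 1L) wedge[i, seq_len(bnd)] <- ellipse[i, seq_len(bnd)]
    }
  }
  breast <- ellipse & !wedge
  n_breast <- sum(breast)

  target <- round(spec$true_dense_fraction * n_breast)
  if (target > n_breast)
    stop("infeasible dense fraction: target exceeds breast area", call. = FALSE)
  dense <- matrix(FALSE, nr, nc)
  r_max <- max(4, 0.10 * min(nr, nc))
  placed <- 0L
  while (placed < target) {
    eligible <- which(breast & !dense)
    ctr <- eligible[sample.int(length(eligible), 1L)]
    cr <- ((ctr - 1L) %% nr) + 1L
    cc <- ((ctr - 1L) %/% nr) + 1L
    rad <- stats::runif(1L, 2.5, r_max)
    box_r <- max(1L, cr - ceiling(rad)):min(nr, cr + ceiling(rad))
    box_c <- max(1L, cc - ceiling(rad)):min(nc, cc + ceiling(rad))
    sub <- as.matrix(expand.grid(box_r, box_c))
    d2 <- (sub[, 1L] - cr)^2 + (sub[, 2L] - cc)^2
    keep <- sub[d2 <= rad^2, , drop = FALSE]
    lin <- (keep[, 2L] - 1L) * nr + keep[, 1L]
    new <- lin[breast[lin] & !dense[lin]]
    if (length(new) > target - placed) {
      # clip the last disk pixel-wise, innermost pixels first
      dd <- (((new - 1L) %% nr) + 1L - cr)^2 + (((new - 1L) %/% nr) + 1L - cc)^2
      new <- new[order(dd)][seq_len(target - placed)]
    }
    dense[new] <- TRUE
    placed <- placed + length(new)
  }

  px <- matrix(spec$background_level, nr, nc)
  px[breast] <- spec$fat_level
  px[dense] <- spec$dense_level
  if (spec$view == "MLO") px[wedge] <- 0.80   # pectoral muscle: bright

  if (spec$edge_falloff_alpha < 1) {
    af <- spec$edge_falloff_alpha
    dmap <- edge_distance_map(ellipse, "left", pect_boundary)
    idx <- which(!is.na(dmap))
    px[idx] <- px[idx] * af / (af + (1 - af) * dmap[idx])
  }

  # label artifacts: disjoint disks in the margin beyond the breast
  label_mask <- matrix(FALSE, nr, nc)
  if (spec$n_labels > 0L) {
    breast_cols <- which(colSums(ellipse) > 0L)
    margin_lo <- max(breast_cols) + 4L
    margin_hi <- nc - 2L
    if (margin_hi - margin_lo < 4L)
      stop("no room for label artifacts outside the breast", call. = FALSE)
    slot <- nr / spec$n_labels
    for (k in seq_len(spec$n_labels)) {
      cr <- round((k - 0.5) * slot + stats::runif(1L, -0.1, 0.1) * slot)
      cc <- round(stats::runif(1L, margin_lo + 2L, margin_hi - 2L))
      rad <- stats::runif(1L, 2, min(slot / 3, (margin_hi - margin_lo) / 3, 8))
      box_r <- max(1L, cr - ceiling(rad)):min(nr, cr + ceiling(rad))
      box_c <- max(margin_lo, cc - ceiling(rad)):min(margin_hi, cc + ceiling(rad))
      sub <- as.matrix(expand.grid(box_r, box_c))
      d2 <- (sub[, 1L] - cr)^2 + (sub[, 2L] - cc)^2
      keep <- sub[d2 <= rad^2, , drop = FALSE]
      lin <- (keep[, 2L] - 1L) * nr + keep[, 1L]
      px[lin] <- 0.95
      label_mask[lin] <- TRUE
    }
  }

  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(nr * nc, 0, spec$noise_sd)
  px <- pmin(pmax(px, 0), 1)

  truth <- matrix(0L, nr, nc)
  truth[breast] <- 1L
  truth[dense] <- 2L

  structure(
    list(image = mammogram(px, view = spec$view, laterality = "L",
                           chest_side = "left", bit_depth = 16L),
         breast = breast, truth = truth, label_mask = label_mask,
         pectoral_boundary = pect_boundary,
         dense_fraction = if (n_breast > 0) sum(dense) / n_breast else NA_real_,
         spec = spec),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, view %s, dense fraction %.4f (target %.4f)\n",
              x$spec$rows, x$spec$cols, x$spec$view, x$dense_fraction,
              x$spec$true_dense_fraction))
  invisible(x)
}

#' Write phantom artifacts to disk
#'
#' Emits the phantom image as PNG (8-bit, quantized), the ground-truth label
#' map and breast mask as PNGs, and a JSON sidecar recording the spec and the
#' achieved dense fraction.
#'
#' @param ph a `phantom` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param basename file stem for the four artifacts.
#' @return named character vector of written paths, invisibly.
#' @export
write_phantom <- function(ph, dir, basename = "phantom") {
  stopifnot(inherits(ph, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, paste0(basename, ".png")),
    truth = file.path(dir, paste0(basename, "_truth.png")),
    breast = file.path(dir, paste0(basename, "_breast.png")),
    spec = file.path(dir, paste0(basename, ".json"))
  )
  write_mammogram_png(ph$image, paths[["image"]])
  png::writePNG(ph$truth / 2, target = paths[["truth"]])
  write_mask_png(ph$breast, paths[["breast"]])
  meta <- c(unclass(ph$spec), list(dense_fraction_achieved = ph$dense_fraction))
  jsonlite::write_json(meta, paths[["spec"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Simulate paired rater readings of percent density
#'
#' Generates per-rater PD readings under an additive noise model around a
#' shared truth: `reading_r = clip(true_pd + bias_r + N(0, sd_r), 0, 100)`.
#' Used to exercise the agreement statistics with known properties (for two
#' raters with equal noise sd `s` around truth of variance `v`, the expected
#' concordance correlation is `v / (v + s^2)`, and the mean pairwise
#' difference equals the bias difference).
#'
#' @param true_pd vector of true PD values in `[0, 100]`.
#' @param rater_bias numeric vector, one additive bias per rater.
#' @param rater_sd numeric vector of per-rater noise standard deviations
#'   (>= 0), same length as `rater_bias`.
#' @param seed integer seed for reproducibility.
#' @return data frame with `image_id` and one `rater_<r>` column per rater.
#' @export
simulate_raters <- function(true_pd, rater_bias, rater_sd, seed = NULL) {
  if (length(rater_bias) != length(rater_sd))
    stop("rater_bias and rater_sd must have the same length", call. = FALSE)
  if (any(rater_sd < 0)) stop("rater_sd must be >= 0", call. = FALSE)
  n <- length(true_pd)
  with_seed(seed, {
    out <- data.frame(image_id = seq_len(n))
    for (r in seq_along(rater_bias)) {
      reading <- true_pd + rater_bias[r] + stats::rnorm(n, 0, rater_sd[r])
      out[[paste0("rater_", r)]] <- pmin(pmax(reading, 0), 100)
    }
    out
  })
}
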