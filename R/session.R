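#' Read a batch session file
#'
#' A session file is the non-interactive replacement for on-screen adjustment:
#' one YAML document holding a `defaults` block (alpha, normalize, stretch
#' percentiles, connectivity, optionally t2), an optional `rater_id`, and an
#' `images` list in which each entry records the per-image choices a reader
#' would have made interactively - `path` (PNG or DICOM by extension), `id`,
#' `view`, `laterality`, `chest_side`, a `t1` override, the manually set `t2`,
#' `alpha`, paths of invalidation mask PNGs (`invalid_masks`), and an optional
#' `pectoral_boundary` CSV (columns `row`, `col`). A session plus its images
#' fully determines the output.
#'
#' @param path path to the YAML session file.
#' @return the validated session as a list.
#' @export
read_session <- function(path) {
  if (!file.exists(path))
    stop("session file '", path, "' does not exist", call. = FALSE)
  s <- yaml::read_yaml(path)
  validate_session(s)
}

validate_session <- function(s) {
  if (is.null(s$images)) s$images <- list()
  if (!is.list(s$images))
    stop("malformed session: 'images' must be a list", call. = FALSE)
  defaults <- s$defaults
  if (is.null(defaults)) defaults <- list()
  bad <- character(0)
  for (i in seq_along(s$images)) {
    img <- s$images[[i]]
    if (is.null(img$path)) bad <- c(bad, sprintf("images[%d].path", i))
    if (is.null(img$t2) && is.null(defaults$t2))
      bad <- c(bad, sprintf("images[%d].t2", i))
    if (is.null(img$id))
      s$images[[i]]$id <- tools::file_path_sans_ext(basename(img$path %||% ""))
  }
  if (length(bad))
    stop("malformed session, missing key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  s$defaults <- defaults
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_pectoral_boundary <- function(path, n_rows) {
  tab <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(tab)))
    stop("pectoral boundary CSV needs columns 'row' and 'col'", call. = FALSE)
  out <- rep(NA_integer_, n_rows)
  out[tab$row] <- as.integer(tab$col)
  out
}

batch_columns <- c("image_id", "rater_id", "t1", "t2", "alpha", "dt_pixels",
                   "ft_pixels", "pd_percent", "pd_display", "boyd_category",
                   "status", "error")

#' Run a batch of density measurements
#'
#' Processes every image of a session through the full pipeline
#' ([measure_pd()]) and returns one row per image. Failures are isolated: an
#' unreadable file or a bad parameter yields an error row (status `"error"`,
#' message in `error`) and the run continues. PD is reported at full floating
#' precision (`pd_percent`) plus a 0.1%-rounded display value (`pd_display`).
#'
#' @param session a session list from [read_session()] or a path to a session
#'   YAML file.
#' @param out_csv optional path; when given, the results are also written as
#'   CSV.
#' @return data frame with columns `image_id, rater_id, t1, t2, alpha,
#'   dt_pixels, ft_pixels, pd_percent, pd_display, boyd_category, status,
#'   error`, plus attribute `n_failed`.
#' @export
run_batch <- function(session, out_csv = NULL) {
  if (is.character(session)) session <- read_session(session)
  else session <- validate_session(session)
  d <- session$defaults
  rater <- session$rater_id %||% "rater_1"
  rows <- vector("list", length(session$images))
  for (i in seq_along(session$images)) {
    e <- session$images[[i]]
    rows[[i]] <- tryCatch({
      img <- read_image_entry(e)
      masks <- lapply(e$invalid_masks %||% list(), read_mask_png)
      pect <- if (!is.null(e$pectoral_boundary))
        read_pectoral_boundary(e$pectoral_boundary, nrow(img$pixels))
      m <- measure_pd(
        img,
        t2 = e$t2 %||% d$t2,
        t1 = e$t1 %||% NULL,
        alpha = e$alpha %||% d$alpha %||% 1,
        normalize = isTRUE(e$normalize %||% d$normalize %||% TRUE),
        stretch = unlist(e$stretch %||% d$stretch %||% c(1, 99)),
        invalid_regions = masks,
        pectoral_boundary = pect,
        connectivity = e$connectivity %||% d$connectivity %||% 8L
      )
      data.frame(image_id = e$id, rater_id = rater, t1 = m$t1, t2 = m$t2,
                 alpha = m$alpha, dt_pixels = m$density$dt_pixels,
                 ft_pixels = m$density$ft_pixels,
                 pd_percent = m$density$pd_percent,
                 pd_display = round(m$density$pd_percent, 1),
                 boyd_category = as.character(m$density$boyd_category),
                 status = "ok", error = "")
    }, error = function(err) {
      data.frame(image_id = e$id, rater_id = rater, t1 = NA_real_,
                 t2 = NA_real_, alpha = NA_real_, dt_pixels = NA_integer_,
                 ft_pixels = NA_integer_, pd_percent = NA_real_,
                 pd_display = NA_real_, boyd_category = NA_character_,
                 status = "error", error = conditionMessage(err))
    })
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else as.data.frame(stats::setNames(
    list(character(), character(), numeric(), numeric(), numeric(), integer(),
         integer(), numeric(), numeric(), character(), character(), character()),
    batch_columns))
  attr(out, "n_failed") <- sum(out$status == "error")
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

read_image_entry <- function(e) {
  ext <- tolower(tools::file_ext(e$path))
  args <- list(e$path, view = e$view %||% "CC", laterality = e$laterality %||% "L",
               chest_side = e$chest_side %||% NULL)
  if (ext %in% c("dcm", "dicom")) do.call(read_mammogram_dicom, args)
  else do.call(read_mammogram_png, args)
}

#' Pairwise rater-agreement summaries
#'
#' Computes, for every pair of raters sharing at least 3 images, the
#' Bland-Altman difference summary (first-listed rater minus second), Lin's
#' CCC with its confidence interval, and the quadratic-weighted kappa after
#' binning the readings at the supplied cut-offs (default: the Boyd scale
#' cut-offs 0, 10, 25, 50, 75).
#'
#' @param readings long-format data frame with columns `image_id`, `rater_id`,
#'   `pd`, or a path to such a CSV (e.g. the output of [run_batch()] renamed,
#'   or pooled across raters).
#' @param cutoffs strictly increasing PD cut-offs for the kappa binning.
#' @param out_csv optional path to also write the summary as CSV.
#' @return data frame with one row per rater pair: `rater_a, rater_b, n,
#'   mean_diff, p05_diff, p95_diff, ccc, ccc_lo, ccc_hi, kappa, kappa_lo,
#'   kappa_hi`.
#' @export
run_agreement <- function(readings, cutoffs = c(0, 10, 25, 50, 75),
                          out_csv = NULL) {
  if (is.character(readings)) readings <- utils::read.csv(readings)
  need <- c("image_id", "rater_id", "pd")
  if (!all(need %in% names(readings)))
    stop("readings must have columns image_id, rater_id, pd", call. = FALSE)
  raters <- unique(readings$rater_id)
  if (length(raters) < 2L)
    stop("agreement needs readings from at least 2 raters", call. = FALSE)
  wide <- stats::reshape(readings[need], idvar = "image_id",
                         timevar = "rater_id", direction = "wide")
  k <- length(cutoffs) + 1L
  rows <- list()
  for (i in seq_len(length(raters) - 1L)) for (j in (i + 1L):length(raters)) {
    x <- wide[[paste0("pd.", raters[i])]]
    y <- wide[[paste0("pd.", raters[j])]]
    ok <- !(is.na(x) | is.na(y))
    if (sum(ok) < 3L) next
    x <- x[ok]; y <- y[ok]
    ba <- bland_altman(x, y)
    cc <- lin_ccc(x, y)
    kp <- weighted_kappa(categorize_cutoffs(x, cutoffs) - 1L,
                         categorize_cutoffs(y, cutoffs) - 1L, k = k)
    rows[[length(rows) + 1L]] <- data.frame(
      rater_a = raters[i], rater_b = raters[j], n = ba$n,
      mean_diff = ba$mean_diff, p05_diff = ba$p05_diff, p95_diff = ba$p95_diff,
      ccc = cc$ccc, ccc_lo = cc$ci[1L], ccc_hi = cc$ci[2L],
      kappa = kp$kappa, kappa_lo = kp$ci[1L], kappa_hi = kp$ci[2L])
  }
  if (!length(rows))
    stop("no rater pair shares at least 3 images", call. = FALSE)
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
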