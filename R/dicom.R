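#' Read mammogram pixel data from a DICOM file
#'
#' Minimal DICOM ingest covering what a density measurement needs: the pixel
#' data, the image-pixel module attributes (rows, columns, bits
#' allocated/stored, pixel representation), the photometric interpretation and
#' the modality rescale. Only uncompressed little-endian transfer syntaxes are
#' supported (Implicit VR `1.2.840.10008.1.2` and Explicit VR
#' `1.2.840.10008.1.2.1`); compressed syntaxes raise an explicit
#' unsupported-codec error. This is not a general DICOM reader: sequences are
#' skipped, presentation LUTs and overlays are ignored.
#'
#' Stored values are mapped through the rescale transform
#' `slope * stored + intercept`, then scaled linearly so the representable
#' range of the stored bit depth spans `[0, 1]`. MONOCHROME1 images (where low
#' stored values are bright) are inverted so that, as everywhere in this
#' package, higher intensity means denser tissue.
#'
#' @param path path to the DICOM file.
#' @inheritParams mammogram
#' @return a [mammogram] with `bit_depth` equal to the stored bit depth.
#' @export
read_mammogram_dicom <- function(path, view = "CC", laterality = "L",
                                 chest_side = NULL) {
  if (!file.exists(path)) stop("cannot read DICOM: '", path, "' does not exist",
                               call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  ds <- parse_dicom(raw, path)

  need <- c("rows", "cols", "bits_allocated", "pixel_data")
  missing <- need[!need %in% names(ds)]
  if (length(missing))
    stop("DICOM '", path, "' lacks required element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  bits_alloc <- ds$bits_allocated
  bits_stored <- if (!is.null(ds$bits_stored)) ds$bits_stored else bits_alloc
  if (!bits_alloc %in% c(8L, 16L))
    stop("unsupported BitsAllocated (", bits_alloc, ") in '", path, "'",
         call. = FALSE)
  signed <- isTRUE(ds$pixel_representation == 1L)

  n_px <- ds$rows * ds$cols
  size <- bits_alloc %/% 8L
  if (length(ds$pixel_data) < n_px * size)
    stop("DICOM '", path, "' pixel data truncated", call. = FALSE)
  vals <- read_pixel_words(ds$pixel_data[seq_len(n_px * size)], size, signed)

  slope <- if (!is.null(ds$rescale_slope)) ds$rescale_slope else 1
  intercept <- if (!is.null(ds$rescale_intercept)) ds$rescale_intercept else 0
  vals <- slope * vals + intercept
  # representable stored range, mapped through the same rescale
  lo_stored <- if (signed) -2^(bits_stored - 1) else 0
  hi_stored <- if (signed) 2^(bits_stored - 1) - 1 else 2^bits_stored - 1
  lo <- slope * lo_stored + intercept
  hi <- slope * hi_stored + intercept
  scaled <- (vals - lo) / (hi - lo)
  scaled <- pmin(pmax(scaled, 0), 1)

  photometric <- if (!is.null(ds$photometric)) ds$photometric else "MONOCHROME2"
  if (photometric == "MONOCHROME1") scaled <- 1 - scaled
  else if (photometric != "MONOCHROME2")
    stop("unsupported photometric interpretation '", photometric, "' in '",
         path, "'", call. = FALSE)

  px <- matrix(scaled, nrow = ds$rows, ncol = ds$cols, byrow = TRUE)
  mammogram(px, view = view, laterality = laterality, chest_side = chest_side,
            bit_depth = bits_stored)
}

read_pixel_words <- function(bytes, size, signed) {
  if (size == 1L && !signed) return(as.integer(bytes))
  readBin(bytes, "integer", n = length(bytes) %/% size, size = size,
          signed = signed || size > 2L, endian = "little")
}

uint16le <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
uint32le <- function(raw, at) {
  b <- as.numeric(raw[at + 0:3])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

# VRs carrying a 2-byte reserved field and 4-byte length in explicit VR
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Parses the data set into the handful of elements the reader uses.
parse_dicom <- function(raw, path) {
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
    # file meta group (0002,xxxx) is always explicit VR little endian
    ts <- "1.2.840.10008.1.2.1"
    repeat {
      if (pos + 7L > length(raw)) break
      group <- uint16le(raw, pos)
      if (group != 2L) break
      elem <- uint16le(raw, pos + 2L)
      vr <- rawToChar(raw[pos + 4:5])
      if (vr %in% LONG_VRS) { len <- uint32le(raw, pos + 8L); hdr <- 12L }
      else { len <- uint16le(raw, pos + 6L); hdr <- 8L }
      if (elem == 0x0010)
        ts <- sub("\\0+$", "", rawToChar(raw[pos + hdr + seq_len(len) - 1L]))
      pos <- pos + hdr + len
    }
    ts <- trimws(ts)
    if (ts == "1.2.840.10008.1.2") explicit <- FALSE
    else if (ts == "1.2.840.10008.1.2.1") explicit <- TRUE
    else stop("unsupported DICOM transfer syntax '", ts, "' in '", path,
              "' (only uncompressed little endian is supported)", call. = FALSE)
  } else {
    explicit <- NA  # no preamble: sniff from the first element
  }

  if (is.na(explicit)) {
    vr_guess <- rawToChar(raw[pos + 4:5])
    explicit <- grepl("^[A-Z]{2}$", vr_guess)
  }

  out <- list()
  while (pos + 7L <= length(raw)) {
    group <- uint16le(raw, pos)
    elem <- uint16le(raw, pos + 2L)
    if (explicit && group != 0xFFFE) {
      vr <- rawToChar(raw[pos + 4:5])
      if (vr %in% LONG_VRS) { len <- uint32le(raw, pos + 8L); hdr <- 12L }
      else { len <- uint16le(raw, pos + 6L); hdr <- 8L }
    } else {
      vr <- ""
      len <- uint32le(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) {           # undefined length: sequence or encapsulated
      if (group == 0x7FE0 && elem == 0x0010)
        stop("encapsulated (compressed) pixel data in '", path,
             "' is not supported", call. = FALSE)
      pos <- skip_undefined(raw, pos + hdr)
      next
    }
    start <- pos + hdr
    val <- raw[start + seq_len(len) - 1L]
    if (group == 0x0028) {
      if (elem == 0x0010) out$rows <- uint16le(val, 1L)
      else if (elem == 0x0011) out$cols <- uint16le(val, 1L)
      else if (elem == 0x0100) out$bits_allocated <- uint16le(val, 1L)
      else if (elem == 0x0101) out$bits_stored <- uint16le(val, 1L)
      else if (elem == 0x0103) out$pixel_representation <- uint16le(val, 1L)
      else if (elem == 0x0004) out$photometric <- trimws(rawToChar(val))
      else if (elem == 0x1052) out$rescale_intercept <- as.numeric(trimws(rawToChar(val)))
      else if (elem == 0x1053) out$rescale_slope <- as.numeric(trimws(rawToChar(val)))
    } else if (group == 0x7FE0 && elem == 0x0010) {
      out$pixel_data <- val
    }
    pos <- start + len
  }
  out
}

# Skip an undefined-length sequence up to and including its (FFFE,E0DD)
# delimiter; items themselves may have undefined length.
skip_undefined <- function(raw, pos) {
  while (pos + 7L <= length(raw)) {
    group <- uint16le(raw, pos)
    elem <- uint16le(raw, pos + 2L)
    len <- uint32le(raw, pos + 4L)
    if (group == 0xFFFE && elem == 0xE0DD) return(pos + 8L)
    if (group == 0xFFFE && elem == 0xE000 && len == 4294967295) pos <- pos + 8L
    else if (group == 0xFFFE && elem == 0xE00D) pos <- pos + 8L
    else pos <- pos + 8L + len
  }
  pos
}
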