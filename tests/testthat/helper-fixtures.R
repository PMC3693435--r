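# Fixtures built in code at test time: tiny images and synthetic DICOM byte
# streams (written to tempdir; nothing binary ships with the package).

blank_image <- function(value = 0, nr = 20, nc = 20) {
  mammogram(matrix(value, nr, nc))
}

# Image with a large "breast" block and a small detached "label" block.
two_blob_image <- function(nr = 32, nc = 32) {
  px <- matrix(0.05, nr, nc)
  px[4:24, 4:20] <- 0.6    # 21 x 17 = 357 px blob
  px[28:30, 28:30] <- 0.9  # 9 px label
  mammogram(px)
}

u16le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256))
u32le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256,
                              (v %/% 65536) %% 256, (v %/% 16777216) %% 256))

pad_even <- function(r, pad = as.raw(0)) if (length(r) %% 2) c(r, pad) else r

dcm_element_explicit <- function(group, elem, vr, value) {
  value <- pad_even(value, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(u16le(group), u16le(elem), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), u32le(length(value))) else u16le(length(value)),
    value)
}

dcm_element_implicit <- function(group, elem, value) {
  value <- pad_even(value)
  c(u16le(group), u16le(elem), u32le(length(value)), value)
}

# Build a single-frame grayscale DICOM file. `stored` is an integer matrix of
# stored pixel values (row-major image), written at `bits` allocated/stored.
write_test_dicom <- function(path, stored, bits = 16,
                             photometric = "MONOCHROME2",
                             slope = NULL, intercept = NULL,
                             transfer_syntax = "1.2.840.10008.1.2.1",
                             implicit_dataset = FALSE) {
  vals <- as.integer(t(stored))           # row-major stream
  pix <- if (bits == 8) as.raw(vals)
         else as.raw(as.vector(rbind(vals %% 256, vals %/% 256)))
  meta <- dcm_element_explicit(0x0002, 0x0010, "UI", charToRaw(transfer_syntax))
  el <- if (implicit_dataset) {
    function(g, e, vr, v) dcm_element_implicit(g, e, v)
  } else dcm_element_explicit
  body <- c(
    el(0x0028, 0x0004, "CS", charToRaw(photometric)),
    el(0x0028, 0x0010, "US", u16le(nrow(stored))),
    el(0x0028, 0x0011, "US", u16le(ncol(stored))),
    el(0x0028, 0x0100, "US", u16le(bits)),
    el(0x0028, 0x0101, "US", u16le(bits)),
    el(0x0028, 0x0103, "US", u16le(0))
  )
  if (!is.null(intercept))
    body <- c(body, el(0x0028, 0x1052, "DS", charToRaw(as.character(intercept))))
  if (!is.null(slope))
    body <- c(body, el(0x0028, 0x1053, "DS", charToRaw(as.character(slope))))
  body <- c(body, el(0x7FE0, 0x0010, "OW", pix))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), path)
  path
}

# Minimal 16-bit grayscale PNG writer for fixtures (package png reads but
# cannot write 16-bit). values: numeric matrix in [0,1].
crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))  # 0xEDB88320
      else bitwShiftR(bitwAnd(c, -2L), 1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(crc32_table[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

u32be <- function(v) {
  v <- as.numeric(v) %% 2^32
  as.raw(c(v %/% 16777216, (v %/% 65536) %% 256, (v %/% 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(as.numeric(crc32(body)) %% 2^32))
}

write_png16 <- function(values, path) {
  stored <- round(values * 65535)
  h <- nrow(stored); w <- ncol(stored)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16, 0, 0, 0, 0)))
  scan <- raw((2 * w + 1) * h)
  pos <- 1L
  for (i in seq_len(h)) {
    row <- as.integer(stored[i, ])
    scan[pos] <- as.raw(0)                      # filter: none
    scan[pos + seq_len(2 * w)] <- as.raw(as.vector(rbind(row %/% 256, row %% 256)))
    pos <- pos + 2L * w + 1L
  }
  idat <- memCompress(scan, type = "gzip")      # RFC 1950 zlib stream
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr), png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  path
}
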