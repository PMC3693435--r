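test_that("PNG intensities are scaled to [0,1] by full-scale division", {
  f <- tempfile(fileext = ".png")
  px <- matrix(0, 20, 20)
  px[1, 1] <- 1          # stored 255 at 8 bit
  px[2, 2] <- 128 / 255
  png::writePNG(px, f)
  img <- read_mammogram_png(f)
  expect_s3_class(img, "mammogram")
  expect_equal(img$bit_depth, 8L)
  expect_equal(img$pixels[1, 1], 1.0)
  expect_equal(img$pixels[1, 2], 0.0)
  expect_equal(img$pixels[2, 2], 128 / 255)
})

test_that("16-bit PNGs are read at 16-bit precision", {
  f <- tempfile(fileext = ".png")
  vals <- matrix(0, 20, 20)
  vals[1, 1] <- 32767 / 65535
  vals[1, 2] <- 1
  write_png16(vals, f)                 # helper encoder: png can't write 16-bit
  img <- read_mammogram_png(f)
  expect_equal(img$bit_depth, 16L)
  expect_equal(img$pixels[1, 1], 32767 / 65535, tolerance = 1e-12)
  expect_equal(img$pixels[1, 2], 1.0)
  # quantization-exact round trip at 16 bits
  set.seed(14)
  g <- matrix(runif(400), 20)
  write_png16(g, f)
  expect_equal(read_mammogram_png(f)$pixels, round(g * 65535) / 65535,
               tolerance = 1e-12)
})

test_that("multi-channel PNGs collapse only when channels agree", {
  f <- tempfile(fileext = ".png")
  g <- matrix(runif(20 * 20), 20)
  png::writePNG(array(rep(g, 3), dim = c(20, 20, 3)), f)
  img <- read_mammogram_png(f)
  expect_equal(img$pixels, matrix(round(g * 255) / 255, 20), tolerance = 1e-9)

  bad <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  png::writePNG(bad, f)
  expect_error(read_mammogram_png(f), "unequal colour channels")
})

test_that("mask round trips are bit-exact and degenerate masks are rejected", {
  f <- tempfile(fileext = ".png")
  m <- matrix(FALSE, 20, 20)
  write_mask_png(m, f)
  expect_identical(read_mask_png(f), m)

  set.seed(5)
  m2 <- matrix(runif(32 * 48) > 0.5, 32, 48)
  write_mask_png(m2, f)
  expect_identical(read_mask_png(f), m2)

  expect_error(write_mask_png(matrix(TRUE, 1, 40), f), "at least 16 x 16")
})

test_that("intensity scaling is monotone and image round trip is quantization-exact", {
  set.seed(11)
  px <- matrix(runif(20 * 20), 20)
  img <- mammogram(px)
  f <- tempfile(fileext = ".png")
  write_mammogram_png(img, f)
  back <- read_mammogram_png(f)
  expect_lt(max(abs(back$pixels - px)), 1 / 255 / 2 + 1e-12)
  # monotone: ordering of distinct 8-bit quantiles preserved
  a <- matrix(c(10, 200, rep(0, 398)) / 255, 20, 20)
  png::writePNG(a, f)
  r <- read_mammogram_png(f)$pixels
  expect_lt(r[1, 1], r[2, 1])
})

test_that("missing or invalid files give informative errors", {
  expect_error(read_mammogram_png(tempfile()), "does not exist")
  f <- tempfile(fileext = ".png")
  writeBin(as.raw(1:64), f)
  expect_error(read_mammogram_png(f), "cannot read PNG|not a PNG")
})

test_that("mammogram invariants are enforced", {
  expect_error(mammogram(matrix(0.5, 4, 40)), "at least 16 x 16")
  expect_error(mammogram(matrix(2, 20, 20)), "\\[0, 1\\]")
  img <- mammogram(matrix(0.5, 20, 20), laterality = "R")
  expect_equal(img$chest_side, "right")
  img <- mammogram(matrix(0.5, 20, 20), laterality = "L")
  expect_equal(img$chest_side, "left")
})

test_that("DICOM MONOCHROME2 maps max stored value to 1 and min to 0", {
  stored <- matrix(0L, 16, 16)
  stored[1, 1] <- 255L
  stored[16, 16] <- 100L
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 8)
  img <- read_mammogram_dicom(f)
  expect_equal(img$pixels[1, 1], 1.0)
  expect_equal(img$pixels[2, 1], 0.0)
  expect_equal(img$pixels[16, 16], 100 / 255)
  expect_equal(img$bit_depth, 8L)
})

test_that("DICOM MONOCHROME1 is inverted so stored minimum becomes 1", {
  stored <- matrix(255L, 16, 16)
  stored[3, 4] <- 0L
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 8,
                        photometric = "MONOCHROME1")
  img <- read_mammogram_dicom(f)
  expect_equal(img$pixels[3, 4], 1.0)
  expect_equal(img$pixels[1, 1], 0.0)
})

test_that("rescale slope/intercept are applied before scaling", {
  stored <- matrix(c(0L, 100L, 200L, 255L), 16, 16)
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 8,
                        slope = 2, intercept = -10)
  img <- read_mammogram_dicom(f)
  # affine rescale then affine [0,1] scaling = plain full-scale division
  expect_equal(img$pixels, matrix(c(0, 100, 200, 255), 16, 16) / 255,
               tolerance = 1e-12)
})

test_that("implicit VR little endian datasets parse too", {
  stored <- matrix(seq_len(256) - 1L, 16, 16)
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 16,
                        transfer_syntax = "1.2.840.10008.1.2",
                        implicit_dataset = TRUE)
  img <- read_mammogram_dicom(f)
  expect_equal(img$pixels, stored / 65535, tolerance = 1e-12)
})

test_that("unsupported transfer syntaxes raise an explicit codec error", {
  stored <- matrix(0L, 16, 16)
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 8,
                        transfer_syntax = "1.2.840.10008.1.2.4.70")
  expect_error(read_mammogram_dicom(f), "unsupported DICOM transfer syntax")
})

test_that("DICOM without pixel data errors by name", {
  f <- tempfile(fileext = ".dcm")
  meta <- dcm_element_explicit(0x0002, 0x0010, "UI",
                               charToRaw("1.2.840.10008.1.2.1"))
  body <- c(dcm_element_explicit(0x0028, 0x0010, "US", u16le(16)),
            dcm_element_explicit(0x0028, 0x0011, "US", u16le(16)),
            dcm_element_explicit(0x0028, 0x0100, "US", u16le(8)))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), f)
  expect_error(read_mammogram_dicom(f), "pixel_data")
})

test_that("DICOM frames round-trip through PNG up to quantization", {
  set.seed(21)
  stored <- matrix(sample.int(256, 20 * 24, replace = TRUE) - 1L, 20, 24)
  f <- write_test_dicom(tempfile(fileext = ".dcm"), stored, bits = 8)
  img <- read_mammogram_dicom(f)
  p <- tempfile(fileext = ".png")
  write_mammogram_png(img, p)
  back <- read_mammogram_png(p)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-12)  # 8-bit grid: exact
})
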