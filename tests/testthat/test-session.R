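write_session_yaml <- function(images, defaults = list(t2 = 0.675, alpha = 1,
                                                       normalize = FALSE),
                               rater = "rater_1") {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(defaults = defaults, rater_id = rater,
                        images = images), f)
  f
}

phantom_session <- function(fractions, dir = tempfile(), seed0 = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  images <- list()
  for (i in seq_along(fractions)) {
    ph <- generate_phantom(phantom_spec(true_dense_fraction = fractions[i],
                                        seed = seed0 + i))
    p <- file.path(dir, sprintf("ph%02d.png", i))
    write_mammogram_png(ph$image, p)
    images[[i]] <- list(id = sprintf("ph%02d", i), path = p, t1 = 0.28)
  }
  images
}

test_that("an empty session yields an empty CSV with the full header", {
  f <- write_session_yaml(list())
  out_csv <- tempfile(fileext = ".csv")
  res <- run_batch(f, out_csv = out_csv)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "n_failed"), 0L)
  back <- utils::read.csv(out_csv)
  expect_true(all(c("image_id", "pd_percent", "boyd_category", "status")
                  %in% names(back)))
  expect_equal(nrow(back), 0)
})

test_that("batch PD matches phantom ground truth within PNG quantization", {
  fr <- c(0.1, 0.3, 0.5)
  images <- phantom_session(fr)
  res <- run_batch(write_session_yaml(images))
  expect_equal(res$status, rep("ok", 3))
  expect_equal(res$pd_percent, 100 * fr, tolerance = 0.01)
  expect_equal(res$pd_display, round(res$pd_percent, 1))
  expect_equal(res$boyd_category, c("10-25%", "25-50%", "50-75%"))
})

test_that("one unreadable image gives an error row and the run continues", {
  images <- phantom_session(c(0.2, 0.4))
  images[[3]] <- list(id = "missing", path = tempfile(fileext = ".png"))
  res <- run_batch(write_session_yaml(images))
  expect_equal(sum(res$status == "ok"), 2)
  expect_equal(sum(res$status == "error"), 1)
  expect_match(res$error[res$status == "error"], "does not exist")
  expect_equal(attr(res, "n_failed"), 1L)
})

test_that("malformed sessions list the offending keys", {
  f <- write_session_yaml(list(list(id = "x", path = "a.png")),
                          defaults = list(alpha = 1))
  expect_error(run_batch(f), "images\\[1\\]\\.t2")
})

test_that("re-running an identical session gives byte-identical CSV bodies", {
  images <- phantom_session(c(0.15, 0.35), seed0 = 55)
  f <- write_session_yaml(images)
  c1 <- tempfile(fileext = ".csv"); c2 <- tempfile(fileext = ".csv")
  run_batch(f, out_csv = c1)
  run_batch(f, out_csv = c2)
  expect_identical(readLines(c1), readLines(c2))
})

test_that("invalidation masks and per-image overrides flow through the batch", {
  ph <- generate_phantom(phantom_spec(true_dense_fraction = 0.3, seed = 4))
  dir <- tempfile(); dir.create(dir)
  img_path <- file.path(dir, "a.png")
  write_mammogram_png(ph$image, img_path)
  inv <- matrix(FALSE, ph$spec$rows, ph$spec$cols)
  inv[, 1:10] <- TRUE
  inv_path <- file.path(dir, "inv.png")
  write_mask_png(inv, inv_path)
  images <- list(list(id = "a", path = img_path, t1 = 0.28, t2 = 0.675,
                      invalid_masks = list(inv_path)))
  res <- run_batch(write_session_yaml(images))
  expect_equal(res$status, "ok")
  expect_lt(res$dt_pixels + res$ft_pixels, sum(ph$breast))
})

test_that("duplicated rater columns give CCC 1 and zero mean difference", {
  pd <- withr::with_seed(6, runif(12, 5, 60))
  readings <- data.frame(image_id = rep(1:12, 2),
                         rater_id = rep(c("r1", "r2"), each = 12),
                         pd = rep(pd, 2))
  out <- run_agreement(readings)
  expect_equal(out$ccc, 1)
  expect_equal(out$mean_diff, 0)
  expect_equal(out$kappa, 1)
})

test_that("agreement pipeline equals direct library calls on simulated raters", {
  truth <- withr::with_seed(18, runif(60, 0, 60))
  rr <- simulate_raters(truth, c(0, -1.6, 2), c(2, 2, 3), seed = 18)
  readings <- data.frame(
    image_id = rep(rr$image_id, 3),
    rater_id = rep(c("rater_1", "rater_2", "rater_3"), each = nrow(rr)),
    pd = c(rr$rater_1, rr$rater_2, rr$rater_3))
  out <- run_agreement(readings)
  expect_equal(nrow(out), 3)

  row12 <- out[out$rater_a == "rater_1" & out$rater_b == "rater_2", ]
  expect_equal(row12$ccc, lin_ccc(rr$rater_1, rr$rater_2)$ccc)
  expect_equal(row12$mean_diff, bland_altman(rr$rater_1, rr$rater_2)$mean_diff)
  cuts <- c(0, 10, 25, 50, 75)
  expect_equal(row12$kappa,
               weighted_kappa(categorize_cutoffs(rr$rater_1, cuts) - 1L,
                              categorize_cutoffs(rr$rater_2, cuts) - 1L,
                              k = 6)$kappa)
})

test_that("fewer than two raters or disjoint image sets are usage errors", {
  readings <- data.frame(image_id = 1:5, rater_id = "r1", pd = 1:5)
  expect_error(run_agreement(readings), "at least 2 raters")
  disjoint <- data.frame(image_id = c(1:5, 6:10),
                         rater_id = rep(c("r1", "r2"), each = 5),
                         pd = runif(10, 0, 50))
  expect_error(run_agreement(disjoint), "shares at least 3")
})

test_that("the command-line driver runs the batch end to end", {
  script <- system.file("cli", "mammodensity.R", package = "mammodensity")
  images <- phantom_session(0.25, seed0 = 71)
  f <- write_session_yaml(images)
  out_csv <- tempfile(fileext = ".csv")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  res <- suppressWarnings(system2("Rscript", c(script, "density", f,
                                               "--out", out_csv),
                                  stdout = TRUE, stderr = TRUE,
                                  env = paste0("R_LIBS=", libs)))
  expect_true(file.exists(out_csv))
  got <- utils::read.csv(out_csv)
  expect_equal(got$status, "ok")
  expect_equal(got$pd_percent, 25, tolerance = 0.05)
})
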