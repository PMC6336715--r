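g1 <- pixel_geometry(1)

ten_regions <- function(side_um = 12) {
  # rows avoid 50..60 where tests plant their fibers
  background_regions(y0 = rep(c(1, 14, 27, 75, 88), 2),
                     x0 = rep(c(1, 41), each = 5), side_um = side_um)
}

test_that("background_stats pools pixels over all regions", {
  pl <- plane_image(matrix(57, 100, 100), 8L, g1)
  s <- background_stats(pl, ten_regions())
  expect_equal(s$mean, 57)
  expect_equal(s$sd, 0)
  expect_identical(s$n_px, 10L * 144L)     # 12 x 12 px at 1 um/px

  # equal counts of 0s and 2s -> mean 1, SD 1
  px <- matrix(0, 100, 100)
  px[, seq(2, 100, by = 2)] <- 2
  s2 <- background_stats(plane_image(px, 8L, g1), ten_regions())
  expect_equal(s2$mean, 1)
  expect_equal(s2$sd, 1)

  expect_error(background_stats(pl, ten_regions()[1:9, ]), "expected 10")
  expect_silent(background_stats(pl, ten_regions()[1:3, ], n_required = 3))
  far <- background_regions(95, 95)
  expect_error(background_stats(pl, far, n_required = 1), "out of bounds")

  over <- background_regions(c(1, 6), c(1, 6))
  expect_warning(s3 <- background_stats(pl, over, n_required = 2), "overlap")
  expect_identical(s3$n_px, length(unique(c(outer(1:12, 0:11 * 100, "+"),
                                            outer(6:17, 5:16 * 100, "+")))))
})

test_that("pooled statistics match explicit pixel enumeration", {
  set.seed(21)
  for (i in 1:25) {
    px <- matrix(sample(0:255, 60 * 60, replace = TRUE), 60, 60)
    pl <- plane_image(px, 8L, g1)
    reg <- background_regions(sample(1:48, 10, replace = TRUE),
                              sample(1:48, 10, replace = TRUE))
    s <- suppressWarnings(background_stats(pl, reg))
    o <- enum_background_stats(px, reg, 12, 12)
    expect_equal(s$mean, o$mean)
    expect_equal(s$sd, o$sd)
  }
})

test_that("region pixel extent follows the geometry, minimum 1 px", {
  pl <- plane_image(matrix(3, 40, 40), 8L, pixel_geometry(0.83))
  s <- background_stats(pl, background_regions(1, 1), n_required = 1)
  expect_identical(s$n_px, 14L * 14L)      # round(12 / 0.83) = 14
  tiny <- plane_image(matrix(3, 4, 4), 8L, pixel_geometry(20))
  s2 <- background_stats(tiny, background_regions(2, 2), n_required = 1)
  expect_identical(s2$n_px, 1L)
})

test_that("quantify_fibers thresholds at mean + k*SD of the background", {
  pl <- plane_image(matrix(100, 100, 100), 8L, g1)
  r <- quantify_fibers(pl, ten_regions())
  expect_equal(r$threshold, 100)
  expect_equal(r$fiber_area_um2, 0)        # strict > on a constant image

  # constant background + planted fiber, zero background SD
  px <- matrix(50, 100, 100)
  fib <- matrix(FALSE, 100, 100)
  for (x in 10:89) fib[50 + round(4 * sin(x / 7)), x] <- TRUE
  px[fib] <- 200
  r2 <- quantify_fibers(plane_image(px, 8L, g1), ten_regions())
  expect_equal(r2$background_sd, 0)
  expect_equal(r2$fiber_area_um2, sum(fib))
  expect_identical(r2$fiber_mask$on, fib)

  # k = 0 with zero-SD background counts every pixel above the mean
  r3 <- quantify_fibers(plane_image(px, 8L, g1), ten_regions(), k = 0)
  expect_equal(r3$fiber_area_um2, sum(fib))
})

test_that("noisy background with planted fiber recovers its area closely", {
  set.seed(77)
  px <- matrix(pmax(0, round(stats::rnorm(120 * 120, 100, 5))), 120, 120)
  fib <- matrix(FALSE, 120, 120)
  fib[60, 21:100] <- TRUE                  # 80 px planted fiber
  px[fib] <- 200
  regions <- background_regions(y0 = rep(c(1, 15, 29, 43, 99), 2),
                                x0 = rep(c(1, 105), each = 5))
  r <- quantify_fibers(plane_image(px, 8L, g1), regions)
  expect_gte(r$fiber_area_um2, 78)
  expect_lte(r$fiber_area_um2, 82)
})

test_that("fiber area is non-increasing in k", {
  set.seed(5)
  px <- matrix(sample(0:120, 80 * 80, replace = TRUE), 80, 80)
  pl <- plane_image(px, 8L, g1)
  reg <- background_regions(sample(1:60, 10, replace = TRUE),
                            sample(1:60, 10, replace = TRUE))
  areas <- vapply(c(0, 1, 2, 4, 6), function(k) {
    suppressWarnings(quantify_fibers(pl, reg, k = k))$fiber_area_um2
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("propose_regions returns valid, low-mean, non-overlapping tiles", {
  px <- matrix(200, 60, 60)
  px[25:36, 1:60] <- 0                      # a dark band
  pl <- plane_image(px, 8L, g1)
  reg <- propose_regions(pl, n = 5)
  s <- background_stats(pl, reg, n_required = 5)
  expect_equal(s$mean, 0)                  # all proposals inside the band
  expect_identical(s$n_px, 5L * 144L)      # no overlap
})

test_that("quantify_batch writes a report row and mask per image", {
  d <- withr::local_tempdir()
  set.seed(8)
  for (i in 1:3) {
    px <- matrix(20, 64, 64)
    px[30 + i, 10:(30 + 5 * i)] <- 180
    write_plane(plane_image(px, 8L, g1), file.path(d, sprintf("m%d.tif", i)))
    utils::write.csv(data.frame(y0 = c(1, 1, 1, 14, 14, 14, 50, 50, 50, 27),
                                x0 = c(1, 14, 50, 1, 14, 50, 1, 14, 50, 50)),
                     file.path(d, sprintf("m%d_regions.csv", i)),
                     row.names = FALSE)
  }
  res <- quantify_batch(d, run_date = as.Date("2020-06-02"))
  expect_identical(nrow(res$report), 3L)
  expect_true(all(res$report$status == "ok"))
  expect_length(res$mask_paths, 3L)
  expect_true(all(file.exists(res$mask_paths)))
  expect_identical(basename(dirname(res$report_path)),
                   "DEFiNE_Quantified_Fibers_06-02-2020")
  expect_equal(res$report$fiber_area_um2, c(26, 31, 36), tolerance = 1e-6)

  # deterministic rerun: byte-identical report
  first <- readLines(res$report_path)
  res2 <- quantify_batch(d, run_date = as.Date("2020-06-02"))
  expect_identical(readLines(res2$report_path), first)

  # an image without regions is skipped and flagged
  px <- matrix(10, 64, 64)
  write_plane(plane_image(px, 8L, g1), file.path(d, "noregions.tif"))
  expect_warning(res3 <- quantify_batch(d, run_date = as.Date("2020-06-02")),
                 "no background regions")
  expect_identical(res3$n_skipped, 1L)
  expect_identical(res3$report$status[res3$report$image == "noregions"],
                   "no_regions")
})
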