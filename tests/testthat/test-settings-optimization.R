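g1 <- pixel_geometry(1)

# stack with one removable disk and one wide "fiber" bar that default
# criteria also remove (the mistake the user will mark)
optimization_fixture <- function() {
  disk <- disk_mask(48, 48, 14, 14, 4)
  bar <- matrix(FALSE, 48, 48); bar[34:36, 10:21] <- TRUE  # 3 x 12 bar
  px <- matrix(0, 48, 48)
  px[disk] <- 200
  px[bar] <- 180
  vox <- array(0, dim = c(48, 48, 1, 2))
  vox[, , 1, 1] <- px
  st <- image_stack(vox, 8L, g1, channel_names = c("sig", "AF"),
                    af_channel = 2L)
  list(stack = st, disk = disk, bar = bar)
}

test_that("preview reports removed particles with their measurements", {
  fx <- optimization_fixture()
  pv <- preview_processing(fx$stack)
  expect_s3_class(pv, "clean_preview")
  removed <- pv$removed_particles
  expect_gte(nrow(removed), 2L)            # disk and bar both removed
  rm_px <- unlist(removed$pixels)
  expect_true(all(which(fx$disk) %in% rm_px))
  expect_true(all(which(fx$bar) %in% rm_px))
  expect_true(all(pv$after$pixels[fx$bar] == 0))
  expect_identical(pv$before$pixels, fx$stack$voxels[, , 1, 1])

  # artifact-free stack: nothing removed, before == after
  vox <- array(0, dim = c(20, 20, 1, 2))
  vox[10, 3:17, 1, 1] <- 150
  st <- image_stack(vox, 8L, g1, af_channel = 2L)
  pv0 <- preview_processing(st)
  expect_identical(nrow(pv0$removed_particles), 0L)
  expect_identical(pv0$before$pixels, pv0$after$pixels)

  # rerun determinism
  pv2 <- preview_processing(fx$stack)
  expect_identical(pv$removed_particles, pv2$removed_particles)
})

test_that("minimal tightening picks the smaller relative change", {
  crit <- data.frame(min_area_um2 = 25, min_circularity = 0.32)
  up <- axdefine:::tighten_criteria(crit, area = 30, circ = 0.35)
  # area route: 30.3 (rel 0.212); circularity route: 0.3535 (rel 0.105)
  expect_equal(up$criteria$min_area_um2, 25)
  expect_equal(up$criteria$min_circularity, 0.35 * 1.01)
  # and the particle no longer matches
  expect_false(30 >= up$criteria$min_area_um2 &&
                 0.35 >= up$criteria$min_circularity)

  # when the circularity route would exceed 1, the area route is forced
  crit2 <- data.frame(min_area_um2 = 5, min_circularity = 0.995)
  up2 <- axdefine:::tighten_criteria(crit2, area = 6, circ = 0.999)
  expect_equal(up2$criteria$min_area_um2, 6 * 1.01)
  expect_equal(up2$criteria$min_circularity, 0.995)
})

test_that("protecting a marked fiber keeps it through a re-run", {
  fx <- optimization_fixture()
  pv <- preview_processing(fx$stack)
  seed <- which(fx$bar, arr.ind = TRUE)[5, ]
  mk <- markings("wrongly_removed_fiber", y = seed[1], x = seed[2])
  rec <- recommend_settings(pv, mk)
  expect_s3_class(rec, "clean_settings")
  expect_identical(nrow(rec$criteria), 5L)
  expect_true(all(rec$criteria$min_circularity <= 1))

  pv2 <- preview_processing(fx$stack, rec)
  expect_true(all(pv2$after$pixels[fx$bar] == 180))  # bar survives
  expect_true(all(pv2$after$pixels[fx$disk] == 0))   # disk still removed
})

test_that("markings that hit nothing are ignored with a note", {
  fx <- optimization_fixture()
  pv <- preview_processing(fx$stack)
  rec <- recommend_settings(pv, markings("wrongly_removed_fiber", 2, 2))
  expect_equal(rec$criteria, pv$settings$criteria)
  expect_match(attr(rec, "notes"), "ignored")
  expect_error(recommend_settings(pv, markings("wrongly_removed_fiber",
                                               integer(0), integer(0))),
               "marking")
})

test_that("a sub-threshold AF-visible artifact lowers af_k", {
  # AF slice: half 0 / half 20 -> mean 10, SD 10; artifact AF value 18
  # is captured only below k = 0.8
  af <- matrix(c(0, 20), 40, 40)
  blob <- disk_mask(40, 40, 20, 20, 3)
  af[blob] <- 18
  sig <- matrix(0, 40, 40)
  bright <- matrix(FALSE, 40, 40); bright[5, 5:30] <- TRUE
  sig[bright] <- 220                        # keeps the blob sub-threshold
  sig[blob] <- 30
  vox <- array(0, dim = c(40, 40, 1, 2))
  vox[, , 1, 1] <- sig
  vox[, , 1, 2] <- af
  st <- image_stack(vox, 8L, g1, af_channel = 2L)

  pv <- preview_processing(st)
  expect_true(any(pv$after$pixels[blob] > 0))  # artifact was kept
  seedpx <- c(20, 20)
  rec <- recommend_settings(pv, markings("wrongly_kept_artifact",
                                         seedpx[1], seedpx[2]))
  expect_lt(rec$af_k, 1)
  expect_gte(rec$af_k, 0.5)
  # with the recommendation the blob is subtracted
  out <- clean_images(st, rec)
  expect_true(all(out$sig$pixels[blob] == 0))
})

test_that("a morphology-visible artifact loosens one criterion", {
  # bright compact blob too small for any default gate at its circularity
  blob <- disk_mask(40, 40, 20, 20, 1.6)    # ~8 px, circ ~1
  sig <- matrix(0, 40, 40)
  sig[blob] <- 200
  fib <- matrix(FALSE, 40, 40); fib[35, 3:38] <- TRUE
  sig[fib] <- 150
  vox <- array(0, dim = c(40, 40, 1, 2))
  vox[, , 1, 1] <- sig
  st <- image_stack(vox, 8L, g1, af_channel = 2L)
  strict <- clean_settings(criteria = list(c(40, 0.17), c(30, 0.9)))
  pv <- preview_processing(st, strict)
  expect_true(any(pv$after$pixels[blob] > 0))
  rec <- recommend_settings(pv, markings("wrongly_kept_artifact", 20, 20))
  expect_match(paste(attr(rec, "notes"), collapse = " "), "loosening")
  out <- clean_images(st, rec)
  expect_true(all(out[[1]]$pixels[blob] == 0))
  expect_true(all(out[[1]]$pixels[fib] == 150))  # fiber untouched
})

test_that("markings round-trip through CSV", {
  d <- withr::local_tempdir()
  mk <- markings(c("wrongly_removed_fiber", "wrongly_kept_artifact"),
                 y = c(3, 7), x = c(4, 8))
  utils::write.csv(mk, file.path(d, "marks.csv"), row.names = FALSE)
  rt <- read_markings(file.path(d, "marks.csv"))
  expect_equal(rt$kind, mk$kind)
  expect_equal(rt$y, mk$y)
})
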