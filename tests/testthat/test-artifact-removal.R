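g1 <- pixel_geometry(1)

test_that("clean_settings validates its invariants", {
  s <- clean_settings()
  expect_identical(nrow(s$criteria), 5L)
  expect_equal(s$criteria$min_area_um2, c(40, 25, 15, 10, 5))
  expect_equal(s$criteria$min_circularity, c(0.17, 0.32, 0.40, 0.70, 0.80))
  expect_equal(s$iteration_ks, c(1.5, 2, 2.5, 3))
  expect_equal(c(s$af_k, s$small_max_area_um2, s$small_k), c(1, 1, 1))
  expect_equal(s$small_circ_range, c(0.99, 1))
  expect_error(clean_settings(criteria = data.frame(
    min_area_um2 = 1:6, min_circularity = rep(0.5, 6))), "1 and 5")
  expect_error(clean_settings(iteration_ks = c(2, 1.5)), "increasing")
  expect_error(clean_settings(small_circ_range = c(0.5, 1.2)), "within")
})

test_that("settings round-trip through YAML with partial overrides", {
  d <- withr::local_tempdir()
  s <- clean_settings(criteria = list(c(30, 0.2), c(8, 0.9)), af_k = 1.5,
                      use_af_subtraction = FALSE)
  write_clean_settings(s, file.path(d, "s.yml"))
  rt <- read_clean_settings(file.path(d, "s.yml"))
  expect_equal(rt$criteria, s$criteria)
  expect_equal(rt$af_k, 1.5)
  expect_false(rt$use_af_subtraction)
  # partial file: only one key overridden
  yaml::write_yaml(list(af_k = 2.5), file.path(d, "p.yml"))
  p <- read_clean_settings(file.path(d, "p.yml"))
  expect_equal(p$af_k, 2.5)
  expect_equal(p$criteria, clean_settings()$criteria)
})

test_that("large-particle removal deletes a compact disk, keeps a fiber", {
  # disk of ~50 um^2 on zero background: compact, removable
  disk <- disk_mask(40, 40, 20, 20, 4)
  pl <- plane_with(40, 40, list(mask = disk, value = 200))
  parts <- label_particles(binarize(pl, sd_threshold(pl$pixels, 1.5),
                                    pl$geometry))
  expect_gte(parts$area_um2, 40)           # meets the 40/0.17 gate
  expect_gte(parts$circularity, 0.8)       # and the 5/0.80 gate
  out <- remove_large_particles(pl)
  expect_true(all(out$pixels[disk] == 0))

  # thin 30 um^2 fiber: low circularity, fully retained
  fib <- matrix(FALSE, 40, 40)
  for (x in 5:34) fib[20 + round(3 * sin(x / 4)), x] <- TRUE
  plf <- plane_with(40, 40, list(mask = fib, value = 200))
  pf <- label_particles(binarize(plf, sd_threshold(plf$pixels, 1.5),
                                 plf$geometry))
  expect_lte(pf$circularity, 0.17)
  outf <- remove_large_particles(plf)
  expect_identical(outf$pixels, plf$pixels)

  # all-zero image is a no-op (strict threshold -> empty mask)
  z <- plane_image(matrix(0, 8, 8), 8L, g1)
  expect_identical(remove_large_particles(z)$pixels, z$pixels)
  expect_error(remove_large_particles(pl, criteria = data.frame(
    min_area_um2 = numeric(0), min_circularity = numeric(0))), "criterion")
})

test_that("stack-level removal is per-plane and exempts the AF channel", {
  disk <- disk_mask(40, 40, 20, 20, 4)
  fib <- matrix(FALSE, 40, 40)
  for (x in 5:34) fib[20 + round(3 * sin(x / 4)), x] <- TRUE
  d <- matrix(0, 40, 40); d[disk] <- 200
  f <- matrix(0, 40, 40); f[fib] <- 180

  st <- stack_from_slices(list(d, f))
  out <- remove_large_particles_stack(st)
  expect_true(all(out$voxels[, , 1, 1] == 0))
  expect_identical(out$voxels[, , 2, 1], f)

  # AF channel passes through even though it holds a removable disk
  vox <- array(0, dim = c(40, 40, 1, 2))
  vox[, , 1, 1] <- f
  vox[, , 1, 2] <- d
  st2 <- image_stack(vox, 8L, g1, af_channel = 2L)
  out2 <- remove_large_particles_stack(st2)
  expect_identical(out2$voxels[, , 1, 2], d)

  # single-slice stack agrees with the plane-level operation
  st3 <- stack_from_slices(list(d))
  expect_identical(remove_large_particles_stack(st3)$voxels[, , 1, 1],
                   remove_large_particles(plane_image(d, 8L, g1))$pixels)
})

test_that("AF subtraction zeroes exactly the AF-bright pixels per slice", {
  blob <- disk_mask(32, 32, 16, 16, 5)
  fib <- matrix(FALSE, 32, 32); fib[16, ] <- TRUE
  vox <- array(0, dim = c(32, 32, 2, 2))
  sig <- matrix(0, 32, 32); sig[fib] <- 150
  vox[, , 1, 1] <- sig; vox[, , 2, 1] <- sig
  af1 <- matrix(0, 32, 32); af1[blob] <- 120
  vox[, , 1, 2] <- af1                      # slice 2 AF stays blank
  st <- image_stack(vox, 8L, g1, af_channel = 2L)

  out <- subtract_autofluorescence(st, af_k = 1)
  th <- sd_threshold(af1, 1)
  on <- af1 > th
  expect_true(all(out$voxels[, , 1, 1][on] == 0))
  expect_identical(out$voxels[, , 1, 1][!on], sig[!on])
  expect_identical(out$voxels[, , 2, 1], sig)      # blank AF slice: no-op
  expect_identical(out$voxels[, , , 2], st$voxels[, , , 2])  # AF unchanged

  # huge af_k: nothing exceeds the threshold
  expect_identical(subtract_autofluorescence(st, af_k = 1e6)$voxels,
                   st$voxels)
  # all-zero AF channel: no-op
  vox[, , 1, 2] <- 0
  st0 <- image_stack(vox, 8L, g1, af_channel = 2L)
  expect_identical(subtract_autofluorescence(st0, 1)$voxels[, , , 1],
                   st0$voxels[, , , 1])
  # unset AF channel: instructive error
  stn <- stack_from_slices(list(sig))
  expect_error(subtract_autofluorescence(stn, 1), "use_af_subtraction")
})

test_that("max_intensity_projection is the exact integer max over z", {
  st <- stack_from_slices(list(matrix(1, 1, 1), matrix(3, 1, 1),
                               matrix(2, 1, 1)))
  expect_equal(max_intensity_projection(st, 1)$pixels, matrix(3, 1, 1))
  one <- stack_from_slices(list(matrix(0:3, 2, 2)))
  expect_equal(max_intensity_projection(one, 1)$pixels, matrix(0:3, 2, 2))

  set.seed(9)
  vox <- array(sample(0:65535, 6 * 5 * 10, replace = TRUE),
               dim = c(6, 5, 10, 1))
  st <- image_stack(vox, 16L, g1)
  expect_equal(max_intensity_projection(st, 1)$pixels, loop_mip(vox, 1))
})

test_that("small-particle removal deletes perfect specks only", {
  speck <- matrix(FALSE, 20, 20); speck[5, 5] <- TRUE
  line <- matrix(FALSE, 20, 20); line[12, 4:8] <- TRUE
  pl <- plane_with(20, 20, list(mask = speck, value = 200),
                   list(mask = line, value = 200))
  out <- remove_small_particles(pl)
  expect_identical(out$pixels[5, 5], 0)            # 1 um^2, circ 1: removed
  expect_identical(out$pixels[line], pl$pixels[line])  # 5 um^2: kept

  # at 0.208 um/px (40x sampling) a 2x2 speck is ~0.17 um^2 and compact
  g40 <- pixel_geometry(0.208)
  sp2 <- matrix(FALSE, 20, 20); sp2[10:11, 10:11] <- TRUE
  pl2 <- plane_image(matrix(0, 20, 20), 8L, g40)
  pl2$pixels[sp2] <- 150
  parts <- label_particles(binarize(pl2, sd_threshold(pl2$pixels, 1),
                                    g40))
  expect_lte(parts$area_um2, 1)
  expect_gte(parts$circularity, 0.99)
  out2 <- remove_small_particles(pl2)
  expect_true(all(out2$pixels == 0))
})

test_that("clean_images composes the stages and excludes the AF output", {
  sc <- overlap_scenario()
  mips <- clean_images(sc$stack)
  expect_named(mips, "signal")
  fm <- apply(sc$truth$fiber_mask[, , , 1], c(1, 2), any)
  expect_true(all(mips$signal$pixels[fm] == 150))
  expect_true(all(mips$signal$pixels[sc$truth$granule_mask[, , 1] & !fm] == 0))

  # artifact-free stack at default settings: output equals the plain MIP
  fib <- matrix(FALSE, 30, 30)
  for (x in 3:27) fib[15 + round(2 * sin(x / 5)), x] <- TRUE
  sig <- matrix(0, 30, 30); sig[fib] <- 140
  vox <- array(0, dim = c(30, 30, 2, 2))
  vox[, , 1, 1] <- sig
  st <- image_stack(vox, 8L, g1, af_channel = 2L)
  out <- clean_images(st)
  expect_identical(out[[1]]$pixels, sig)

  # morphology-only path works without an AF channel
  stn <- stack_from_slices(list(sig, matrix(0, 30, 30)))
  outn <- clean_images(stn, clean_settings(use_af_subtraction = FALSE))
  expect_identical(outn[[1]]$pixels, sig)
  # but AF subtraction without an AF channel errors
  expect_error(clean_images(stn, clean_settings()), "autofluorescence")
})

test_that("every stage only destroys signal and is deterministic", {
  for (seed in c(2, 5)) {
    ph <- generate_phantom(phantom_spec(seed = seed, y = 96, x = 96, z = 3))
    st <- ph$stack
    s1 <- remove_large_particles_stack(st)
    expect_true(all(s1$voxels <= st$voxels))
    s2 <- subtract_autofluorescence(s1, 1)
    expect_true(all(s2$voxels <= s1$voxels))
    for (ch in signal_channels(st)) {
      mip <- max_intensity_projection(s2, ch)
      s3 <- remove_small_particles(mip)
      expect_true(all(s3$pixels <= mip$pixels))
    }
    m1 <- clean_images(st)
    m2 <- clean_images(st)
    expect_identical(m1, m2)
  }
})
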