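# Stage 1: cavity model configuration, training contracts, boundary
# refinement

test_that("cavity configuration validates and carries reference defaults", {
  full <- cavity_config("3d")
  expect_identical(full$input_size, c(40L, 64L, 64L))
  expect_identical(full$kernel, 3L)
  expect_identical(full$epochs, 320L)
  expect_identical(full$lr, 1e-4)
  full2d <- cavity_config("2d")
  expect_identical(full2d$input_size, c(512L, 512L))  # 512x512 slices accepted
  expect_identical(full2d$kernel, 5L)
  expect_identical(full2d$epochs, 30L)
  expect_error(cavity_config("2d", input_size = c(510, 510)), "divisible")
  expect_error(cavity_config("3d", epochs = 0), "epochs")
  expect_error(cavity_config("3d", lr = -1), "learning")
})

test_that("a tiny cavity model overfits a handful of phantoms", {
  co <- fixture_cohort()
  cfg <- cavity_config("3d", input_size = c(8, 16, 16), filters = c(3, 4, 6),
                       epochs = 5, lr = 3e-3, augment = FALSE)
  m <- build_cavity_model(cfg, seed = 1)
  m <- train_cavity(m, co$samples[1:4], co$samples[5], seed = 1)
  h <- m$history
  expect_identical(nrow(h), 5L)
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  # returned weights belong to the epoch with minimal validation loss
  m2 <- build_cavity_model(cfg, seed = 1)
  m2 <- train_cavity(m2, co$samples[1:4], co$samples[5], seed = 1)
  expect_identical(m$history, m2$history)   # seeded determinism
  expect_identical(m$params, m2$params)
  expect_error(train_cavity(build_cavity_model(cfg), list(), list()),
               "at least one")
})

test_that("trained segmenters reach Dice >= 0.90 on held-out phantoms", {
  co <- generate_cohort(12, 0.5, seed = 310L,
                        split_fractions = c(train = 8 / 12, val = 2 / 12,
                                            test = 2 / 12))
  tr <- co$samples[1:8]; va <- co$samples[9:10]; te <- co$samples[11:12]
  m3 <- build_cavity_model(cavity_config("3d", desk = TRUE), seed = 1)
  m3 <- train_cavity(m3, tr, va, seed = 1)
  m2 <- build_cavity_model(cavity_config("2d", desk = TRUE, epochs = 3),
                           seed = 1)
  m2 <- train_cavity(m2, tr[1:4], va[1], seed = 1)
  for (s in te) {
    nv <- clip_normalize(s$volume)
    for (m in list(m3, m2)) {
      seg <- segment_cavity(m, nv)
      expect_identical(dim(seg$voxels), dim(s$volume$voxels))
      expect_true(all(seg$voxels %in% c(0L, 1L)))
      expect_gte(dice_coefficient(seg$voxels, s$cavity$voxels), 0.90)
    }
  }
  # all-air input yields a near-empty mask
  air <- normalized_volume(array(0, dim(te[[1]]$volume$voxels)),
                           te[[1]]$volume)
  seg_air <- segment_cavity(m3, air)
  expect_lt(mean(seg_air$voxels), 0.02)
})

test_that("boundary refinement applies the band/HU rule exactly", {
  # synthetic slice: 20x20 square mask, known HU pattern
  vox <- array(30, c(1, 20, 20))
  m <- array(0L, c(1, 20, 20))
  m[1, 5:16, 5:16] <- 1L
  vox[1, 10, 5] <- 60    # on the boundary, HU 60 -> excluded
  vox[1, 10, 10] <- 70   # deep interior at band 2 -> retained
  sp <- c(5, 1, 1)
  ref <- refine_boundary(seg_mask(m, sp), ct_volume(vox, sp), band_px = 2,
                         hu_max = 50)
  expect_identical(ref$voxels[1, 10, 5], 0L)
  expect_identical(ref$voxels[1, 10, 10], 1L)
  # empty mask stays empty
  ref0 <- refine_boundary(seg_mask(array(0L, c(1, 8, 8)), sp),
                          ct_volume(array(0, c(1, 8, 8)), sp))
  expect_identical(sum(ref0$voxels), 0L)
  expect_error(refine_boundary(seg_mask(m, sp), ct_volume(vox, sp),
                               band_px = -1), "band_px")
})

test_that("refinement changes membership only within the band", {
  set.seed(41)
  for (rep in 1:5) {
    ny <- 24; nx <- 24
    m <- array(0L, c(1, ny, nx))
    cy <- sample(8:16, 1); cx <- sample(8:16, 1); r <- sample(4:7, 1)
    for (y in 1:ny) for (x in 1:nx)
      if ((y - cy)^2 + (x - cx)^2 <= r^2) m[1, y, x] <- 1L
    vox <- array(stats::runif(ny * nx, 0, 100), c(1, ny, nx))
    band <- 3
    ref <- refine_boundary(seg_mask(m, c(5, 1, 1)),
                           ct_volume(vox, c(5, 1, 1)), band_px = band)
    # brute-force distance of every changed voxel to the input boundary
    bpts <- which(nctstroke:::boundary_pixels(m[1, , ]) == 1, arr.ind = TRUE)
    dist <- oracle_dist2d(ny, nx, bpts)
    changed <- which(ref$voxels[1, , ] != m[1, , ], arr.ind = TRUE)
    if (nrow(changed) > 0)
      expect_true(all(dist[changed] <= band))
    # and inside the band the HU rule holds on both sides
    inband <- dist <= band
    expect_identical(ref$voxels[1, , ][inband],
                     as.integer(vox[1, , ][inband] < 50))
  }
})
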