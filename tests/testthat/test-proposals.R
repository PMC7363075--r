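# Stage 2: Dice loss, proposal training/inference, component filtering

test_that("dice coefficient matches its closed form on worked cases", {
  a <- array(0, c(1, 4, 4)); b <- array(0, c(1, 4, 4))
  a[1, 1, 1:2] <- 1           # |S| = 2
  b[1, 1, 1:4] <- 1           # |y| = 4, overlap 2
  expect_equal(dice_coefficient(a, b), 2 * 2 / (2 + 4), tolerance = 1e-5)
  expect_equal(dice_coefficient(b, b), 1, tolerance = 1e-5)
  disj <- array(0, c(1, 4, 4)); disj[1, 4, 4] <- 1
  expect_lt(dice_coefficient(a, disj), 1e-5)
  expect_error(dice_coefficient(a, array(0, c(1, 2, 2))), "shape")
})

test_that("dice coefficient equals the set formula on random binary masks", {
  set.seed(21)
  for (i in 1:200) {
    S <- array(rbinom(60, 1, runif(1, 0.1, 0.9)), c(3, 4, 5))
    y <- array(rbinom(60, 1, runif(1, 0.1, 0.9)), c(3, 4, 5))
    oracle <- if (sum(S) + sum(y) == 0) 1 else
      2 * sum(S & y) / (sum(S) + sum(y))
    expect_equal(dice_coefficient(S, y), oracle, tolerance = 1e-4)
    # symmetry for binary inputs
    expect_equal(dice_coefficient(S, y), dice_coefficient(y, S),
                 tolerance = 1e-12)
  }
})

test_that("batch dice loss averages per-sample losses", {
  y <- array(rbinom(16, 1, 0.5), c(4, 4))
  wrong <- 1 - y
  expect_lt(dice_loss_batch(list(y), list(y)), 1e-5)
  expect_equal(dice_loss_batch(list(y, wrong), list(y, y)), 0.5,
               tolerance = 1e-4)
  expect_equal(dice_loss_batch(list(y, wrong), list(y, y)),
               dice_loss_batch(list(wrong, y), list(y, y)),
               tolerance = 1e-12)
  expect_error(dice_loss_batch(list(), list()), "empty")
  expect_error(dice_loss_batch(list(y), list(y, y)), "unequal")
})

test_that("training uses only lesion-bearing slices and is seeded", {
  s <- fixture_phantom()
  items <- nctstroke:::proposal_slices(s, c(32L, 32L), stroke_only = TRUE)
  n_lesion_slices <- sum(apply(s$lesions$voxels, 1, sum) > 0)
  expect_identical(length(items), as.integer(n_lesion_slices))
  all_items <- nctstroke:::proposal_slices(s, c(32L, 32L),
                                           stroke_only = FALSE)
  expect_identical(length(all_items), dim(s$volume$voxels)[1])
  # seeded determinism of a short training run
  cfg <- proposal_config(input_size = c(32, 32), filters = c(3, 4, 6),
                         epochs = 2, lr = 1e-3, augment = FALSE, desk = TRUE)
  m1 <- train_region_proposal(build_proposal_model(cfg, 1), list(s), list(s),
                              seed = 9)
  m2 <- train_region_proposal(build_proposal_model(cfg, 1), list(s), list(s),
                              seed = 9)
  expect_identical(m1$history, m2$history)
  # a healthy-only training set has no lesion slices
  h <- generate_phantom(phantom_params(seed = 6L,
                                       lesion_count_range = c(0, 0)))
  expect_error(train_region_proposal(build_proposal_model(cfg, 1), list(h),
                                     list(h), 1), "lesion-bearing")
})

test_that("proposal inference returns a binary grid-aligned mask", {
  s <- fixture_phantom()
  cfg <- proposal_config(input_size = c(32, 32), filters = c(3, 4, 6),
                         epochs = 1, lr = 1e-3, augment = FALSE, desk = TRUE)
  m <- train_region_proposal(build_proposal_model(cfg, 1), list(s), list(s),
                             seed = 1)
  prop <- propose_regions(m, clip_normalize(s$volume))
  expect_identical(dim(prop$voxels), dim(s$volume$voxels))
  expect_true(all(prop$voxels %in% c(0L, 1L)))
})

test_that("component filtering enforces the 0.2 cm3 bound strictly", {
  # 1 mm isotropic: 150 voxels = 0.15 cm3 -> removed; 250 -> kept
  m <- array(0L, c(10, 20, 20))
  m[1:6, 1:5, 1:5] <- 1L          # 150 voxels
  big <- array(0L, c(10, 20, 20))
  big[1:10, 10:14, 10:14] <- 1L   # 250 voxels
  both <- pmax(m, big)
  f <- filter_small_components(seg_mask(both, c(1, 1, 1)), min_cm3 = 0.2)
  expect_identical(sum(f$voxels[1:6, 1:5, 1:5]), 0L)
  expect_identical(sum(f$voxels[1:10, 10:14, 10:14]), 250L)
  # empty stays empty
  e <- filter_small_components(seg_mask(array(0L, c(2, 3, 3)), c(1, 1, 1)))
  expect_identical(sum(e$voxels), 0L)
  # mixed slice thickness: volume uses the per-slice thickness
  mix <- array(0L, c(4, 10, 10))
  mix[1:2, 1:5, 1:5] <- 1L  # 50 voxels: 2 slices x 25 px
  msk <- seg_mask(mix, c(3, 2, 2), z_thickness = c(3, 6, 3, 3))
  # 25 * (2*2) * (3 + 6) = 900 mm3 = 0.9 cm3 -> kept
  expect_identical(sum(filter_small_components(msk, 0.85)$voxels), 50L)
  expect_identical(sum(filter_small_components(msk, 0.95)$voxels), 0L)
})

test_that("component filtering agrees with exhaustive enumeration", {
  set.seed(23)
  for (rep in 1:6) {
    m <- array(as.integer(stats::runif(20^3) < 0.08), c(20, 20, 20))
    sp <- c(1, 1, 1)
    thr_vox <- 200    # 0.2 cm3 at 1 mm iso
    f <- filter_small_components(seg_mask(m, sp), min_cm3 = 0.2)
    lab <- oracle_label3d(m)
    expected <- array(0L, dim(m))
    if (max(lab) > 0)
      for (l in seq_len(max(lab))) {
        comp <- lab == l
        if (sum(comp) >= thr_vox) expected[comp] <- 1L
      }
    expect_identical(f$voxels, expected)
    # output is a subset of the input
    expect_true(all(f$voxels <= m))
  }
})
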