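# Stage 3: lesions, borders, dual patches, dataset assembly, classifier

sp1 <- c(5, 2, 2)

test_that("connected-component labelling follows 26-connectivity", {
  m <- array(0L, c(3, 8, 8))
  m[1, 1:2, 1:2] <- 1L
  m[3, 6:7, 6:7] <- 1L
  les <- label_lesions(seg_mask(m, sp1))
  expect_length(les, 2L)
  # two voxels touching only diagonally in-plane form one lesion
  d <- array(0L, c(1, 4, 4))
  d[1, 1, 1] <- 1L; d[1, 2, 2] <- 1L
  expect_length(label_lesions(seg_mask(d, sp1)), 1L)
  # and across slices diagonally as well
  dz <- array(0L, c(2, 4, 4))
  dz[1, 1, 1] <- 1L; dz[2, 2, 2] <- 1L
  expect_length(label_lesions(seg_mask(dz, sp1)), 1L)
  expect_length(label_lesions(seg_mask(array(0L, c(2, 4, 4)), sp1)), 0L)
  # physical volume: voxel = 5 * 2 * 2 = 20 mm^3
  expect_equal(label_lesions(seg_mask(d, sp1))[[1]]$volume_cm3, 2 * 20 / 1000)
})

test_that("the Sobel border of a filled square is its perimeter", {
  m <- array(0L, c(1, 12, 12))
  m[1, 4:8, 4:8] <- 1L   # 5x5 square
  les <- label_lesions(seg_mask(m, sp1))[[1]]
  border <- lesion_border(les, dim(m))
  expect_identical(nrow(border), 16L)
  # border is a subset of the lesion
  expect_true(all(m[border] == 1L))
  # oracle: lesion pixels adjacent in-plane to a non-lesion pixel
  oracle <- which(m[1, , ] == 1 &
                    nctstroke:::boundary_pixels(m[1, , ]) == 1,
                  arr.ind = TRUE)
  expect_identical(nrow(border), nrow(oracle))
  expect_setequal(paste(border[, "y"], border[, "x"]),
                  paste(oracle[, 1], oracle[, 2]))
  # single-voxel lesion: the voxel itself
  s1 <- array(0L, c(1, 5, 5)); s1[1, 3, 3] <- 1L
  b1 <- lesion_border(label_lesions(seg_mask(s1, sp1))[[1]], dim(s1))
  expect_identical(unname(b1), matrix(c(1L, 3L, 3L), 1))
})

test_that("border extraction matches the adjacency oracle on random boxes", {
  set.seed(33)
  for (rep in 1:10) {
    m <- array(0L, c(2, 14, 14))
    y0 <- sample(2:6, 1); x0 <- sample(2:6, 1)
    m[1, y0:(y0 + sample(2:6, 1)), x0:(x0 + sample(2:6, 1))] <- 1L
    les <- label_lesions(seg_mask(m, sp1))[[1]]
    border <- lesion_border(les, dim(m))
    oracle <- which(m[1, , ] == 1 &
                      nctstroke:::boundary_pixels(m[1, , ]) == 1,
                    arr.ind = TRUE)
    expect_setequal(paste(border[, "y"], border[, "x"]),
                    paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("border position sampling honours the replacement rule", {
  big <- cbind(z = rep(1L, 200), y = 1:200, x = 1:200)
  s <- sample_border_positions(big, 70, seed = 3)
  expect_identical(nrow(s), 70L)
  expect_identical(anyDuplicated(s), 0L)     # without replacement
  small <- big[1:5, ]
  s2 <- sample_border_positions(small, 70, seed = 3)
  expect_identical(nrow(s2), 70L)
  expect_true(all(s2[, "y"] %in% small[, "y"]))  # with replacement
  expect_identical(sample_border_positions(big, 70, seed = 9),
                   sample_border_positions(big, 70, seed = 9))
  expect_error(sample_border_positions(big[0, ], 70), "empty")
})

test_that("dual patches have exact shape, centring and padding", {
  v <- ct_volume(array(40, c(8, 130, 130)), sp1)
  nv <- clip_normalize(v)
  p <- extract_dual_patch(nv, c(4, 65, 65))
  expect_identical(dim(p$fine), c(3L, 32L, 32L))
  expect_identical(dim(p$coarse), c(3L, 32L, 32L))
  expect_true(all(abs(p$fine - 0.5) < 1e-12))
  expect_true(all(abs(p$coarse - 0.5) < 1e-12))
  # centre voxel of the fine patch equals the volume value at the centre
  nv$voxels[4, 65, 65] <- 0.25
  p2 <- extract_dual_patch(nv, c(4, 65, 65))
  expect_identical(p2$fine[2, 16, 16], 0.25)
  # corner centre: out-of-volume region zero padded, shape unchanged
  pc <- extract_dual_patch(nv, c(1, 1, 1))
  expect_identical(dim(pc$fine), c(3L, 32L, 32L))
  expect_identical(unique(as.vector(pc$fine[1, , ])), 0)   # z = 0 slice
  expect_identical(pc$fine[2, 1, 1], 0)                    # y/x < 1 region
  expect_error(extract_dual_patch(nv, c(0, 1, 1)), "outside")
})

test_that("patch extraction is translation-consistent away from edges", {
  set.seed(34)
  base <- array(stats::runif(8 * 140 * 140), c(8, 140, 140))
  v <- normalized_volume(base, ct_volume(base * 80, sp1))
  shifted <- base[, c(3:140, 1:2), ]   # shift y by -2
  vs <- normalized_volume(shifted, ct_volume(shifted * 80, sp1))
  a <- extract_dual_patch(v, c(4, 70, 70))
  b <- extract_dual_patch(vs, c(4, 68, 70))
  expect_equal(a$fine, b$fine, tolerance = 1e-12)
  expect_equal(a$coarse, b$coarse, tolerance = 1e-12)
})

test_that("patch datasets balance classes exactly via oversampling", {
  mk <- function(n, lab) replicate(n, structure(
    list(fine = array(0, c(3, 32, 32)), coarse = array(0, c(3, 32, 32)),
         center = c(1, 1, 1), label = lab), class = "dual_patch"),
    simplify = FALSE)
  ds <- build_patch_dataset(mk(40, "stroke"), mk(100, "non-stroke"),
                            seed = 4)
  expect_identical(length(ds$patches), 200L)
  expect_identical(sum(ds$label == 1), 100L)
  expect_identical(sum(ds$label == 0), 100L)
  # already balanced input is unchanged in size
  ds2 <- build_patch_dataset(mk(30, "stroke"), mk(30, "non-stroke"), seed = 4)
  expect_identical(length(ds2$patches), 60L)
  expect_identical(mean(ds2$label), 0.5)
  expect_error(build_patch_dataset(list(), mk(3, "non-stroke")), "non-empty")
})

test_that("the dual-pathway classifier obeys its structural contracts", {
  cfg <- patch_config(blocks = c(2, 2), growth = 3, stem = 3, fc = 8)
  m <- build_patch_classifier(cfg, seed = 5)
  # dense connectivity: layer k of a block sees all previous outputs
  expect_identical(nrow(m$params$f_b1_l1$W), 27L * 3L)        # stem channels
  expect_identical(nrow(m$params$f_b1_l2$W), 27L * (3L + 3L)) # + growth
  expect_identical(nrow(m$params$f_b2_l2$W),
                   nrow(m$params$f_b2_l1$W) + 27L * 3L)
  # identical seeds give identical weights
  expect_identical(build_patch_classifier(cfg, seed = 5)$params, m$params)
  # forward pass: two probabilities summing to one, deterministic at
  # inference (dropout off)
  set.seed(6)
  pts <- replicate(3, structure(
    list(fine = array(stats::runif(3072), c(3, 32, 32)),
         coarse = array(stats::runif(3072), c(3, 32, 32)),
         center = c(1, 1, 1), label = "unlabeled"), class = "dual_patch"),
    simplify = FALSE)
  p <- classify_patches(m, pts)
  expect_length(p, 3L)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, classify_patches(m, pts))
  # duplicated patch gets an identical probability; order permutes outputs
  p2 <- classify_patches(m, pts[c(2, 1, 3)])
  expect_equal(p2, p[c(2, 1, 3)], tolerance = 1e-12)
})

test_that("hard negatives yield n-per-component patches on proposal borders", {
  s <- generate_phantom(phantom_params(seed = 71L,
                                       lesion_count_range = c(0, 0)), "h1")
  cfg <- proposal_config(input_size = c(32, 32), filters = c(3, 4, 6),
                         epochs = 1, lr = 1e-3, augment = FALSE, desk = TRUE)
  str <- fixture_phantom()
  pm <- train_region_proposal(build_proposal_model(cfg, 1), list(str),
                              list(str), seed = 1)
  nv <- clip_normalize(s$volume)
  surviving <- label_lesions(
    filter_small_components(propose_regions(pm, nv), 0.2))
  neg <- mine_hard_negatives(list(s), pm, n_per_lesion = 15, seed = 2)
  expect_identical(length(neg), 15L * length(surviving))
  if (length(neg) > 0)
    expect_true(all(vapply(neg, function(p) p$label == "non-stroke",
                           logical(1))))
})

test_that("a tiny classifier separates hypodense from parenchymal patches", {
  # synthetic patches: stroke-like centres (hypodense core) vs uniform
  # parenchyma; a small network must reach >= 0.8 validation accuracy
  set.seed(35)
  mkpatch <- function(hypo) {
    base <- array(stats::rnorm(3072, 35 / 80, 0.03), c(3, 32, 32))
    if (hypo) base[, 9:24, 9:24] <- stats::rnorm(3 * 16 * 16, 20 / 80, 0.03)
    base <- pmin(pmax(base, 0), 1)
    structure(list(fine = base, coarse = base, center = c(1, 1, 1),
                   label = if (hypo) "stroke" else "non-stroke"),
              class = "dual_patch")
  }
  pos <- replicate(40, mkpatch(TRUE), simplify = FALSE)
  neg <- replicate(40, mkpatch(FALSE), simplify = FALSE)
  ds <- build_patch_dataset(pos[1:30], neg[1:30], seed = 1)
  vds <- build_patch_dataset(pos[31:40], neg[31:40], seed = 2)
  cfg <- patch_config(blocks = c(1, 1), growth = 3, stem = 3, fc = 8,
                      lr = 3e-3, epochs = 20, batch = 10)
  m <- build_patch_classifier(cfg, seed = 7)
  m <- train_patch_classifier(m, ds, vds, seed = 8)
  expect_gte(max(m$history$val_acc), 0.8)
  # loss decreases while overfitting
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  # seeded determinism of the history
  m2 <- build_patch_classifier(cfg, seed = 7)
  m2 <- train_patch_classifier(m2, ds, vds, seed = 8)
  expect_identical(m$history, m2$history)
})
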