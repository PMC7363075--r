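# Synthetic head phantom generator

test_that("phantom parameters are validated", {
  expect_error(phantom_params(lesion_hu = 40), "32")
  expect_error(phantom_params(lesion_hu = 30, parenchyma_hu = 25),
               "parenchyma")
  expect_error(phantom_params(lesion_radius_mm = c(-1, 5)), "radii")
  expect_error(phantom_params(spacing = c(0, 2, 2)), "spacing")
  expect_error(phantom_params(scanner = "nope"), "scanner")
  expect_error(generate_phantom(phantom_params(lesion_radius_mm = c(90, 95))),
               "too large")
})

test_that("a generated phantom honours its geometry contracts", {
  s <- fixture_phantom()
  d <- dim(s$volume$voxels)
  expect_identical(d, dim(s$cavity$voxels))
  expect_identical(d, dim(s$lesions$voxels))
  # lesion mask inside cavity mask
  expect_true(all(s$cavity$voxels[s$lesions$voxels == 1] == 1))
  # skull shell bright: ring just outside the cavity exceeds 80 HU
  mid <- round(d[1] / 2)
  cav <- s$cavity$voxels[mid, , ]
  # ring: non-cavity pixels with a cavity 4-neighbour (skull inner edge)
  pad <- matrix(0L, nrow(cav) + 2, ncol(cav) + 2)
  pad[2:(nrow(cav) + 1), 2:(ncol(cav) + 1)] <- cav
  nb <- pad[1:nrow(cav), 2:(ncol(cav) + 1)] +
    pad[3:(nrow(cav) + 2), 2:(ncol(cav) + 1)] +
    pad[2:(nrow(cav) + 1), 1:ncol(cav)] +
    pad[2:(nrow(cav) + 1), 3:(ncol(cav) + 2)]
  ring <- cav == 0 & nb > 0
  expect_gt(mean(s$volume$voxels[mid, , ][ring] > 80), 0.9)
  # parenchyma near its mean away from boundaries
  interior <- cav == 1
  interior[nctstroke:::boundary_pixels(cav) == 1] <- FALSE
  vals <- s$volume$voxels[mid, , ][interior]
  expect_lt(abs(median(vals) - 35), 8)
})

test_that("lesion intensity sits below surrounding parenchyma", {
  s <- fixture_phantom()
  v <- s$volume$voxels
  les_mean <- mean(v[s$lesions$voxels == 1])
  par_mean <- mean(v[s$cavity$voxels == 1 & s$lesions$voxels == 0])
  expect_lt(les_mean, par_mean)
  expect_lt(les_mean, 32)
})

test_that("the seed fully determines the sample", {
  p <- phantom_params(seed = 77L, rotation_deg = c(-10, 10))
  a <- generate_phantom(p, "s")
  b <- generate_phantom(p, "s")
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$cavity$voxels, b$cavity$voxels)
  expect_identical(a$lesions$voxels, b$lesions$voxels)
  expect_identical(a$angle, b$angle)
})

test_that("zero lesion requests give empty lesion masks", {
  s <- generate_phantom(phantom_params(seed = 5L,
                                       lesion_count_range = c(0, 0)))
  expect_identical(sum(s$lesions$voxels), 0L)
  co <- generate_cohort(4, 0, seed = 9L)
  expect_true(all(vapply(co$samples, function(x) sum(x$lesions$voxels) == 0,
                         logical(1))))
})

test_that("cohorts have the requested composition and label consistency", {
  co <- fixture_cohort()
  expect_identical(length(co$samples), 8L)
  expect_identical(sum(co$cohort$label), 4L)
  for (s in co$samples) {
    has_lesion <- sum(s$lesions$voxels) > 0
    expect_identical(s$record$label == 1L, has_lesion)
    # lesion component count is consistent with the labelling
    if (has_lesion)
      expect_gte(length(label_lesions(s$lesions)), 1L)
  }
  expect_setequal(names(table(co$cohort$split)), c("train", "val", "test"))
  # seeded determinism of the whole cohort
  co2 <- generate_cohort(8, 0.5, seed = 202L,
                         split_fractions = c(train = 0.5, val = 0.25,
                                             test = 0.25))
  expect_identical(co$cohort, co2$cohort)
  expect_identical(co$samples[[3]]$volume$voxels,
                   co2$samples[[3]]$volume$voxels)
})

test_that("scanner profiles produce different high-frequency texture", {
  pa <- phantom_params(seed = 31L, scanner = "A", lesion_count_range = c(0, 0))
  pb <- phantom_params(seed = 31L, scanner = "B", lesion_count_range = c(0, 0))
  lap_energy <- function(s) {
    mid <- round(dim(s$volume$voxels)[1] / 2)
    m <- s$volume$voxels[mid, , ]
    inner <- s$cavity$voxels[mid, , ] == 1
    lap <- 4 * m
    lap[-1, ] <- lap[-1, ] - m[-nrow(m), ]
    lap[-nrow(m), ] <- lap[-nrow(m), ] - m[-1, ]
    lap[, -1] <- lap[, -1] - m[, -ncol(m)]
    lap[, -ncol(m)] <- lap[, -ncol(m)] - m[, -1]
    mean(lap[inner]^2)
  }
  ea <- mean(vapply(1:3, function(i) {
    pa$seed <- 31L + i; lap_energy(generate_phantom(pa))
  }, numeric(1)))
  eb <- mean(vapply(1:3, function(i) {
    pb$seed <- 31L + i; lap_energy(generate_phantom(pb))
  }, numeric(1)))
  # profile B smooths more aggressively -> lower Laplacian energy
  expect_gt(ea, 1.5 * eb)
})
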