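test_that("the 2D worked traversal records one pixel per x interval", {
  # single-slice 6 x 3 grid, ray from (0,0) with direction (dy, dx) = (2, 5):
  # the split axis is x (exit face), n = 5, rows follow round(0.4 s)
  vol <- segmented_volume(array(3L, dim = c(1, 3, 6)), 1)
  rec <- traverse(vol, c(0, 0, 0), c(0, 2, 5), record_path = TRUE)
  expect_identical(rec$total_count, 6L)
  expect_identical(rec$driving_axis, "x")
  expect_identical(rec$end_voxel, c(0L, 2L, 5L))
  expect_identical(rec$path[, 2], as.integer(round(0.4 * 0:5)))
  expect_identical(rec$path[, 3], 0:5)
  # path length is the Euclidean distance of the printed endpoints
  expect_equal(rec$euclidean_length_voxels, sqrt(29))
  expect_equal(unname(path_lengths(rec, 1)[["crystal"]]), sqrt(29))
})

test_that("axis-aligned traversal records one voxel per step to the boundary", {
  vol <- segmented_volume(array(3L, dim = c(5, 7, 11)), 1)
  rec <- traverse(vol, c(2, 3, 0), c(0, 0, 1))
  expect_identical(rec$total_count, 11L)
  expect_identical(rec$end_voxel, c(2L, 3L, 10L))
  expect_equal(rec$euclidean_length_voxels, 10)
})

test_that("traversal material counts agree with the dense marching oracle", {
  vol <- sphere32()
  cv <- crystal_voxels(vol)
  set.seed(5)
  worst <- 0
  for (i in 1:25) {
    start <- as.integer(cv[sample.int(nrow(cv), 1), ])
    d <- runit()
    lens <- traverse_lengths_voxels(vol, start, d)
    oracle <- march_lengths(vol, start, d)
    worst <- max(worst, abs(lens - oracle))
    expect_true(all(abs(lens - oracle) <= 1.0),
                info = sprintf("ray %d: max dev %.3f voxels", i, max(abs(lens - oracle))))
  }
})

test_that("traversal never leaves the volume and ends on the boundary", {
  vol <- sphere32()
  dims <- dim(vol$labels)
  set.seed(9)
  for (i in 1:20) {
    start <- c(sample(0:(dims[1] - 1), 1), sample(0:(dims[2] - 1), 1),
               sample(0:(dims[3] - 1), 1))
    rec <- traverse(vol, start, runit(), record_path = TRUE)
    expect_true(all(rec$path >= 0))
    expect_true(all(sweep(rec$path, 2, dims - 1L, `<=`)))
    expect_true(any(rec$end_voxel == 0L | rec$end_voxel == dims - 1L))
  }
})

test_that("path lengths scale voxel counts by the zigzag-corrected total", {
  rec <- structure(
    list(counts = c(crystal = 3, liquor = 1), total_count = 4L,
         euclidean_length_voxels = 6),
    class = "path_record"
  )
  expect_equal(path_lengths(rec, 0.3),
               c(crystal = 1.35, liquor = 0.45))

  vol <- segmented_volume(array(3L, dim = c(9, 9, 9)), 0.5)
  rec2 <- traverse(vol, c(4, 4, 4), c(1, 0.2, 0.1))
  pl <- path_lengths(rec2, vol$voxel_size_um)
  expect_equal(sum(pl), rec2$euclidean_length_voxels * 0.5)
  expect_equal(unname(pl[["crystal"]]), sum(pl))
})

test_that("voxel exponent combines reversed-incident and diffracted lengths", {
  vol <- segmented_volume(array(3L, dim = c(11, 11, 11)), 0.3)
  mu <- material_coefficients(crystal = 0.01)
  # incident +x, diffracted +x from the center: L1 = L2 = 5 voxels x 0.3 um
  expect_equal(voxel_exponent(vol, mu, c(5, 5, 5), c(0, 0, 1), c(0, 0, 1)), 0.03)
  # zero coefficients
  expect_identical(
    voxel_exponent(vol, material_coefficients(), c(5, 5, 5), c(0, 0, 1), c(0, 1, 0)),
    0
  )
  # linearity in mu
  e1 <- voxel_exponent(vol, mu, c(5, 5, 5), c(0, 0.3, 1), c(0.2, 0, 1))
  e2 <- voxel_exponent(vol, material_coefficients(crystal = 0.02),
                       c(5, 5, 5), c(0, 0.3, 1), c(0.2, 0, 1))
  expect_equal(e2, 2 * e1)
  # non-crystal start is rejected
  vol2 <- make_phantom("sphere", 3, shells = c(2, 1), volume_dims = c(16, 16, 16))
  expect_error(voxel_exponent(vol2, mu, c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               "not crystal")
})

test_that("absorption factor is the mean transmission over sampled voxels", {
  vol <- make_phantom("sphere", 4, shells = c(2, 1), volume_dims = c(16, 16, 16))
  mu0 <- material_coefficients()
  expect_identical(absorption_factor(vol, mu0, c(0, 0, 1), c(0, 1, 0)), 1)

  one <- segmented_volume(array(c(3L, rep(0L, 26)), dim = c(3, 3, 3)), 0.3)
  mu <- material_coefficients(preset = "insulin")
  e <- voxel_exponent(one, mu, c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(absorption_factor(one, mu, c(0, 0, 1), c(0, 1, 0)), exp(-e))
})

test_that("full-sampling factor matches an independent marching-based mean", {
  vol <- make_phantom("sphere", 4, shells = c(2, 1), volume_dims = c(16, 16, 16))
  mu <- material_coefficients(preset = "thaumatin")
  inc <- c(0, 0.3, 1) / sqrt(1.09)
  dif <- c(0.2, -0.5, 1) / sqrt(sum(c(0.2, -0.5, 1)^2))
  cv <- crystal_voxels(vol)
  muv <- unclass(mu)[names(vol$label_map)]
  oracle <- vapply(seq_len(nrow(cv)), function(i) {
    st <- as.integer(cv[i, ])
    l1 <- march_lengths(vol, st, -inc) * vol$voxel_size_um
    l2 <- march_lengths(vol, st, dif) * vol$voxel_size_um
    exp(-sum(muv * (l1 + l2)))
  }, numeric(1))
  A <- absorption_factor(vol, mu, inc, dif)
  expect_equal(A, mean(oracle), tolerance = 5e-3)
})

test_that("run_standard preserves order, matches per-reflection calls, ignores workers", {
  vol <- make_phantom("sphere", 5, shells = c(2, 1), volume_dims = c(20, 20, 20))
  mu <- material_coefficients(preset = "insulin")
  refl <- random_reflections(20, seed = 3)

  empty <- run_standard(vol, mu, refl[0, ])
  expect_identical(nrow(empty), 0L)

  res1 <- run_standard(vol, mu, refl, workers = 1)
  res4 <- run_standard(vol, mu, refl, workers = 4)
  expect_identical(res1$A, res4$A)

  seq_A <- vapply(seq_len(nrow(refl)), function(r) {
    absorption_factor(vol, mu,
                      c(refl$iz[r], refl$iy[r], refl$ix[r]),
                      c(refl$dz[r], refl$dy[r], refl$dx[r]))
  }, numeric(1))
  expect_equal(res1$A, seq_A, tolerance = 1e-12)
  expect_true(all(res1$A > 0 & res1$A <= 1))
})

test_that("slab geometry reproduces the closed-form column transmission", {
  D <- 15L
  vox <- 0.3
  mu_val <- 0.02
  vol <- segmented_volume(array(3L, dim = c(D, D, D)), vox)
  mu <- material_coefficients(crystal = mu_val)
  refl <- tibble::tibble(ix = 1, iy = 0, iz = 0, dx = 1, dy = 0, dz = 0)
  A <- run_standard(vol, mu, refl)$A
  # every column contributes exp(-mu * T) with T between (D-1) and D voxels
  expect_gte(A, exp(-mu_val * D * vox) - 1e-12)
  expect_lte(A, exp(-mu_val * (D - 1) * vox) + 1e-12)
})

test_that("raising any coefficient strictly lowers affected factors", {
  vol <- sphere32()
  refl <- random_reflections(5, seed = 8)
  lo <- run_standard(vol, material_coefficients(preset = "insulin"), refl)$A
  hi_mu <- material_coefficients(crystal = 0.00745 * 2, liquor = 0.0072,
                                 loop = 0.0069)
  hi <- run_standard(vol, hi_mu, refl)$A
  expect_true(all(hi < lo))
})

test_that("single precision tracks double precision closely but not exactly", {
  vol <- sphere32()
  mu <- material_coefficients(preset = "thermolysin")
  refl <- random_reflections(10, seed = 2)
  dd <- run_standard(vol, mu, refl)$A
  ss <- run_standard(vol, mu, refl, precision = "single")$A
  expect_equal(ss, dd, tolerance = 1e-5)
})
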