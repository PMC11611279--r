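fake_list <- function(N) tibble::tibble(z = 0L, y = 0L, x = seq_len(N) - 1L)

test_that("systematic sampling strides the sorted list at round(1/ratio)", {
  cl <- fake_list(10000)
  p <- systematic_sample(cl, 0.001)
  expect_identical(p$positions, seq.int(0L, 9000L, by = 1000L))
  expect_identical(nrow(p$selected), 10L)

  # the classic 0.05% ratio gives an interval of 2000
  p2 <- systematic_sample(cl, 0.0005)
  expect_identical(diff(p2$positions), rep(2000L, 4L))

  p3 <- systematic_sample(cl, 1)
  expect_identical(length(p3$positions), 10000L)

  p4 <- systematic_sample(cl, 0.001, offset = 500)
  expect_identical(p4$positions[1], 500L)
  expect_error(systematic_sample(cl, 0), "ratio")
  expect_error(systematic_sample(cl, 1.5), "ratio")
})

test_that("randomized systematic draws stay inside their interval", {
  cl <- fake_list(10000)
  p <- randomized_systematic_sample(cl, 0.001, seed = 5)
  k <- 1000L
  expect_identical(p$positions %/% k, 0:9)
  expect_identical(length(p$positions),
                   length(systematic_sample(cl, 0.001)$positions))
  expect_identical(randomized_systematic_sample(cl, 0.001, seed = 5)$positions,
                   p$positions)
  expect_false(identical(randomized_systematic_sample(cl, 0.001, seed = 6)$positions,
                         p$positions))
  expect_identical(randomized_systematic_sample(cl, 1, seed = 3)$positions,
                   seq.int(0L, 9999L))
})

test_that("random sampling is uniform without replacement", {
  cl <- fake_list(2000)
  for (ratio in c(0.001, 0.01, 0.1)) {
    p <- random_sample(cl, ratio, seed = 2)
    expect_identical(length(p$positions), max(1L, as.integer(round(ratio * 2000))))
    expect_false(anyDuplicated(p$positions) > 0)
  }
  expect_identical(length(random_sample(cl, 1, seed = 1)$positions), 2000L)

  # empirical per-voxel selection frequency over many draws approximates the ratio
  N <- 50L; ratio <- 0.2; reps <- 4000L
  hits <- integer(N)
  for (s in seq_len(reps)) {
    hits[random_sample(fake_list(N), ratio, seed = s)$positions + 1L] <-
      hits[random_sample(fake_list(N), ratio, seed = s)$positions + 1L] + 1L
  }
  freq <- hits / reps
  sigma <- sqrt(ratio * (1 - ratio) / reps)
  expect_lt(max(abs(freq - ratio)), 4.5 * sigma)
})

test_that("stratified sampling spreads picks across spatial regions", {
  vol <- sphere32()
  N <- nrow(crystal_voxels(vol))
  p <- stratified_sample(vol, 8 / N, seed = 3)
  expect_identical(length(p$positions), 8L)
  expect_identical(stratified_sample(vol, 8 / N, seed = 3)$positions, p$positions)

  # selected voxels occupy several distinct octants around the centroid
  sel <- p$selected
  ctr <- colMeans(crystal_voxels(vol))
  octant <- paste(sel$z > ctr[["z"]], sel$y > ctr[["y"]], sel$x > ctr[["x"]])
  expect_gte(length(unique(octant)), 4L)

  full <- stratified_sample(vol, 1, seed = 1)
  expect_identical(length(full$positions), N)
  expect_error(stratified_sample(vol, 1 + 1e-9), "ratio")
})

test_that("ratio 1 reproduces no-sampling factors bitwise for every strategy", {
  vol <- make_phantom("sphere", 4, shells = c(2, 1), volume_dims = c(16, 16, 16))
  mu <- material_coefficients(preset = "thermolysin")
  refl <- random_reflections(6, seed = 12)
  base <- run_standard(vol, mu, refl)$A
  for (m in c("systematic", "randomized_systematic", "random", "stratified")) {
    plan <- sampling_plan(vol, m, ratio = 1, seed = 4)
    expect_identical(run_standard(vol, mu, refl, plan = plan)$A, base,
                     label = paste("strategy", m))
  }
})

test_that("KS comparison matches the brute-force ECDF sup difference", {
  x <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(ks_compare(x, x), list(statistic = 0, p_value = 1))
  expect_equal(ks_compare(c(1, 2, 3), c(10, 11, 12))$statistic, 1)

  vol <- make_phantom("sphere", 5, shells = c(2, 1), volume_dims = c(20, 20, 20))
  mu <- material_coefficients(preset = "thaumatin")
  r1 <- random_reflections(1, seed = 7)
  rep1 <- sample_report(vol, mu, r1, ratios = 0.5, seeds = 1,
                        method = "systematic")
  cl <- crystal_voxels(vol)
  plan <- systematic_sample(cl, 0.5)
  full <- vapply(seq_len(nrow(cl)), function(i) {
    exp(-voxel_exponent(vol, mu, as.integer(cl[i, ]),
                        c(r1$iz, r1$iy, r1$ix), c(r1$dz, r1$dy, r1$dx)))
  }, numeric(1))
  expect_equal(rep1$statistic,
               ecdf_sup_diff(full[plan$positions + 1], full),
               tolerance = 1e-12)
})

test_that("plans serialize to JSON and restore exactly", {
  vol <- make_phantom("sphere", 4, shells = c(2, 1), volume_dims = c(16, 16, 16))
  plan <- sampling_plan(vol, "randomized_systematic", ratio = 0.03, seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f, vol)
  expect_identical(back$positions, plan$positions)
  expect_identical(back$selected, plan$selected)
  expect_identical(back$method, plan$method)
})
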