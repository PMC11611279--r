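# Label sequences are laid out explicitly in 1 x 1 x n stripe volumes so the
# expected boundary steps are known by construction.

test_that("label_at agrees with the recorded traversal labels", {
  vol <- sphere32()
  cv <- crystal_voxels(vol)
  set.seed(21)
  for (i in 1:8) {
    start <- as.integer(cv[sample.int(nrow(cv), 1), ])
    d <- runit()
    ray <- ray_param(vol, start, d)
    rec <- traverse(vol, start, d, record_path = TRUE)
    for (s in unique(c(0L, ray$n, sample(0:ray$n, 5, replace = TRUE)))) {
      co <- rec$path[s + 1, ]
      code <- vol$labels[co[1] + 1, co[2] + 1, co[3] + 1]
      expect_identical(label_at(vol, ray, s),
                       names(vol$label_map)[match(code, vol$label_map)])
    }
  }
})

test_that("find_boundary locates transitions like a linear scan", {
  vol <- stripe_volume(c(rep(3L, 11), rep(1L, 30)))
  ray <- ray_param(vol, c(0, 0, 0), c(0, 0, 1))
  expect_identical(find_boundary(vol, ray, "crystal", 0, ray$n, going_in = FALSE), 10L)
  expect_identical(scan_boundary(vol, ray, "crystal", 0L, ray$n), 10L)

  set.seed(13)
  for (i in 1:10) {
    b <- sample(1:62, 1)
    vol2 <- stripe_volume(c(rep(3L, b), rep(1L, 64 - b)))
    ray2 <- ray_param(vol2, c(0, 0, 0), c(0, 0, 1))
    bis <- find_boundary(vol2, ray2, "crystal", 0, ray2$n, going_in = FALSE)
    expect_identical(bis, scan_boundary(vol2, ray2, "crystal", 0L, ray2$n))
  }

  # adjacent bracket returns immediately
  expect_identical(find_boundary(vol, ray, "crystal", 10, 11, going_in = FALSE), 10L)
  # unbracketed predicate errors
  expect_error(find_boundary(vol, ray, "crystal", 0, 5, going_in = FALSE),
               "no boundary")
  # orientation mismatch errors
  expect_error(find_boundary(vol, ray, "crystal", 0, ray$n, going_in = TRUE),
               "going_in")
})

test_that("bisection needs at most ceiling(log2(n)) queries per boundary", {
  vol <- stripe_volume(c(rep(3L, 700), rep(1L, 324)))  # flip inside [0, 1023]
  ray <- ray_param(vol, c(0, 0, 0), c(0, 0, 1))
  queries <- 0L
  pred <- function(m) { queries <<- queries + 1L; m == "crystal" }
  b <- find_boundary(vol, ray, pred, 0, 1023, going_in = FALSE,
                     check_bracket = FALSE)
  expect_identical(b, 699L)
  expect_lte(queries, 11L)  # ceiling(log2(1023)) + 1
})

test_that("bisection path lengths reproduce the worked concentric layout", {
  vol <- stripe_volume(c(rep(3L, 11), rep(1L, 10), rep(2L, 10), rep(0L, 33)))
  bl <- bisection_path_lengths(vol, c(0, 0, 0), c(0, 0, 1))
  expect_identical(unname(bl$steps),
                   c(11L, 10L, 10L, 33L))  # crystal, liquor, loop, vacuum
  expect_identical(unname(bl$boundaries[c("crystal_outer", "air",
                                          "loop_inner", "loop_outer")]),
                   c(10L, 31L, 21L, 30L))
  # lengths are steps x (euclid per step) x voxel size; sum equals the total
  expect_equal(sum(bl$lengths_um), bl$euclidean_length_voxels * 0.3)
  expect_equal(unname(bl$lengths_um[["crystal"]]), 11 / 64 * 63 * 0.3)
})

test_that("all-crystal rays assign the whole length to crystal", {
  vol <- segmented_volume(array(3L, dim = c(9, 9, 9)), 0.3)
  bl <- bisection_path_lengths(vol, c(4, 4, 4), c(0, 0.2, 1))
  expect_equal(unname(bl$lengths_um[["crystal"]]), sum(bl$lengths_um))
  expect_identical(unname(bl$steps[c("liquor", "loop", "background")]),
                   c(0L, 0L, 0L))
})

test_that("absent loop is flagged and liquor obtained by subtraction", {
  vol <- stripe_volume(c(rep(3L, 11), rep(1L, 20), rep(0L, 33)))
  bl <- bisection_path_lengths(vol, c(0, 0, 0), c(0, 0, 1))
  expect_true(is.na(bl$boundaries[["loop_inner"]]))
  expect_identical(unname(bl$steps),
                   c(11L, 20L, 0L, 33L))
})

test_that("bisection boundaries sit within one step of the scan on phantoms", {
  vol <- sphere32()
  cv <- crystal_voxels(vol)
  set.seed(31)
  for (i in 1:10) {
    start <- as.integer(cv[sample.int(nrow(cv), 1), ])
    d <- runit()
    ray <- ray_param(vol, start, d)
    bl <- bisection_path_lengths(vol, start, d)
    scan <- vapply(0:ray$n, function(s) label_at(vol, ray, s), "")
    # per-material voxel counts from full scan vs bisection, within 2 steps
    for (m in c("crystal", "liquor", "loop", "background")) {
      expect_lte(abs(sum(scan == m) - bl$steps[[m]]), 2L,
                 label = sprintf("material %s, ray %d", m, i))
    }
  }
})

test_that("bisection factors track the standard back-end within 1%", {
  vol <- sphere32()
  mu <- material_coefficients(preset = "thermolysin")
  refl <- random_reflections(12, seed = 4)
  plan <- sampling_plan(vol, "systematic", ratio = 0.05)
  A_std <- run_standard(vol, mu, refl, plan = plan)$A
  A_bis <- run_bisection(vol, mu, refl, plan = plan)$A
  expect_true(all(abs(A_bis - A_std) / A_std < 0.01))
})

test_that("bisection degenerates gracefully", {
  vol <- sphere32()
  mu0 <- material_coefficients()
  refl <- random_reflections(3, seed = 1)
  expect_true(all(run_bisection(vol, mu0, refl,
                                plan = sampling_plan(vol, ratio = 0.02))$A == 1))
  expect_identical(nrow(run_bisection(vol, mu0, refl[0, ])), 0L)
})
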