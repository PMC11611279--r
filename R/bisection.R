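#' Material label at a step along a discretized ray
#'
#' Uses the same driving-axis stepping and nearest-voxel rounding as
#' [traverse()], but queries a single step, which is the primitive the
#' bisection boundary search builds on.
#'
#' @param volume A [segmented_volume()].
#' @param ray A `voxel_ray` from [ray_param()].
#' @param s Integer step in `[0, ray$n]`.
#' @return Material name (character).
#' @export
label_at <- function(volume, ray, s) {
  if (s < 0L || s > ray$n) stop("step outside [0, n]")
  dims <- dim(volume$labels)
  co <- round_half_away(ray$start + s * ray$step)
  co <- pmin(pmax(co, 0), dims - 1)
  code <- volume$labels[co[1] + 1L, co[2] + 1L, co[3] + 1L]
  names(volume$label_map)[match(code, volume$label_map)]
}

#' Bisection search for a material boundary along a ray
#'
#' Locates the step at which a material predicate flips between `lo` and
#' `hi` by repeated halving, using at most `ceiling(log2(hi - lo)) + 1`
#' label queries beyond the two bracket checks. Returns the last step at
#' which the predicate still has its `lo` value, i.e. the last voxel before
#' the transition.
#'
#' @inheritParams label_at
#' @param target Material name (the predicate is `label == target`) or a
#'   predicate function over material names.
#' @param lo,hi Bracketing steps, `lo < hi`, with differing predicate values.
#' @param going_in If `TRUE` the ray is entering the target material (the
#'   predicate is expected `FALSE` at `lo`); if `FALSE` it is leaving
#'   (`TRUE` at `lo`). Used to classify the located boundary as inner or
#'   outer; a mismatch errors.
#' @param check_bracket If `TRUE` (default), query both bracket ends and
#'   verify they differ; `FALSE` trusts the caller (the two bracket queries
#'   are then saved, keeping the per-boundary cost at
#'   `ceiling(log2(hi - lo))` label queries).
#' @return Integer step index of the last voxel before the predicate flips.
#' @export
find_boundary <- function(volume, ray, target, lo, hi, going_in = TRUE,
                          check_bracket = TRUE) {
  pred <- if (is.function(target)) target else function(m) m == target
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) stop("need lo < hi")
  plo <- !going_in
  if (check_bracket) {
    plo <- pred(label_at(volume, ray, lo))
    phi <- pred(label_at(volume, ray, hi))
    if (plo == phi) stop("no boundary bracketed: predicate identical at lo and hi")
    if (plo == going_in) {
      stop(sprintf("bracket orientation inconsistent with going_in = %s", going_in))
    }
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pred(label_at(volume, ray, mid)) == plo) lo <- mid else hi <- mid
  }
  lo
}

#' Per-material path lengths by bisection
#'
#' Instead of stepping every voxel, locates material boundaries along the
#' ray by bisection in the default order — crystal outer boundary, air
#' boundary (sample/vacuum), loop inner, loop outer — and obtains the
#' mother-liquor length by subtracting all other lengths from the total.
#' Valid on models whose materials are layered along the ray with no
#' air/vacuum gap between crystal and loop; a detected air pocket inside the
#' sample region triggers a warning (documented inaccuracy of the method).
#'
#' @inheritParams label_at
#' @param start Integer `(z, y, x)` crystal voxel (0-based).
#' @param d Direction vector `(z, y, x)`.
#' @return A list of class `bisection_lengths`: `lengths_um` (named,
#'   micrometres), `steps` (named voxel counts), `boundaries` (step indices:
#'   `crystal_outer`, `air`, `loop_inner`, `loop_outer`, `NA` when absent),
#'   `n`, `euclidean_length_voxels`.
#' @export
bisection_path_lengths <- function(volume, start, d) {
  ray <- ray_param(volume, start, d)
  n <- ray$n
  lm <- volume$label_map
  lab0 <- label_at(volume, ray, 0L)
  if (lab0 != "crystal") stop("ray must start inside the crystal")
  labn <- label_at(volume, ray, n)

  # crystal outer boundary: last crystal step scanning out from the voxel
  c_out <- if (n == 0L || labn == "crystal") {
    n
  } else {
    find_boundary(volume, ray, "crystal", 0L, n, going_in = FALSE)
  }

  # air boundary: first background step beyond the sample
  air <- NA_integer_
  if (labn == "background" && c_out < n) {
    last_sample <- if (label_at(volume, ray, c_out + 1L) == "background") {
      c_out  # crystal touches vacuum directly
    } else {
      find_boundary(volume, ray, function(m) m == "background",
                    c_out, n, going_in = TRUE)
    }
    air <- last_sample + 1L
  }
  vac_steps <- if (is.na(air)) 0L else n - air + 1L

  # loop boundaries inside (crystal outer, air)
  loop_inner <- loop_outer <- NA_integer_
  loop_steps <- 0L
  sample_end <- if (is.na(air)) n else air - 1L
  if ("loop" %in% names(lm) && sample_end > c_out &&
      label_at(volume, ray, sample_end) == "loop") {
    loop_outer <- sample_end
    loop_inner <- if (label_at(volume, ray, c_out + 1L) == "loop") {
      c_out + 1L
    } else {
      find_boundary(volume, ray, "loop", c_out, loop_outer, going_in = TRUE) + 1L
    }
    loop_steps <- loop_outer - loop_inner + 1L
  }

  crystal_steps <- c_out + 1L
  liquor_steps <- (n + 1L) - crystal_steps - loop_steps - vac_steps
  if (liquor_steps < 0L) {
    warning("non-conforming model along ray (air pocket inside the sample?); ",
            "liquor length clamped to 0")
    liquor_steps <- 0L
  } else if (!is.na(loop_inner) && loop_inner - c_out > 2L) {
    # probe the bracketed liquor stretch for stray vacuum (air pockets)
    probes <- unique(round(seq(c_out + 1L, loop_inner - 1L, length.out = 3L)))
    if (any(vapply(probes, function(s) label_at(volume, ray, s), "") == "background")) {
      warning("non-conforming model: air/vacuum between crystal and loop; ",
              "bisection lengths may be inaccurate")
    }
  }

  dims <- dim(volume$labels)
  endco <- pmin(pmax(round_half_away(ray$start + n * ray$step), 0), dims - 1)
  euclid <- sqrt(sum((endco - ray$start)^2))
  steps <- c(crystal = crystal_steps, liquor = liquor_steps,
             loop = loop_steps, background = vac_steps)
  scale <- euclid / (n + 1L) * volume$voxel_size_um
  structure(
    list(
      lengths_um = steps * scale,
      steps = steps,
      boundaries = c(crystal_outer = c_out, air = air,
                     loop_inner = loop_inner, loop_outer = loop_outer),
      n = n,
      euclidean_length_voxels = euclid
    ),
    class = "bisection_lengths"
  )
}

#' Bisection back-end driver
#'
#' Same contract as [run_standard()] but with per-material path lengths
#' from [bisection_path_lengths()]; per-ray cost is logarithmic in the ray
#' length instead of linear.
#'
#' @inheritParams run_standard
#' @return An `absorption_result` tibble.
#' @export
run_bisection <- function(volume, coeffs, reflections, plan = NULL,
                          workers = 1L) {
  refl <- reflections_matrix(reflections)
  sel <- if (nrow(refl) > 0L) selection_matrix(volume, plan) else NULL
  mats <- c("crystal", "liquor", "loop", "background")
  mu <- vapply(mats, function(m) {
    if (m %in% names(coeffs)) unclass(coeffs)[[m]] else 0
  }, numeric(1))

  one_ray <- function(vox, d) {
    bl <- bisection_path_lengths(volume, vox, d)
    sum(mu * bl$lengths_um)
  }
  factors <- run_chunked(nrow(refl), workers, function(rows) {
    vapply(rows, function(r) {
      inc <- refl[r, 1:3]
      dif <- refl[r, 4:6]
      expo <- vapply(seq_len(nrow(sel)), function(i) {
        one_ray(sel[i, ], -inc) + one_ray(sel[i, ], dif)
      }, numeric(1))
      mean_exp_neg_cpp(expo)
    }, numeric(1))
  })
  absorption_result(factors, method = "bisection", volume = volume, plan = plan)
}
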