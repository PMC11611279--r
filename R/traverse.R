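#' Traverse voxels along a ray (standard back-end)
#'
#' Walks from `start` to the volume boundary, one voxel per integer step
#' along the driving axis (the axis of the ray's exit face); the remaining
#' coordinates are `start + s * step` rounded to the nearest integer, so
#' exactly one voxel is recorded per interval. Traversal always continues to
#' the model boundary — vacuum regions are stepped through, never used as an
#' early stop, so absorbing material beyond a vacuum gap is still counted.
#'
#' @param volume A [segmented_volume()].
#' @param start Integer `(z, y, x)` start voxel (0-based), inside the volume.
#' @param d Direction vector `(z, y, x)`, non-zero.
#' @param record_path If `TRUE`, also return the (n+1) x 3 matrix of recorded
#'   voxel coordinates.
#' @return A list of class `path_record`: `counts` (named per-material voxel
#'   counts), `total_count`, `start_voxel`, `end_voxel`,
#'   `euclidean_length_voxels` (distance between start and end voxel),
#'   `driving_axis`, and optionally `path`.
#' @examples
#' vol <- make_phantom("sphere", 6, shells = c(2, 2), volume_dims = c(24, 24, 24))
#' rec <- traverse(vol, c(12, 12, 12), c(0, 0.3, 1))
#' rec$counts
#' @export
traverse <- function(volume, start, d, record_path = FALSE) {
  res <- traverse_cpp(volume$labels, as.integer(start), as.numeric(d),
                      max_code(volume), record_path)
  counts <- res$counts[volume$label_map + 1L]
  names(counts) <- names(volume$label_map)
  structure(
    list(
      counts = counts,
      total_count = res$n + 1L,
      start_voxel = as.integer(start),
      end_voxel = res$end,
      euclidean_length_voxels = res$euclid,
      driving_axis = c("z", "y", "x")[res$axis + 1L],
      path = res$path
    ),
    class = "path_record"
  )
}

#' @export
print.path_record <- function(x, ...) {
  cat(sprintf("<path_record> %d voxels along %s, |end - start| = %.4g voxels\n",
              x$total_count, x$driving_axis, x$euclidean_length_voxels))
  print(x$counts)
  invisible(x)
}

#' Per-material path lengths from a traversal record
#'
#' Converts recorded voxel counts to physical lengths with the zigzag
#' correction: each material receives its proportion of recorded voxels
#' times the Euclidean start-to-end distance, so the per-material lengths
#' sum exactly to the Euclidean ray length regardless of the staircase
#' pattern of the discrete path.
#'
#' @param record A `path_record` from [traverse()].
#' @param voxel_size_um Voxel edge length in micrometres.
#' @return Named numeric vector of per-material lengths in micrometres.
#' @examples
#' vol <- make_phantom("sphere", 6, shells = c(2, 2), volume_dims = c(24, 24, 24))
#' rec <- traverse(vol, c(12, 12, 12), c(0, 0.3, 1))
#' path_lengths(rec, vol$voxel_size_um)
#' @export
path_lengths <- function(record, voxel_size_um) {
  record$counts / record$total_count *
    record$euclidean_length_voxels * voxel_size_um
}

#' Attenuation exponent for one crystal voxel and one reflection
#'
#' Sum over materials of mu_m (L1_m + L2_m): L1 comes from traversing along
#' the reversed incident direction (the ray is traced from the diffracting
#' voxel back toward the source), L2 along the diffracted direction.
#' Background contributes zero.
#'
#' @inheritParams traverse
#' @param coeffs [material_coefficients()].
#' @param n Integer `(z, y, x)` crystal voxel (0-based).
#' @param incident,diffracted Unit `(z, y, x)` propagation directions of the
#'   incoming and outgoing beams.
#' @param precision `"double"` (default) or `"single"`; single precision
#'   mirrors GPU-style FP32 arithmetic for speed/accuracy comparisons.
#' @param on_non_crystal `"error"`, `"warn"` or `"ignore"` when `n` is not
#'   crystal-labelled.
#' @return Non-negative exponent (dimensionless).
#' @export
voxel_exponent <- function(volume, coeffs, n, incident, diffracted,
                           precision = c("double", "single"),
                           on_non_crystal = c("error", "warn", "ignore")) {
  precision <- match.arg(precision)
  on_non_crystal <- match.arg(on_non_crystal)
  n <- as.integer(n)
  code <- volume$labels[n[1] + 1L, n[2] + 1L, n[3] + 1L]
  if (code != volume$label_map[["crystal"]] && on_non_crystal != "ignore") {
    msg <- sprintf("voxel (%d, %d, %d) is not crystal-labelled", n[1], n[2], n[3])
    if (on_non_crystal == "error") stop(msg) else warning(msg)
  }
  exponent_cpp(volume$labels, mu_by_code(volume, coeffs), n,
               as.numeric(incident), as.numeric(diffracted),
               volume$voxel_size_um, precision == "single")
}

#' Absorption factor for a single reflection
#'
#' The mean over the sampled crystal voxels of `exp(-exponent)`, i.e. the
#' per-reflection transmission factor A_h in (0, 1]; equal to 1 when all
#' coefficients are zero.
#'
#' @inheritParams voxel_exponent
#' @param plan Optional [sampling_plan()]; `NULL` means every crystal voxel.
#' @return A single numeric value in (0, 1].
#' @export
absorption_factor <- function(volume, coeffs, incident, diffracted,
                              plan = NULL,
                              precision = c("double", "single")) {
  precision <- match.arg(precision)
  sel <- selection_matrix(volume, plan)
  refl <- as.numeric(c(incident, diffracted))
  mean(voxel_factors_cpp(volume$labels, mu_by_code(volume, coeffs), sel,
                         refl, volume$voxel_size_um, precision == "single"))
}

# n x 3 integer matrix of selected (z, y, x) voxels, sorted row-major
selection_matrix <- function(volume, plan = NULL) {
  sel <- if (is.null(plan)) crystal_voxels(volume) else plan$selected
  if (nrow(sel) == 0L) stop("empty crystal-voxel selection")
  cbind(sel$z, sel$y, sel$x)
}
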