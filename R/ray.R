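#' Exit point of a ray leaving the voxel cuboid
#'
#' The cuboid's six faces are the planes bounding `[0, dim - 1]` on each
#' axis (voxel-center convention). For a ray `P0 + t * d` starting inside,
#' the exit is the minimal non-negative `t` over the outgoing face planes;
#' planes parallel to the ray contribute no candidate. Ties at an edge or
#' corner resolve deterministically to the lowest face index, with faces
#' ordered `x-`, `x+`, `y-`, `y+`, `z-`, `z+`.
#'
#' @param P0 Numeric length-3 point `(z, y, x)` inside the cuboid (0-based
#'   voxel coordinates).
#' @param d Numeric length-3 direction `(z, y, x)`, non-zero; normalized
#'   internally so `t` is in voxel units.
#' @param dims Integer `(z, y, x)` dimensions of the cuboid.
#' @return A list of class `ray_exit` with `t` (distance in voxels),
#'   `exit_point` (on the face plane), and `face` (one of `"x-"`, `"x+"`,
#'   `"y-"`, `"y+"`, `"z-"`, `"z+"`).
#' @examples
#' exit_point(c(5, 5, 5), c(0, 0, 1), c(11, 11, 11))
#' @export
exit_point <- function(P0, d, dims) {
  res <- exit_point_cpp(as.numeric(P0), as.numeric(d), as.integer(dims))
  res$face <- face_names()[res$face]
  class(res) <- "ray_exit"
  res
}

face_names <- function() c("x-", "x+", "y-", "y+", "z-", "z+")

#' @export
print.ray_exit <- function(x, ...) {
  cat(sprintf("<ray_exit> t = %.6g, face %s, point (%.4g, %.4g, %.4g)\n",
              x$t, x$face, x$exit_point[1], x$exit_point[2], x$exit_point[3]))
  invisible(x)
}

#' Discretized ray through a volume
#'
#' Precomputes the stepping parameters of a ray for per-step label queries:
#' the driving (split) axis taken from the ray's exit face, the per-step
#' increment vector (one voxel per step along the driving axis), and the
#' maximum step index `n` at which the ray leaves the volume. Step `s` of the
#' ray is the voxel at `start + s * step`, rounded to the nearest voxel.
#'
#' @param volume A [segmented_volume()].
#' @param start Integer `(z, y, x)` start voxel (0-based).
#' @param d Direction vector `(z, y, x)`, non-zero.
#' @return A list of class `voxel_ray` with `start`, `step`, `n`,
#'   `driving_axis` (`"z"`, `"y"` or `"x"`).
#' @seealso [label_at()], [find_boundary()]
#' @export
ray_param <- function(volume, start, d) {
  start <- as.integer(start)
  dims <- dim(volume$labels)
  if (any(start < 0L) || any(start > dims - 1L)) stop("start outside volume")
  ex <- exit_point_cpp(as.numeric(start), as.numeric(d), dims)
  axis <- c("x-" = 3L, "x+" = 3L, "y-" = 2L, "y+" = 2L,
            "z-" = 1L, "z+" = 1L)[[face_names()[ex$face]]]
  du <- as.numeric(d) / sqrt(sum(as.numeric(d)^2))
  step <- du / abs(du[axis])
  n <- if (du[axis] > 0) dims[axis] - 1L - start[axis] else start[axis]
  structure(
    list(start = start, step = step, n = as.integer(n),
         driving_axis = c("z", "y", "x")[axis]),
    class = "voxel_ray"
  )
}

# round half away from zero, matching the C++ traversal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
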