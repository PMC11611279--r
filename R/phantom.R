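#' Generate a synthetic segmented phantom
#'
#' Builds a segmented volume emulating the tomograms this method consumes:
#' a crystal body (sphere, rod or bipyramid) wrapped in a mother-liquor
#' shell, a loop shell that only partially surrounds the liquor (open on the
#' +y side, as a real mounting loop is, with the liquor drop bulging through
#' the opening), and background (vacuum) elsewhere. The outer surface is
#' convex, so along any ray leaving a crystal voxel the materials appear
#' with no vacuum strictly between crystal and loop — the layered-material
#' assumption of the bisection back-end holds on noiseless phantoms.
#'
#' Shapes mirror the morphologies this correction is used on: `sphere`
#' (insulin-like), `rod` (thermolysin-like, axis along x) and `bipyramid`
#' (thaumatin-like octahedral habit).
#'
#' @param kind `"sphere"`, `"rod"` or `"bipyramid"`.
#' @param crystal_extent_voxels Crystal half-extents in voxels: radius for
#'   `sphere`; `c(radius, half_length)` for `rod`; `c(half_width,
#'   half_height)` for `bipyramid`.
#' @param shells Numeric `c(liquor, loop)` shell thicknesses in voxels;
#'   `c(0, 0)` gives a bare crystal in vacuum.
#' @param volume_dims Integer `(z, y, x)` dimensions of the volume.
#' @param voxel_size_um Isotropic voxel size in micrometres (default 0.3, the
#'   tomographic resolution this engine targets).
#' @param seed Integer seed; only consulted when `noise_rate > 0`.
#' @param noise_rate Fraction of voxels whose label is flipped to a random
#'   other material, emulating segmentation noise. Off (0) by default; note
#'   that noise breaks the layered-material assumption of the bisection
#'   back-end.
#' @param label_map Material code assignment, see [default_label_map()].
#'
#' @return A [segmented_volume()].
#' @examples
#' vol <- make_phantom("sphere", 8, shells = c(3, 2), volume_dims = c(32, 32, 32))
#' table(vol$labels)
#' @export
make_phantom <- function(kind = c("sphere", "rod", "bipyramid"),
                         crystal_extent_voxels,
                         shells = c(liquor = 3, loop = 2),
                         volume_dims = c(32L, 32L, 32L),
                         voxel_size_um = 0.3,
                         seed = 1L,
                         noise_rate = 0,
                         label_map = default_label_map()) {
  kind <- match.arg(kind)
  label_map <- validate_label_map(label_map)
  dims <- as.integer(volume_dims)
  if (length(dims) != 3L || any(dims < 3L)) {
    stop("volume_dims must be three integers >= 3")
  }
  ext <- as.numeric(crystal_extent_voxels)
  s1 <- as.numeric(shells[[1]])
  s2 <- as.numeric(shells[[2]])
  if (s1 < 0 || s2 < 0) stop("shell thicknesses must be non-negative")
  center <- (dims - 1) / 2

  # half-extent of the outermost (loop) body along each (z, y, x) axis
  outer_ext <- switch(kind,
    sphere = rep(ext[1] + s1 + s2, 3),
    rod = c(ext[1] + s1 + s2, ext[1] + s1 + s2, ext[2] + s1 + s2),
    bipyramid = c(ext[2] + s1 + s2, ext[1] + s1 + s2, ext[1] + s1 + s2)
  )
  # any positive clearance leaves >= 1 integer background coordinate per face
  margin <- pmin(center, dims - 1 - center) - outer_ext
  if (any(margin <= 0)) {
    stop("bodies do not fit: need >= 1 voxel of background margin on every face")
  }

  tmpl <- array(0L, dim = dims)
  Z <- slice.index(tmpl, 1) - 1 - center[1]
  Y <- slice.index(tmpl, 2) - 1 - center[2]
  X <- slice.index(tmpl, 3) - 1 - center[3]

  inside <- function(extra) {
    switch(kind,
      sphere = sqrt(Z^2 + Y^2 + X^2) <= ext[1] + extra,
      rod = sqrt(Z^2 + Y^2) <= ext[1] + extra & abs(X) <= ext[2] + extra,
      bipyramid = abs(Y) / (ext[1] + extra) + abs(X) / (ext[1] + extra) +
        abs(Z) / (ext[2] + extra) <= 1
    )
  }

  lab <- tmpl + label_map[["background"]]
  if ((s1 > 0 || s2 > 0) && "liquor" %in% names(label_map)) {
    # liquor fills the loop opening out to the outer surface: the outer body
    # stays convex, so no ray can meet vacuum strictly between crystal and
    # loop (the layered-material assumption of the bisection back-end)
    lab[inside(s1 + s2) & !inside(0)] <- label_map[["liquor"]]
  }
  if (s2 > 0 && "loop" %in% names(label_map)) {
    lab[inside(s1 + s2) & !inside(s1) & Y <= 0] <- label_map[["loop"]]
  }
  lab[inside(0)] <- label_map[["crystal"]]

  if (noise_rate > 0) {
    lab <- with_local_seed(seed, flip_labels(lab, noise_rate, label_map))
  }
  segmented_volume(lab, voxel_size_um = voxel_size_um, label_map = label_map)
}

flip_labels <- function(lab, rate, label_map) {
  n <- length(lab)
  hit <- which(stats::runif(n) < rate)
  if (length(hit) > 0L) {
    codes <- unname(label_map)
    cur <- lab[hit]
    repl <- codes[sample.int(length(codes), length(hit), replace = TRUE)]
    same <- repl == cur
    while (any(same)) {
      repl[same] <- codes[sample.int(length(codes), sum(same), replace = TRUE)]
      same <- repl == cur
    }
    lab[hit] <- repl
  }
  lab
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
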