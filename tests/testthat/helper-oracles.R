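# Independent oracles used across the suite.

# Dense-marching path-length oracle: walk the ray in tiny steps, look up the
# nearest voxel at each point, and accumulate length per material. Entirely
# independent of the traversal code path (pure R, geometric occupancy).
march_lengths <- function(volume, start, d, step = 1e-3) {
  du <- as.numeric(d) / sqrt(sum(d^2))
  dims <- dim(volume$labels)
  ex <- exit_point(as.numeric(start), du, dims)
  tt <- seq(0, ex$t, by = step)
  co <- sweep(outer(tt, du), 2, as.numeric(start), `+`)
  co <- pmin(pmax(floor(co + 0.5), 0), matrix(dims - 1, nrow(co), 3, byrow = TRUE))
  lin <- co[, 1] + dims[1] * co[, 2] + dims[1] * dims[2] * co[, 3] + 1
  codes <- as.vector(volume$labels)[lin]
  counts <- tabulate(codes + 1L, nbins = max(volume$label_map) + 1L)
  lens <- counts[volume$label_map + 1L] * step
  names(lens) <- names(volume$label_map)
  lens  # in voxel units
}

# Per-material lengths (voxel units) from the package's traversal route.
traverse_lengths_voxels <- function(volume, start, d) {
  rec <- traverse(volume, start, d)
  path_lengths(rec, 1)  # voxel_size 1 => voxel units
}

# Linear scan for the last step (from lo) at which pred holds, via label_at.
scan_boundary <- function(volume, ray, target, lo, hi) {
  pred <- if (is.function(target)) target else function(m) m == target
  plo <- pred(label_at(volume, ray, lo))
  for (s in lo:hi) {
    if (pred(label_at(volume, ray, s)) != plo) return(s - 1L)
  }
  hi
}

# Brute-force two-sample ECDF sup-difference.
ecdf_sup_diff <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

# A 1 x 1 x n "stripe" volume with an explicit label sequence along x.
stripe_volume <- function(codes, voxel_size_um = 0.3) {
  segmented_volume(array(as.integer(codes), dim = c(1, 1, length(codes))),
                   voxel_size_um)
}

# Standard fixture: 32^3 four-material sphere phantom.
sphere32 <- function() {
  make_phantom("sphere", 8, shells = c(3, 2), volume_dims = c(32, 32, 32),
               voxel_size_um = 0.3)
}

# Uniformly random unit vector, given the current RNG stream.
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
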