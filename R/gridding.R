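#' Angular grid of one-way attenuation exponents for one crystal voxel
#'
#' Precomputes, for rays leaving the voxel in every direction on a 1-degree
#' spherical grid, the one-way exponent sum_m mu_m L_m using the standard
#' traversal machinery. The grid has shape (360, 180): row i is azimuth
#' theta = i - 1 degrees about the z axis, column j is polar angle
#' phi = j - 1 degrees from +z; the direction is
#' `(cos phi, sin phi sin theta, sin phi cos theta)` in `(z, y, x)`.
#' A padded copy of shape (420, 210) with wrap-around continuation is kept
#' for edge-safe nearest-neighbour queries.
#'
#' @inheritParams voxel_exponent
#' @return An object of class `angular_grid`: list with `voxel`, `values`
#'   ((360, 180) matrix), `padded` ((420, 210) matrix).
#' @export
build_voxel_grid <- function(volume, coeffs, n,
                             on_non_crystal = c("error", "warn", "ignore")) {
  on_non_crystal <- match.arg(on_non_crystal)
  n <- as.integer(n)
  code <- volume$labels[n[1] + 1L, n[2] + 1L, n[3] + 1L]
  if (code != volume$label_map[["crystal"]] && on_non_crystal != "ignore") {
    msg <- sprintf("voxel (%d, %d, %d) is not crystal-labelled", n[1], n[2], n[3])
    if (on_non_crystal == "error") stop(msg) else warning(msg)
  }
  values <- grid_cpp(volume$labels, mu_by_code(volume, coeffs), n,
                     volume$voxel_size_um)
  structure(list(voxel = n, values = values, padded = pad_grid(values)),
            class = "angular_grid")
}

#' Pad an angular grid for edge-continuous interpolation
#'
#' Extends a (360, 180) grid to (420, 210): 30 degrees of azimuth padding per
#' side wrapping modulo 360, and 15 degrees of polar padding per side
#' reflecting across the poles (phi = -k maps to phi = k at theta + 180; past
#' the south pole the mirror row is clamped to phi = 179, a <= 1 degree
#' approximation at the pole where all azimuths converge).
#'
#' @param values Numeric (360, 180) matrix.
#' @return Numeric (420, 210) matrix whose central block equals `values`.
#' @export
pad_grid <- function(values) {
  if (!identical(dim(values), c(360L, 180L))) {
    stop("grid must have shape (360, 180)")
  }
  opp <- c(181:360, 1:180)  # theta + 180 degrees
  top <- values[opp, 16:2, drop = FALSE]                # phi = -15 .. -1 -> 15 .. 1
  bottom_cols <- pmin(180L, 181L - 0:14)                # phi = 180 .. 194 mirrored
  bottom <- values[opp, bottom_cols, drop = FALSE]
  phip <- cbind(top, values, bottom)                    # 360 x 210
  rbind(phip[331:360, , drop = FALSE], phip, phip[1:30, , drop = FALSE])
}

#' Direction vector of an angular-grid node
#'
#' @param theta_deg Azimuth in degrees about z (0-359 on the grid).
#' @param phi_deg Polar angle in degrees from +z (0-179 on the grid).
#' @return Unit `(z, y, x)` direction, bitwise identical to the direction
#'   used when building grids.
#' @export
grid_node_direction <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  c(cos(ph), sin(ph) * sin(th), sin(ph) * cos(th))
}

#' Nearest-neighbour lookup of a one-way exponent
#'
#' Converts a direction to spherical angles and returns the value of the
#' nearest node on the padded grid; queries exactly on a node return that
#' node's value unchanged.
#'
#' @param grid An `angular_grid` from [build_voxel_grid()].
#' @param direction `(z, y, x)` direction vector, non-zero.
#' @return Non-negative exponent.
#' @export
interpolate_exponent <- function(grid, direction) {
  idx <- grid_query_index(direction)
  grid$padded[idx[1], idx[2]]
}

# padded-grid (row, col) of the node nearest to `direction`
grid_query_index <- function(direction) {
  d <- as.numeric(direction)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("zero direction vector")
  d <- d / nrm
  theta <- atan2(d[2], d[3]) * 180 / pi
  if (theta < 0) theta <- theta + 360
  phi <- acos(min(1, max(-1, d[1]))) * 180 / pi
  c(round(theta) + 31, round(phi) + 16)
}

#' @export
print.angular_grid <- function(x, ...) {
  cat(sprintf("<angular_grid> voxel (%d, %d, %d): (360, 180) @ 1 deg, padded (420, 210)\n",
              x$voxel[1], x$voxel[2], x$voxel[3]))
  invisible(x)
}

#' Gridding back-end driver
#'
#' Builds one angular grid per sampled crystal voxel (once), then answers
#' each reflection by two nearest-neighbour lookups per voxel — reversed
#' incident plus diffracted direction — so the build cost is amortized over
#' arbitrarily many reflections. Grids are double precision, about 0.5 MB
#' per voxel; the builder refuses plans whose total grid memory would exceed
#' `memory_budget_bytes`.
#'
#' @inheritParams run_standard
#' @param cache_dir Optional directory for an on-disk grid cache keyed by
#'   volume checksum and coefficient hash; a cached file whose checksum does
#'   not match the volume errors.
#' @param memory_budget_bytes Refuse to build more grid memory than this
#'   (default 2 GiB).
#' @return An `absorption_result` tibble.
#' @export
run_gridding <- function(volume, coeffs, reflections, plan = NULL,
                         workers = 1L, cache_dir = NULL,
                         memory_budget_bytes = 2^31) {
  refl <- reflections_matrix(reflections)
  if (nrow(refl) == 0L) {
    return(absorption_result(numeric(0), method = "gridding",
                             volume = volume, plan = plan))
  }
  sel <- selection_matrix(volume, plan)
  need <- nrow(sel) * 360 * 180 * 8
  if (need > memory_budget_bytes) {
    stop(sprintf("plan needs %.2f GiB of grids, over the %.2f GiB budget; %s",
                 need / 2^30, memory_budget_bytes / 2^30,
                 "use a smaller sampling ratio or raise memory_budget_bytes"))
  }
  mu <- mu_by_code(volume, coeffs)

  grids <- NULL
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir, sprintf("grids-%s.rds", volume_checksum(volume)))
    if (file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (!identical(cached$checksum, volume_checksum(volume))) {
        stop("grid cache/volume checksum mismatch: ", cache_file)
      }
      if (identical(cached$coeffs, coeff_hash(coeffs)) &&
          identical(cached$sel, sel)) {
        grids <- cached$grids
      }
    }
  }
  if (is.null(grids)) {
    padded <- run_chunked_list(nrow(sel), workers, function(rows) {
      lapply(rows, function(i) {
        pad_grid(grid_cpp(volume$labels, mu, sel[i, ], volume$voxel_size_um))
      })
    })
    grids <- padded
    if (!is.null(cache_file)) {
      saveRDS(list(checksum = volume_checksum(volume),
                   coeffs = coeff_hash(coeffs), sel = sel, grids = grids),
              cache_file)
    }
  }

  # one (row, col) node index pair per reflection; shared by all voxels
  idx_inc <- t(apply(refl[, 1:3, drop = FALSE], 1, function(v) grid_query_index(-v)))
  idx_dif <- t(apply(refl[, 4:6, drop = FALSE], 1, function(v) grid_query_index(v)))
  factors <- vapply(seq_len(nrow(refl)), function(r) {
    expo <- vapply(grids, function(g) {
      g[idx_inc[r, 1], idx_inc[r, 2]] + g[idx_dif[r, 1], idx_dif[r, 2]]
    }, numeric(1))
    mean_exp_neg_cpp(expo)
  }, numeric(1))
  absorption_result(factors, method = "gridding", volume = volume, plan = plan,
                    extra = list(n_grids = length(grids)))
}

# like run_chunked but for list-valued chunks
run_chunked_list <- function(n, workers, fn) {
  if (n == 0L) return(list())
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || n < 2L * workers || .Platform$OS.type != "unix") {
    return(fn(seq_len(n)))
  }
  chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
  res <- parallel::mclapply(chunks, fn, mc.cores = workers)
  err <- vapply(res, inherits, logical(1), "try-error")
  if (any(err)) stop("worker failure: ", res[[which(err)[1]]])
  do.call(c, res)
}
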