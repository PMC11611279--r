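#' Compute absorption factors (tidy front end)
#'
#' The main entry point: takes a reflection table, dispatches one of the
#' three back-ends, and returns the table augmented with the per-reflection
#' absorption factor `A` in input order.
#'
#' @param reflections A data frame with numeric columns `ix, iy, iz`
#'   (incident beam propagation direction) and `dx, dy, dz` (diffracted
#'   direction); norms must lie in \[0.99, 1.01\] and are renormalized.
#'   See [load_reflections()].
#' @param volume A [segmented_volume()].
#' @param coeffs [material_coefficients()].
#' @param method `"standard"` (voxel traversal), `"bisection"` (boundary
#'   search) or `"gridding"` (precomputed angular grids).
#' @param plan Optional [sampling_plan()] restricting the crystal-voxel sum;
#'   `NULL` uses every crystal voxel.
#' @param workers Number of parallel workers (forked; results are identical
#'   for any worker count).
#' @param precision `"double"` or `"single"` (standard back-end only).
#' @param ... Passed on to the back-end driver (e.g. `cache_dir` for
#'   gridding).
#' @return An `absorption_result`: a tibble with columns `index` and `A`
#'   (one row per reflection, input order), carrying method and sampling
#'   metadata in attributes. Use [generics::tidy()] / [generics::glance()].
#' @examples
#' vol <- make_phantom("sphere", 6, shells = c(2, 2), volume_dims = c(24, 24, 24))
#' mu <- material_coefficients(preset = "insulin")
#' refl <- random_reflections(5, seed = 1)
#' refl |> absorb(vol, mu, method = "standard")
#' @export
absorb <- function(reflections, volume, coeffs,
                   method = c("standard", "bisection", "gridding"),
                   plan = NULL, workers = 1L,
                   precision = c("double", "single"), ...) {
  method <- match.arg(method)
  switch(method,
    standard = run_standard(volume, coeffs, reflections, plan = plan,
                            workers = workers, precision = precision),
    bisection = run_bisection(volume, coeffs, reflections, plan = plan,
                              workers = workers),
    gridding = run_gridding(volume, coeffs, reflections, plan = plan,
                            workers = workers, ...)
  )
}

#' Standard ray-tracing driver
#'
#' Computes A_h for every reflection by full voxel traversal of the reversed
#' incident and diffracted rays from each sampled crystal voxel. Results are
#' independent of `workers` and preserve the input reflection order.
#'
#' @inheritParams absorb
#' @return An `absorption_result` tibble.
#' @export
run_standard <- function(volume, coeffs, reflections, plan = NULL,
                         workers = 1L, precision = c("double", "single")) {
  precision <- match.arg(precision)
  refl <- reflections_matrix(reflections)
  sel <- if (nrow(refl) > 0L) selection_matrix(volume, plan) else NULL
  mu <- mu_by_code(volume, coeffs)
  fp32 <- precision == "single"
  factors <- run_chunked(nrow(refl), workers, function(rows) {
    factors_cpp(volume$labels, mu, sel, refl[rows, , drop = FALSE],
                volume$voxel_size_um, fp32)
  })
  absorption_result(factors, method = "standard", volume = volume,
                    plan = plan, precision = precision)
}

# Split 1:n into worker chunks, compute, reassemble in order. Each reflection
# is computed independently, so the result is bitwise identical for any
# worker count.
run_chunked <- function(n, workers, fn) {
  if (n == 0L) return(numeric(0))
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || n < 2L * workers || .Platform$OS.type != "unix") {
    return(fn(seq_len(n)))
  }
  chunks <- split(seq_len(n), cut(seq_len(n), workers, labels = FALSE))
  res <- parallel::mclapply(chunks, fn, mc.cores = workers)
  err <- vapply(res, inherits, logical(1), "try-error")
  if (any(err)) stop("worker failure: ", res[[which(err)[1]]])
  unlist(res, use.names = FALSE)
}

absorption_result <- function(factors, method, volume, plan,
                              precision = "double", extra = list()) {
  out <- tibble::tibble(index = seq_along(factors), A = as.numeric(factors))
  attr(out, "method") <- method
  attr(out, "precision") <- precision
  attr(out, "sampling") <- if (is.null(plan)) {
    list(method = "none", ratio = 1, seed = NA_integer_,
         n_selected = nrow(crystal_voxels(volume)))
  } else {
    list(method = plan$method, ratio = plan$ratio, seed = plan$seed,
         n_selected = nrow(plan$selected))
  }
  attr(out, "volume_checksum") <- volume_checksum(volume)
  attr(out, "voxel_size_um") <- volume$voxel_size_um
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("absorption_result", class(out))
  out
}

#' @export
print.absorption_result <- function(x, ...) {
  s <- attr(x, "sampling")
  cat(sprintf("<absorption_result> %d reflections, method = %s, sampling = %s (ratio %g)\n",
              nrow(x), attr(x, "method"), s$method, s$ratio))
  NextMethod()
}

# internal: reflection table -> m x 6 matrix (iz, iy, ix, dz, dy, dx) of
# unit vectors in the (z, y, x) frame
reflections_matrix <- function(reflections) {
  if (is.matrix(reflections)) {
    stopifnot(ncol(reflections) == 6L)
    m <- reflections
  } else {
    need <- c("ix", "iy", "iz", "dx", "dy", "dz")
    missing_cols <- setdiff(need, names(reflections))
    if (length(missing_cols) > 0L) {
      stop("reflection table lacks columns: ", paste(missing_cols, collapse = ", "))
    }
    m <- cbind(reflections$iz, reflections$iy, reflections$ix,
               reflections$dz, reflections$dy, reflections$dx)
  }
  if (nrow(m) == 0L) return(m)
  if (any(!is.finite(m))) stop("non-numeric or non-finite reflection entries")
  for (block in list(1:3, 4:6)) {
    nrm <- sqrt(rowSums(m[, block, drop = FALSE]^2))
    bad <- which(nrm < 0.99 | nrm > 1.01)
    if (length(bad) > 0L) {
      stop("direction vectors with norm outside [0.99, 1.01] in rows: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    m[, block] <- m[, block, drop = FALSE] / nrm
  }
  m
}
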