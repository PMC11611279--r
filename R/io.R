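#' Read a reflection table
#'
#' Accepts CSV (header `ix,iy,iz,dx,dy,dz`) or JSON (array of objects with
#' the same fields): the propagation direction of the incident beam and the
#' diffracted beam direction per reflection, in laboratory (x, y, z)
#' components consistent with the volume's (z, y, x) frame. Vector norms
#' must lie in \[0.99, 1.01\] and are renormalized to unit length; rows with
#' zero or malformed vectors error, naming the row.
#'
#' @param path CSV or JSON file.
#' @return A tibble with `index`, `ix`, `iy`, `iz`, `dx`, `dy`, `dz`
#'   (unit-normalized).
#' @export
load_reflections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    utils::read.csv(path)
  }
  df <- tibble::as_tibble(df)
  need <- c("ix", "iy", "iz", "dx", "dy", "dz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("reflection table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (cn in need) {
    if (!is.numeric(df[[cn]])) stop("non-numeric entries in column ", cn)
    if (any(!is.finite(df[[cn]]))) stop("non-finite entries in column ", cn)
  }
  for (block in list(c("ix", "iy", "iz"), c("dx", "dy", "dz"))) {
    nrm <- sqrt(df[[block[1]]]^2 + df[[block[2]]]^2 + df[[block[3]]]^2)
    bad <- which(nrm < 0.99 | nrm > 1.01)
    if (length(bad) > 0L) {
      stop("rows with direction norm outside [0.99, 1.01]: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    for (cn in block) df[[cn]] <- df[[cn]] / nrm
  }
  dplyr::bind_cols(tibble::tibble(index = seq_len(nrow(df))), df[need])
}

#' Generate random reflections for testing
#'
#' Incident and diffracted directions drawn independently and uniformly on
#' the unit sphere; a physical reflection table would relate them through
#' the scattering angle, which is irrelevant for exercising the path-length
#' machinery.
#'
#' @param n Number of reflections.
#' @param seed Integer seed.
#' @return A reflection tibble as from [load_reflections()].
#' @export
random_reflections <- function(n, seed = 1L) {
  with_local_seed(seed, {
    u <- matrix(stats::rnorm(6 * n), ncol = 6)
    ni <- sqrt(rowSums(u[, 1:3, drop = FALSE]^2))
    nd <- sqrt(rowSums(u[, 4:6, drop = FALSE]^2))
    tibble::tibble(
      index = seq_len(n),
      ix = u[, 1] / ni, iy = u[, 2] / ni, iz = u[, 3] / ni,
      dx = u[, 4] / nd, dy = u[, 5] / nd, dz = u[, 6] / nd
    )
  })
}

#' Write absorption factors to JSON
#'
#' Emits `{"factors": [...], "metadata": {...}}`: a bare array of factors in
#' input reflection order (the format consumed downstream by scaling
#' programs) plus a metadata block — method, sampling strategy/ratio/seed,
#' volume checksum — sufficient to reproduce the run.
#'
#' @param result An `absorption_result` from [absorb()] or a back-end driver.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factors <- function(result, path) {
  s <- attr(result, "sampling")
  jsonlite::write_json(
    list(
      factors = result$A,
      metadata = list(
        method = attr(result, "method"),
        precision = attr(result, "precision") %||% "double",
        sampling = s,
        volume_checksum = attr(result, "volume_checksum"),
        n_reflections = nrow(result)
      )
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_factors
#' @return `read_factors()`: a list with `factors` (numeric vector) and
#'   `metadata`.
#' @export
read_factors <- function(path) {
  out <- jsonlite::fromJSON(path)
  out$factors <- as.numeric(out$factors)
  out
}
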