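#' Segmented voxel model of a crystallography sample
#'
#' A `segmented_volume` wraps a 3D integer label array in `(z, y, x)` axis
#' order (z is the slice-stacking axis), together with the isotropic voxel
#' edge length in micrometres and a label map naming each material code.
#' Voxel centers sit at integer coordinates and the cuboid occupies
#' `[0, dim - 1]` along each axis; all coordinates in this package are
#' 0-based in that frame.
#'
#' @param labels 3D integer array of material codes, axis order `(z, y, x)`.
#' @param voxel_size_um Positive isotropic voxel edge length in micrometres.
#' @param label_map Named integer vector mapping material names to codes.
#'   Must contain at least `background` and `crystal`; codes must be distinct
#'   and non-negative.
#'
#' @return An object of class `segmented_volume`: a list with elements
#'   `labels`, `voxel_size_um`, `label_map`.
#' @examples
#' lab <- array(3L, dim = c(4, 4, 4))
#' vol <- segmented_volume(lab, voxel_size_um = 0.3)
#' vol
#' @export
segmented_volume <- function(labels, voxel_size_um, label_map = default_label_map()) {
  if (length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array, got ", length(dim(labels)), " dimensions")
  }
  if (any(dim(labels) < 1L)) stop("all three dimensions must be >= 1")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  label_map <- validate_label_map(label_map)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_map))
  if (length(bad) > 0L) {
    stop("labels contain codes absent from label_map: ",
         paste(sort(bad), collapse = ", "))
  }
  structure(
    list(labels = labels, voxel_size_um = voxel_size_um, label_map = label_map),
    class = "segmented_volume"
  )
}

#' Default material label codes
#'
#' Background (vacuum/air) is 0, mother liquor 1, loop 2, crystal 3. Any
#' other assignment can be supplied through the `label_map` arguments.
#'
#' @return Named integer vector.
#' @export
default_label_map <- function() {
  c(background = 0L, liquor = 1L, loop = 2L, crystal = 3L)
}

validate_label_map <- function(label_map) {
  lm <- as.integer(label_map)
  names(lm) <- names(label_map)
  if (is.null(names(lm)) || any(!nzchar(names(lm)))) {
    stop("label_map must be a named integer vector")
  }
  if (anyDuplicated(lm)) stop("label codes must be distinct")
  if (anyDuplicated(names(lm))) stop("material names must be distinct")
  if (any(lm < 0L)) stop("label codes must be non-negative")
  for (req in c("background", "crystal")) {
    if (!req %in% names(lm)) stop("label_map must name a '", req, "' material")
  }
  lm
}

#' @export
print.segmented_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<segmented_volume> %d x %d x %d voxels (z, y, x) @ %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  tab <- tabulate(as.vector(x$labels) + 1L, nbins = max(x$label_map) + 1L)
  for (m in names(x$label_map)) {
    cat(sprintf("  %-10s code %d: %d voxels\n", m, x$label_map[[m]],
                tab[x$label_map[[m]] + 1L]))
  }
  invisible(x)
}

#' @export
dim.segmented_volume <- function(x) dim(x$labels)

max_code <- function(volume) max(volume$label_map)

#' Content checksum of a volume's labels
#'
#' FNV-1a 64-bit hash of the raw label buffer, used to key grid caches and
#' stamp output metadata.
#'
#' @param volume A [segmented_volume()].
#' @return A 16-character hex string.
#' @export
volume_checksum <- function(volume) checksum_cpp(volume$labels)

#' Enumerate crystal voxels in row-major order
#'
#' Returns the 0-based coordinates of every crystal-labelled voxel, sorted in
#' row-major `(z, y, x)` order (z slowest, x fastest). This sorted list is the
#' summation set whose size N enters the absorption-factor mean, and the 1D
#' array over which systematic sampling strides.
#'
#' @param volume A [segmented_volume()].
#' @return A tibble with integer columns `z`, `y`, `x` (0-based), one row per
#'   crystal voxel, ordered.
#' @examples
#' vol <- make_phantom("sphere", 4, shells = c(2, 1), volume_dims = c(16, 16, 16))
#' nrow(crystal_voxels(vol))
#' @export
crystal_voxels <- function(volume) {
  idx <- which(volume$labels == volume$label_map[["crystal"]], arr.ind = TRUE)
  out <- tibble::tibble(z = idx[, 1] - 1L, y = idx[, 2] - 1L, x = idx[, 3] - 1L)
  out[order(out$z, out$y, out$x), , drop = FALSE]
}

#' Load a segmented volume from disk
#'
#' Supported formats: `npy` (NumPy v1.0, C- or Fortran-order integer array)
#' and `tiff` (multi-page stack, one page per z slice). HDF5 input is not
#' supported.
#'
#' @param path Path to the volume file.
#' @param format One of `"npy"`, `"tiff"`; guessed from the file extension
#'   when omitted.
#' @inheritParams segmented_volume
#' @return A validated [segmented_volume()].
#' @export
load_volume <- function(path, format = c("auto", "npy", "tiff", "hdf5"),
                        voxel_size_um, label_map = default_label_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      npy = "npy", tif = "tiff", tiff = "tiff",
      h5 = "hdf5", hdf5 = "hdf5",
      stop("cannot guess format from extension of ", path)
    )
  }
  labels <- switch(format,
    npy = read_npy(path),
    tiff = read_tiff_stack(path),
    hdf5 = stop("HDF5 volumes are not supported; convert to NPY or TIFF")
  )
  segmented_volume(labels, voxel_size_um = voxel_size_um, label_map = label_map)
}

#' Save a segmented volume to disk
#'
#' Writes the label array as a NumPy `.npy` file (int32, C-order) so volumes
#' round-trip between this package and NumPy-based tooling.
#'
#' @param volume A [segmented_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  write_npy(volume$labels, path)
  invisible(path)
}

# --- minimal NumPy .npy v1.0 reader/writer (3D integer arrays) ------------

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexec("'descr':\\s*'([^']+)'", header))[[1]][2]
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- regmatches(header, regexec("'shape':\\s*\\(([^)]*)\\)", header))[[1]][2]
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  if (length(shape) != 3L) stop("NPY array is not 3D (shape ", shape_s, ")")
  n <- prod(shape)
  type <- substr(descr, nchar(descr) - 1L, nchar(descr))
  endian <- if (substr(descr, 1, 1) == ">") "big" else "little"
  dat <- switch(type,
    i1 = readBin(con, "integer", n, size = 1L),
    u1 = readBin(con, "integer", n, size = 1L, signed = FALSE),
    i2 = readBin(con, "integer", n, size = 2L, endian = endian),
    u2 = readBin(con, "integer", n, size = 2L, endian = endian, signed = FALSE),
    i4 = readBin(con, "integer", n, size = 4L, endian = endian),
    i8 = {
      # decode int64 as word pairs; label codes must fit in 32 bits
      w <- readBin(con, "integer", 2L * n, size = 4L, endian = endian)
      lo <- if (endian == "little") w[c(TRUE, FALSE)] else w[c(FALSE, TRUE)]
      hi <- if (endian == "little") w[c(FALSE, TRUE)] else w[c(TRUE, FALSE)]
      if (any(hi != 0L & hi != -1L)) stop("int64 label values exceed 32-bit range")
      lo
    },
    stop("unsupported NPY dtype: ", descr)
  )
  if (fortran) {
    array(dat, dim = shape)
  } else {
    # C-order: last axis varies fastest; build reversed then permute
    aperm(array(dat, dim = rev(shape)), 3:1)
  }
}

write_npy <- function(arr, path) {
  shape <- dim(arr)
  header <- sprintf("{'descr': '<i4', 'fortran_order': False, 'shape': (%s), }",
                    paste0(paste(shape, collapse = ", "), ""))
  # pad so that 10 + header length is a multiple of 64, newline-terminated
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(aperm(arr, 3:1)), con, size = 4L, endian = "little")
  invisible(path)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0L, dim = c(length(pages), d2[1], d2[2]))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d2)) stop("TIFF pages differ in size")
    arr[i, , ] <- as.integer(pages[[i]])
  }
  arr
}
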