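#' Crystal-voxel sampling plans
#'
#' The absorption factor is a mean over crystal voxels; neighbouring voxels
#' contribute near-identical terms, so a representative subset suffices.
#' Four strategies are provided over the row-major-sorted crystal-voxel
#' list: `systematic` (every k-th voxel, k = round(1/ratio); a 0.05% ratio
#' gives the classic interval of 2000), `randomized_systematic` (one uniform
#' draw per interval), `random` (uniform without replacement) and
#' `stratified` (k-means over voxel coordinates plus distance to the crystal
#' centroid; cluster-nearest voxels are selected). The default strategy and
#' ratio (systematic, 0.5%) match the regime where sampled factor
#' distributions become statistically indistinguishable from full
#' enumeration.
#'
#' @param volume A [segmented_volume()].
#' @param method Sampling strategy.
#' @param ratio Sampling ratio in (0, 1]; 1 selects every crystal voxel.
#' @param seed Integer seed for the stochastic strategies.
#' @param offset Starting index for `systematic` (0-based).
#' @return A `sampling_plan`: list with `method`, `ratio`, `seed`, `offset`,
#'   `positions` (0-based positions into the sorted crystal list, ascending)
#'   and `selected` (tibble of `z`, `y`, `x`).
#' @examples
#' vol <- make_phantom("sphere", 8, shells = c(2, 1), volume_dims = c(32, 32, 32))
#' plan <- sampling_plan(vol, "systematic", ratio = 0.05)
#' nrow(plan$selected)
#' @export
sampling_plan <- function(volume,
                          method = c("systematic", "randomized_systematic",
                                     "random", "stratified"),
                          ratio = 0.005, seed = 1L, offset = 0L) {
  method <- match.arg(method)
  cl <- crystal_voxels(volume)
  switch(method,
    systematic = systematic_sample(cl, ratio, offset = offset),
    randomized_systematic = randomized_systematic_sample(cl, ratio, seed = seed),
    random = random_sample(cl, ratio, seed = seed),
    stratified = stratified_sample(volume, ratio, seed = seed)
  )
}

check_ratio <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stop("ratio must be in (0, 1]")
  }
  ratio
}

new_plan <- function(method, ratio, seed, offset, positions, crystal_list) {
  positions <- sort(unique(as.integer(positions)))
  structure(
    list(method = method, ratio = ratio, seed = seed, offset = offset,
         positions = positions,
         selected = crystal_list[positions + 1L, , drop = FALSE],
         n_total = nrow(crystal_list)),
    class = "sampling_plan"
  )
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> %s, ratio %g: %d of %d crystal voxels\n",
              x$method, x$ratio, length(x$positions), x$n_total))
  invisible(x)
}

#' Systematic sampling of the sorted crystal-voxel list
#'
#' Selects positions `offset, offset + k, offset + 2k, ...` with interval
#' `k = max(1, round(1 / ratio))`; deterministic.
#'
#' @param crystal_list Sorted crystal voxels, see [crystal_voxels()].
#' @inheritParams sampling_plan
#' @export
systematic_sample <- function(crystal_list, ratio, offset = 0L) {
  check_ratio(ratio)
  N <- nrow(crystal_list)
  if (N == 0L) stop("no crystal voxels to sample")
  k <- max(1L, as.integer(round(1 / ratio)))
  offset <- as.integer(offset) %% k
  new_plan("systematic", ratio, NA_integer_, offset,
           seq.int(offset, N - 1L, by = k), crystal_list)
}

#' Randomized systematic sampling
#'
#' One voxel drawn uniformly inside each length-k interval of the sorted
#' crystal list instead of at its edge; reproducible for a fixed seed.
#'
#' @inheritParams systematic_sample
#' @export
randomized_systematic_sample <- function(crystal_list, ratio, seed = 1L) {
  check_ratio(ratio)
  N <- nrow(crystal_list)
  if (N == 0L) stop("no crystal voxels to sample")
  k <- max(1L, as.integer(round(1 / ratio)))
  starts <- seq.int(0L, N - 1L, by = k)
  pos <- with_local_seed(seed, {
    ends <- pmin(starts + k - 1L, N - 1L)
    starts + floor(stats::runif(length(starts)) * (ends - starts + 1L))
  })
  new_plan("randomized_systematic", ratio, as.integer(seed), 0L, pos, crystal_list)
}

#' Uniform random sampling without replacement
#'
#' @inheritParams systematic_sample
#' @export
random_sample <- function(crystal_list, ratio, seed = 1L) {
  check_ratio(ratio)
  N <- nrow(crystal_list)
  if (N == 0L) stop("no crystal voxels to sample")
  size <- max(1L, as.integer(round(ratio * N)))
  pos <- with_local_seed(seed, sample.int(N, size) - 1L)
  new_plan("random", ratio, as.integer(seed), 0L, pos, crystal_list)
}

#' Stratified sampling by spatial k-means
#'
#' Clusters crystal voxels on the features (z, y, x, distance to the crystal
#' centroid) into S = max(1, round(ratio * N)) regions (k-means, single
#' random initialization from `seed`, at most 300 iterations) and selects
#' the crystal voxel nearest each cluster centre.
#'
#' @inheritParams sampling_plan
#' @export
stratified_sample <- function(volume, ratio, seed = 1L) {
  check_ratio(ratio)
  cl <- crystal_voxels(volume)
  N <- nrow(cl)
  if (N == 0L) stop("no crystal voxels to sample")
  S <- max(1L, as.integer(round(ratio * N)))
  if (S > N) stop("requested more strata than crystal voxels")
  if (S == N) {
    return(new_plan("stratified", ratio, as.integer(seed), 0L,
                    seq.int(0L, N - 1L), cl))
  }
  centroid <- colMeans(cl)
  feats <- cbind(cl$z, cl$y, cl$x,
                 sqrt((cl$z - centroid[["z"]])^2 + (cl$y - centroid[["y"]])^2 +
                        (cl$x - centroid[["x"]])^2))
  km <- with_local_seed(seed, suppressWarnings(
    stats::kmeans(feats, centers = S, iter.max = 300L, nstart = 1L)
  ))
  # nearest distinct crystal voxel to each cluster centre (greedy, no reuse)
  taken <- logical(N)
  pos <- integer(nrow(km$centers))
  for (i in seq_len(nrow(km$centers))) {
    d2 <- rowSums(sweep(feats, 2, km$centers[i, ])^2)
    d2[taken] <- Inf
    j <- which.min(d2)
    pos[i] <- j - 1L
    taken[j] <- TRUE
  }
  new_plan("stratified", ratio, as.integer(seed), 0L, pos, cl)
}

#' Serialize / restore a sampling plan
#'
#' Plans are written as JSON (method, ratio, seed, offset, 0-based
#' positions) so any run can be reproduced exactly.
#'
#' @param plan A `sampling_plan`.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(method = plan$method, ratio = plan$ratio, seed = plan$seed,
         offset = plan$offset, n_total = plan$n_total,
         positions = plan$positions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @param volume The volume the plan indexes into (positions refer to its
#'   sorted crystal-voxel list).
#' @export
read_plan <- function(path, volume) {
  p <- jsonlite::fromJSON(path)
  cl <- crystal_voxels(volume)
  if (p$n_total != nrow(cl)) {
    stop("plan was built for a volume with ", p$n_total,
         " crystal voxels, this one has ", nrow(cl))
  }
  new_plan(p$method, p$ratio, p$seed, p$offset %||% 0L, p$positions, cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kolmogorov-Smirnov comparison of sampled vs full factor distributions
#'
#' Two-sample KS test between the per-voxel linear factors exp(-exponent)
#' of a sampled plan and of full (100%) sampling for one reflection; the
#' statistic is 0 and the p-value 1 when the samples coincide.
#'
#' @param full_values Per-voxel factors at full sampling.
#' @param sampled_values Per-voxel factors of the sampled subset.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_compare <- function(full_values, sampled_values) {
  kt <- suppressWarnings(stats::ks.test(sampled_values, full_values))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Sampling-fidelity report across ratios
#'
#' For one reflection, computes the per-voxel factor distribution at full
#' sampling once, then the KS statistic and p-value of each sampling
#' ratio/seed combination against it — the diagnostic used to justify a
#' default sampling ratio.
#'
#' @inheritParams run_standard
#' @param reflection A one-row reflection table (columns `ix..dz`).
#' @param ratios Numeric vector of sampling ratios in (0, 1].
#' @param seeds Integer vector of seeds (ignored for `systematic`, which is
#'   deterministic and reported once per ratio with its offset = 0).
#' @param method Sampling strategy used for the sampled subsets.
#' @return A `sample_report` tibble: `ratio`, `seed`, `n_selected`,
#'   `statistic`, `p_value`.
#' @export
sample_report <- function(volume, coeffs, reflection,
                          ratios = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                          seeds = 1:20,
                          method = c("randomized_systematic", "systematic",
                                     "random", "stratified")) {
  method <- match.arg(method)
  refl <- reflections_matrix(reflection)
  if (nrow(refl) != 1L) stop("reflection must be a single row")
  cl <- crystal_voxels(volume)
  full <- voxel_factors_cpp(volume$labels, mu_by_code(volume, coeffs),
                            cbind(cl$z, cl$y, cl$x), refl[1, ],
                            volume$voxel_size_um, FALSE)
  if (method == "systematic") seeds <- seeds[1]
  grid <- expand.grid(ratio = ratios, seed = seeds)
  rows <- purrr::pmap(grid, function(ratio, seed) {
    plan <- switch(method,
      systematic = systematic_sample(cl, ratio),
      randomized_systematic = randomized_systematic_sample(cl, ratio, seed),
      random = random_sample(cl, ratio, seed),
      stratified = stratified_sample(volume, ratio, seed)
    )
    ks <- ks_compare(full, full[plan$positions + 1L])
    tibble::tibble(ratio = ratio, seed = as.integer(seed),
                   n_selected = length(plan$positions),
                   statistic = ks$statistic, p_value = ks$p_value)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "method") <- method
  class(out) <- c("sample_report", class(out))
  out
}
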