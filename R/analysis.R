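# Perception readouts and modulation statistics --------------------------------

#' Reconstruct an image from averaged network responses
#'
#' Brightness-perception readout: each pixel is rebuilt from the learned
#' feedforward weights and averaged firing rates,
#' `I_rec(x) = sum_kn zbar_k w_kn xbar_n a_n f_n(x)`, where
#' `a_n = sum_x' I(x') f_n(x')` is the afferent DoG response to the stimulus
#' (not rectified), `zbar_k` the mean second-layer excitatory rate and
#' `xbar_n` the mean afferent rate over testing timesteps and simulations.
#'
#' @param image a `stimulus_image` (or pixel matrix).
#' @param W learned K x N feedforward weights.
#' @param mean_rates_z length-K average excitatory spike rates.
#' @param mean_rates_x length-N average afferent spike rates.
#' @param population the afferent population.
#' @param filter_matrix optional precomputed [dog_filter_matrix()].
#' @return a `reconstruction`: list with `values` (pixel matrix) and the
#'   per-neuron coefficients.
#' @export
reconstruct <- function(image, W, mean_rates_z, mean_rates_x, population,
                        filter_matrix = NULL) {
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  if (is.null(filter_matrix)) filter_matrix <- dog_filter_matrix(population)
  N <- nrow(filter_matrix)
  if (ncol(W) != N || length(mean_rates_x) != N)
    stop_param("dimension mismatch between W, rates and population")
  if (nrow(W) != length(mean_rates_z))
    stop_param("mean_rates_z length must equal nrow(W)")
  a <- as.vector(filter_matrix %*% as.vector(px))
  coef <- as.vector(crossprod(W, mean_rates_z)) * mean_rates_x * a
  vals <- matrix(as.vector(crossprod(filter_matrix, coef)),
                 nrow(px), ncol(px))
  structure(list(values = vals, coef = coef, a = a), class = "reconstruction")
}

#' Pooled normalization of a set of reconstructions
#'
#' All pixel values of all reconstructions in the set are pooled; the pooled
#' mean and standard deviation z-score every grid, so compared images share
#' one scale.
#'
#' @param reconstructions list of `reconstruction`s or matrices (>= 2).
#' @return list of matrices of normalized values.
#' @export
normalize_set <- function(reconstructions) {
  if (length(reconstructions) < 2) stop_param("need at least 2 reconstructions")
  mats <- lapply(reconstructions, function(r)
    if (inherits(r, "reconstruction")) r$values else as.matrix(r))
  pooled <- unlist(mats)
  mu <- mean(pooled)
  sd0 <- stats::sd(pooled)
  if (!is.finite(sd0) || sd0 == 0)
    stop_param("degenerate input: pooled standard deviation is zero")
  lapply(mats, function(m) (m - mu) / sd0)
}

#' Mean normalized brightness over the target region
#'
#' @param normalized a normalized reconstruction matrix.
#' @param img the stimulus the reconstruction belongs to.
#' @return scalar mean over target-region pixels.
#' @export
target_region_mean <- function(normalized, img) {
  ix <- rect_index(img$target_region)
  mean(normalized[ix$rows, ix$cols])
}

#' Contextual modulation index
#'
#' `CMI_k = (r_k1 - r_k2) / (r_k1 + r_k2)` on per-neuron spike counts under
#' two conditions; bounded in \[-1, 1\]. Neurons with `r_k1 + r_k2 = 0` are
#' undefined (0/0) and returned as `NA` with an exclusion flag.
#'
#' @param counts_1,counts_2 nonnegative integer spike counts per neuron.
#' @return list with `cmi` (NA where excluded), `excluded` (logical), and
#'   `n_excluded`.
#' @export
cmi <- function(counts_1, counts_2) {
  if (length(counts_1) != length(counts_2)) stop_param("length mismatch")
  if (any(counts_1 < 0) || any(counts_2 < 0))
    stop_param("counts must be nonnegative")
  tot <- counts_1 + counts_2
  excluded <- tot == 0
  v <- ifelse(excluded, NA_real_, (counts_1 - counts_2) / tot)
  list(cmi = v, excluded = excluded, n_excluded = sum(excluded))
}

zero_lag_corr <- function(raster) {
  # Pearson correlation of spike trains at lag 0; pairs involving a constant
  # train are defined as 0 (correlation undefined otherwise).
  C <- suppressWarnings(stats::cor(t(raster)))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' Cross-correlation difference between two conditions
#'
#' Per simulation and condition, the zero-lag Pearson correlation of every
#' pair of excitatory spike trains; pairs with a constant train contribute 0
#' for that simulation. Correlation matrices are averaged over simulations per
#' condition; the result is condition A minus condition B (antisymmetric under
#' swapping conditions).
#'
#' @param raster_pairs_condA,raster_pairs_condB lists of K x T rasters, one
#'   per simulation; rasters must have equal length.
#' @return K x K difference matrix.
#' @export
xcorr_diff <- function(raster_pairs_condA, raster_pairs_condB) {
  Ta <- unique(vapply(raster_pairs_condA, ncol, 1L))
  Tb <- unique(vapply(raster_pairs_condB, ncol, 1L))
  if (length(Ta) != 1 || length(Tb) != 1 || Ta != Tb)
    stop_param("rasters must all have the same length")
  avg <- function(lst) Reduce(`+`, lapply(lst, zero_lag_corr)) / length(lst)
  A <- avg(raster_pairs_condA)
  B <- avg(raster_pairs_condB)
  A - B
}

#' Averaged firing-rate map
#'
#' Mean spike indicator per (neuron, timestep) over simulations, with rows
#' (neurons) re-ordered by total responding strength, strongest first.
#'
#' @param rasters list of K x T rasters, one per simulation.
#' @return list with `map` (sorted K x T matrix) and `order` (original neuron
#'   indices in sorted position).
#' @export
rate_map <- function(rasters) {
  if (length(rasters) < 1) stop_param("need at least one raster")
  m <- Reduce(`+`, rasters) / length(rasters)
  ord <- order(rowSums(m), decreasing = TRUE)
  list(map = m[ord, , drop = FALSE], order = ord)
}
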