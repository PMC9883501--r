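# First-layer afferent encoding ----------------------------------------------
#
# Afferent neurons sit on a regular grid over the image and carry isotropic
# Difference-of-Gaussians (DoG) receptive fields
#   f_n(x) = exp(-|x - x_n|^2 / sigma_c^2) - phi * exp(-|x - x_n|^2 / sigma_s^2).
# A stimulus drives per-neuron Bernoulli spike probabilities (at most one
# spike per 1-ms timestep) proportional to the rectified, max-normalized
# filter response. Spikes are low-pass filtered into synaptic traces with a
# positive double-exponential kernel eps(d) = exp(-d/tau_f) - exp(-d/tau_r).

#' Difference-of-Gaussians receptive field
#'
#' @param center length-2 numeric, field center in pixel coordinates.
#' @param sigma_c center Gaussian radius (px), > 0.
#' @param sigma_s surround Gaussian radius (px), > `sigma_c`.
#' @param ratio surround weight phi >= 0.
#' @return a `receptive_field` list.
#' @export
receptive_field <- function(center, sigma_c, sigma_s, ratio = 0.9) {
  if (!is.numeric(center) || length(center) != 2L || any(!is.finite(center)))
    stop_param("center must be two finite coordinates")
  check_number(sigma_c, "sigma_c", .Machine$double.eps, Inf)
  check_number(sigma_s, "sigma_s", .Machine$double.eps, Inf)
  if (sigma_s <= sigma_c) stop_param("sigma_s must exceed sigma_c")
  check_number(ratio, "ratio", 0, Inf)
  structure(list(center = as.numeric(center), sigma_c = sigma_c,
                 sigma_s = sigma_s, ratio = ratio),
            class = "receptive_field")
}

#' Evaluate a DoG filter at a point
#'
#' @param point length-2 numeric coordinates (or an n x 2 matrix of points).
#' @param field a [receptive_field()].
#' @return filter value(s) `g_c(point) - ratio * g_s(point)`.
#' @export
dog_filter_value <- function(point, field) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 2L)
  if (any(!is.finite(point))) stop_param("point coordinates must be finite")
  d2 <- (point[, 1] - field$center[1])^2 + (point[, 2] - field$center[2])^2
  exp(-d2 / field$sigma_c^2) - field$ratio * exp(-d2 / field$sigma_s^2)
}

#' Default receptive-field parameter sampler
#'
#' Draws `sigma_c ~ Uniform(1.5, 3)` px, sets `sigma_s = 2 * sigma_c` and a
#' fixed surround ratio. Uses the current RNG stream.
#'
#' With peak-1 Gaussians the surround integral exceeds the center integral by
#' the factor `ratio * surround_factor^2`, so the filter only keeps a net
#' excitatory response to uniform luminance when
#' `ratio <= 1 / surround_factor^2` (0.25 here). The default 0.2 is slightly
#' center-dominant: contrast edges still dominate the code, but uniform
#' regions keep a weak luminance-proportional response and each edge field's
#' net contribution to nearby surfaces stays positive — at the exact balance
#' point that contribution is zero and surface readouts lose their sign (see
#' the methods vignette).
#'
#' @param sigma_c_range range for the center radius.
#' @param surround_factor `sigma_s / sigma_c`.
#' @param ratio surround weight phi.
#' @return a function `f(n)` returning a data.frame with columns `sigma_c`,
#'   `sigma_s`, `ratio`.
#' @export
default_rf_sampler <- function(sigma_c_range = c(1.5, 3), surround_factor = 2,
                               ratio = 0.2) {
  force(sigma_c_range); force(surround_factor); force(ratio)
  function(n) {
    sc <- runif(n, sigma_c_range[1], sigma_c_range[2])
    data.frame(sigma_c = sc, sigma_s = surround_factor * sc, ratio = ratio)
  }
}

#' Build the afferent population grid
#'
#' Places one receptive field per grid point, with `spacing` px between
#' centers; parameters are drawn once from `rf_param_sampler` under `seed`
#' and then fixed. A 60x60 image with 2-px spacing yields 900 neurons.
#'
#' Pixel (i, j) (1-based) has center coordinate (i - 0.5, j - 0.5); the grid
#' center of block g along an axis is at (g - 0.5) * spacing.
#'
#' @param image_size image side length (px); must be divisible by `spacing`.
#' @param spacing grid spacing (px).
#' @param rf_param_sampler see [default_rf_sampler()].
#' @param seed integer seed fixing the sampled parameters.
#' @return an `afferent_population`: list with `fields` data.frame
#'   (`cx`, `cy`, `sigma_c`, `sigma_s`, `ratio`), `spacing`, `image_size`.
#' @export
build_grid <- function(image_size, spacing = 2,
                       rf_param_sampler = default_rf_sampler(), seed = 1L) {
  check_number(image_size, "image_size", 1, Inf)
  check_number(spacing, "spacing", 1, image_size)
  if (image_size %% spacing != 0)
    stop_param("spacing must divide image_size")
  g <- image_size %/% spacing
  centers <- (seq_len(g) - 0.5) * spacing
  grid <- expand.grid(cx = centers, cy = centers)  # row index fast, N = g^2
  n <- nrow(grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pars <- rf_param_sampler(n)
  stopifnot(all(pars$sigma_s > pars$sigma_c), all(pars$sigma_c > 0))
  structure(list(fields = cbind(grid, pars), spacing = spacing,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "afferent_population")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.afferent_population <- function(x, ...) {
  cat(sprintf("<afferent_population> %d DoG fields, %dx%d image, spacing %g px\n",
              nrow(x$fields), x$image_size, x$image_size, x$spacing))
  invisible(x)
}

#' Filter matrix of a population over all image pixels
#'
#' @param population an [build_grid()] population.
#' @return N x P matrix; column p is the DoG response of every neuron at pixel
#'   p, pixels in column-major matrix order.
#' @export
dog_filter_matrix <- function(population) {
  sz <- population$image_size
  f <- population$fields
  px <- seq_len(sz) - 0.5
  # pixel p = (row r, col c) column-major; coordinates (x1, x2) = (r, c) centers
  pr <- rep(px, times = sz)
  pc <- rep(px, each = sz)
  d2 <- outer(f$cx, pr, function(a, b) (b - a)^2) +
    outer(f$cy, pc, function(a, b) (b - a)^2)
  exp(-d2 / f$sigma_c^2) - f$ratio * exp(-d2 / f$sigma_s^2)
}

#' Stimulus-driven afferent firing probabilities
#'
#' Computes the DoG response `a_n = sum_x I(x) f_n(x)`, rectifies it, and
#' scales by `rate_max / max(rectified a)`; all-zero if every `a_n <= 0`.
#'
#' @param population an afferent population.
#' @param image a `stimulus_image` or numeric matrix matching the grid extent.
#' @param rate_max maximal per-timestep spike probability, in (0, 1].
#' @param filter_matrix optional precomputed [dog_filter_matrix()].
#' @return list with `rates` (length N), raw responses `a`, and `rate_max`.
#' @export
stimulus_rates <- function(population, image, rate_max = 0.05,
                           filter_matrix = NULL) {
  if (!(is.numeric(rate_max) && length(rate_max) == 1L &&
        rate_max > 0 && rate_max <= 1))
    stop_param("rate_max must be a per-timestep probability in (0, 1]")
  px <- if (inherits(image, "stimulus_image")) image$pixels else image
  if (!all(dim(px) == population$image_size))
    stop_param("image dimensions do not match the population grid extent")
  if (is.null(filter_matrix)) filter_matrix <- dog_filter_matrix(population)
  a <- as.vector(filter_matrix %*% as.vector(px))
  pos <- pmax(a, 0)
  m <- max(pos)
  rates <- if (m > 0) rate_max * pos / m else rep(0, length(a))
  list(rates = rates, a = a, rate_max = rate_max)
}

#' Encode a set of stimuli with divisive (semisaturation) normalization
#'
#' The experiment-level encoder: canonical contrast normalization with a
#' semisaturation constant. Each image's rectified DoG profile is divided by
#' its own total drive plus a semisaturation term,
#' `q_n = rect(a_n) / (c50 + sum_n rect(a_n))` with
#' `c50 = c50_frac * mean total over the set`, and one gain common to the
#' whole set scales the largest entry to `rate_max`. A stronger context
#' (lighter, bigger, or more fully visible distractors; a brighter
#' background) therefore dilutes the rates of every other afferent in that
#' image — including the target's — while the image's total drive still
#' grows (sublinearly) with its total contrast energy, so different stimuli
#' remain separable by the population activity they evoke.
#'
#' @param population an afferent population.
#' @param images list of `stimulus_image`s (or matrices).
#' @param rate_max maximal per-timestep spike probability.
#' @param c50_frac semisaturation constant as a fraction of the set's mean
#'   total rectified response.
#' @param drive_total mean total afferent spikes per timestep over the set
#'   (the population spike budget anchoring the circuit's operating point).
#' @param filter_matrix optional precomputed [dog_filter_matrix()].
#' @return list with `rates` (list of per-image rate vectors), `a` (list of
#'   raw responses), the shared `gain` and `c50`.
#' @export
encode_stimulus_set <- function(population, images, rate_max = 0.12,
                                c50_frac = 0.5, drive_total = 3,
                                filter_matrix = NULL) {
  if (is.null(filter_matrix)) filter_matrix <- dog_filter_matrix(population)
  enc <- lapply(images, function(im)
    stimulus_rates(population, im, rate_max, filter_matrix))
  pos <- lapply(enc, function(e) pmax(e$a, 0))
  totals <- vapply(pos, sum, numeric(1))
  c50 <- c50_frac * mean(totals)
  q <- Map(function(p, tot) if (c50 + tot > 0) p / (c50 + tot) else p,
           pos, totals)
  qbar <- mean(vapply(q, sum, numeric(1)))
  gain <- if (qbar > 0) drive_total / qbar else 0
  list(rates = lapply(q, function(v) pmin(rate_max, v * gain)),
       a = lapply(enc, `[[`, "a"), gain = gain, c50 = c50)
}

#' Generate afferent Poisson (Bernoulli) spikes
#'
#' Independent Bernoulli(`rates[n]`) per neuron and timestep; at most one
#' spike per timestep.
#'
#' @param rates per-neuron spike probabilities in \[0, 1\].
#' @param T number of timesteps (>= 1).
#' @param seed optional integer seed (uses current stream when `NULL`).
#' @return integer N x T spike matrix.
#' @export
generate_afferent_spikes <- function(rates, T, seed = NULL) {
  check_number(T, "T", 1, Inf)
  stopifnot(all(rates >= 0), all(rates <= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(rates)
  # column-by-column so draw order matches the simulation engine
  out <- matrix(0L, n, T)
  for (t in seq_len(T)) out[, t] <- as.integer(runif(n) < rates)
  out
}

# Synaptic traces -------------------------------------------------------------

#' Double-exponential synaptic kernel
#'
#' `eps(d) = exp(-d / tau_f) - exp(-d / tau_r)` for `d >= 0`, else 0; with the
#' defaults `tau_r = 1`, `tau_f = 10` timesteps the kernel is nonnegative,
#' zero at `d = 0`, and peaks at `tau_r tau_f log(tau_f / tau_r) /
#' (tau_f - tau_r)` (about 2.558 timesteps).
#'
#' @param d lag in timesteps (vectorized).
#' @param tau_r,tau_f rise and fall time constants, `tau_f > tau_r > 0`.
#' @return kernel values.
#' @export
trace_kernel <- function(d, tau_r = 1, tau_f = 10) {
  if (tau_f <= tau_r || tau_r <= 0) stop_param("need tau_f > tau_r > 0")
  ifelse(d >= 0, exp(-d / tau_f) - exp(-d / tau_r), 0)
}

#' Synaptic trace at a timestep from a spike history (kernel sum)
#'
#' Explicit evaluation of `sum_g eps(t - t_g)` per neuron; the simulation
#' engine uses the equivalent two-exponential recursion (see
#' [trace_recursive()]).
#'
#' @param raster_history N x T spike matrix (columns = timesteps 1..T).
#' @param t timestep at which to evaluate (within 1..T).
#' @param tau_r,tau_f kernel time constants.
#' @return length-N trace vector.
#' @export
update_traces <- function(raster_history, t, tau_r = 1, tau_f = 10) {
  if (t < 1 || t > ncol(raster_history)) stop_param("t outside history")
  k <- trace_kernel(t - seq_len(t), tau_r, tau_f)
  as.vector(raster_history[, seq_len(t), drop = FALSE] %*% k)
}

#' Recursive trace computation
#'
#' State-space form of [update_traces()]: two exponential accumulators per
#' neuron, `F_t = d_f (F_(t-1) + s_(t-1))`, trace `= F - R`. Matches the
#' explicit kernel sum to numerical precision.
#'
#' @inheritParams update_traces
#' @return N x T matrix of traces at every timestep (trace at t uses spikes up
#'   to and including t; the kernel is zero at lag 0, so this equals the
#'   trace driven by spikes strictly before t plus nothing).
#' @export
trace_recursive <- function(raster_history, tau_r = 1, tau_f = 10) {
  if (tau_f <= tau_r || tau_r <= 0) stop_param("need tau_f > tau_r > 0")
  df <- exp(-1 / tau_f); dr <- exp(-1 / tau_r)
  n <- nrow(raster_history); T <- ncol(raster_history)
  out <- matrix(0, n, T)
  Fv <- Rv <- rep(0, n)
  for (t in seq_len(T)) {
    out[, t] <- Fv - Rv
    s <- raster_history[, t]
    Fv <- (Fv + s) * df
    Rv <- (Rv + s) * dr
  }
  out
}
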