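#' @useDynLib wtabright, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
NULL

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_param(name, " must be in [", lower, ", ", upper, "]")
  invisible(x)
}

logistic <- function(u) 1 / (1 + exp(-u))

# empirical quantile, type 1 (inverse ECDF): the ceil(q*n)-th order statistic.
# Shared convention between the R identification functions and the C++ engine.
quantile_type1 <- function(x, q) {
  n <- length(x)
  idx <- min(max(1L, as.integer(ceiling(q * n))), n)
  sort(x)[idx]
}

# Deterministic per-component seed streams below 2^31, derived from one
# master seed so stimuli, wiring, warm-up, learning and testing can be
# varied independently.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((abs(master) + stream * 1000003) %% 2147483587) + 1L
}
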