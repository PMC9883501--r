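# Reward-gated plasticity -----------------------------------------------------
#
# Weight updates follow the gradient of a discounted log-likelihood over all
# sub-sequence lengths, realized online as per-synapse eligibility traces
#   E_W[k, n] <- gamma * E_W[k, n] + z_tk * (x~_tn - h(w_kn)),
# with the weight-dependent penalty h(w) = 1 - 1/w + 1/(exp(w) - 1) (the mean
# of the exponentially tilted uniform emission density on [0, 1], so the
# update is the exact gradient of that emission log-likelihood). A reward
# r_t = 1 converts the eligibility into a weight change; r_t = 0 leaves all
# weights untouched.

#' Learning configuration
#'
#' @param gamma discount factor in (0, 1); default 0.9.
#' @param eta learning-rate step; default 0.001, chosen so the plastic
#'   weights keep their graded structure over a learning protocol (see the
#'   methods vignette).
#' @param clip_eps clipping margin keeping weights strictly inside (0, 1).
#' @return a `learning_config` list.
#' @export
learning_config <- function(gamma = 0.9, eta = 0.001, clip_eps = 1e-6) {
  if (!(gamma > 0 && gamma < 1)) stop_param("gamma must be in (0, 1)")
  if (!(eta > 0)) stop_param("eta must be positive")
  if (!(clip_eps > 0 && clip_eps < 0.5)) stop_param("clip_eps must be in (0, 0.5)")
  structure(list(gamma = gamma, eta = eta, clip_eps = clip_eps),
            class = "learning_config")
}

#' Discounted sub-sequence weight
#'
#' The contribution of a T-step sub-sequence to the reward,
#' `alpha(T) = (1 - gamma) * gamma^(T - 1)`; sums to 1 over T >= 1.
#'
#' @param T sub-sequence length (>= 1).
#' @param gamma discount factor in (0, 1).
#' @return `alpha(T)`.
#' @export
subsequence_weight <- function(T, gamma = 0.9) {
  if (any(T < 1)) stop_param("T must be >= 1")
  if (!(gamma > 0 && gamma < 1)) stop_param("gamma must be in (0, 1)")
  (1 - gamma) * gamma^(T - 1)
}

#' Weight penalty term of the update direction
#'
#' `h(w) = 1 - 1/w + 1/(exp(w) - 1)`, monotone increasing on (0, 1). The two
#' apparent poles cancel (the Laurent expansion of `1/(exp(w) - 1)` is
#' `1/w - 1/2 + w/12 - ...`), so `h(w) = 1/2 + w/12 + O(w^2)`: the penalty is
#' confined to the narrow band (0.5, 0.582).
#'
#' @param w weight(s) strictly inside (0, 1).
#' @return `h(w)`.
#' @export
weight_penalty <- function(w) {
  if (any(w <= 0) || any(w >= 1)) stop_param("w must be strictly inside (0, 1)")
  # expm1 avoids catastrophic cancellation for weights near the clip floor
  1 - 1 / w + 1 / expm1(w)
}

#' Initialize eligibility accumulators
#'
#' @param K,N second-layer excitatory and afferent counts.
#' @return list with zero matrices `E_W` (K x N) and `E_V` (K x K).
#' @export
eligibility_init <- function(K, N) {
  list(E_W = matrix(0, K, N), E_V = matrix(0, K, K))
}

#' Accumulate eligibility for one timestep
#'
#' Recursive form of the discounted gradient sums: decay both accumulators by
#' `gamma`, then add `z_t (x~_t - h(W))` rowwise for the feedforward matrix
#' and `z_t (z~_t - h(V))` for the lateral one (diagonal kept at zero).
#'
#' @param elig an [eligibility_init()] list.
#' @param spikes_z_t binary length-K excitatory spike vector at t.
#' @param traces_x_t,traces_z_t afferent and lateral trace vectors at t.
#' @param W,V current plastic weights.
#' @param gamma discount factor.
#' @return the updated eligibility list.
#' @export
accumulate_eligibility <- function(elig, spikes_z_t, traces_x_t, traces_z_t,
                                   W, V, gamma = 0.9) {
  E_W <- gamma * elig$E_W
  E_V <- gamma * elig$E_V
  active <- which(spikes_z_t != 0)
  for (k in active) {
    E_W[k, ] <- E_W[k, ] + (traces_x_t - weight_penalty(W[k, ]))
    hv <- numeric(ncol(V))
    off <- setdiff(seq_len(ncol(V)), k)
    hv[off] <- weight_penalty(V[k, off])
    ev <- traces_z_t - hv
    ev[k] <- 0
    E_V[k, ] <- E_V[k, ] + ev
  }
  list(E_W = E_W, E_V = E_V)
}

#' Apply a reward-gated weight update
#'
#' With `r_t = 0` the weights are returned unchanged (bitwise); with
#' `r_t = 1`, `W <- clip(W + eta * E_W, clip_eps, 1 - clip_eps)` and likewise
#' for `V`, whose diagonal stays 0.
#'
#' @param W,V plastic weight matrices.
#' @param elig eligibility list.
#' @param r_t reward in {0, 1}.
#' @param eta learning rate.
#' @param clip_eps clipping margin.
#' @return list with updated `W` and `V`.
#' @export
apply_update <- function(W, V, elig, r_t, eta = 0.01, clip_eps = 1e-6) {
  if (!r_t %in% c(0, 1)) stop_param("r_t must be 0 or 1")
  if (r_t == 0) return(list(W = W, V = V))
  W <- pmin(pmax(W + eta * elig$E_W, clip_eps), 1 - clip_eps)
  V <- pmin(pmax(V + eta * elig$E_V, clip_eps), 1 - clip_eps)
  diag(V) <- 0
  list(W = W, V = V)
}
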