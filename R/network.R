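# Second-layer circuit --------------------------------------------------------
#
# K excitatory and J inhibitory neurons. Excitatory membrane potential
#   u_k = sum_n w_kn x~_n + sum_k' v_kk' z~_k' - v_EI sum_{j in J_k} y~_j + b_k
# drives a per-timestep Bernoulli spike with probability logistic(u_k)
# (exponential dependence on the potential, normalized over {0, 1}), followed
# by an absolute refractory period. Inhibitory neurons are rate-based:
# rho_j = rectify(v_IE sum_{k in phi_j} z~_k - v_II sum_{j' in sigma_j} y~_j')
# generates Poisson spikes, discretized to probability 1 - exp(-rho) per
# timestep with at most one spike.

#' Network configuration
#'
#' @param K,J,N excitatory / inhibitory / afferent neuron counts
#'   (paper-scale defaults 100 / 50 / 900).
#' @param p_EI,p_IE,p_II connection probabilities for the inhibitory-to-
#'   excitatory, excitatory-to-inhibitory and inhibitory-to-inhibitory masks
#'   (defaults 0.6 / 0.575 / 0.55).
#' @param v_EI,v_IE,v_II fixed inhibitory-pathway weights. `v_IE` and `v_II`
#'   default to 0.5 (the mean of the (0, 1) plastic-weight range); `v_EI`
#'   defaults to 4, calibrated so that feedback inhibition — whose firing is
#'   refractory-capped at 0.25/timestep — can actually balance the
#'   feedforward and recurrent excitation and enforce sparse competition
#'   (see the methods vignette).
#' @param tau_r,tau_f synaptic trace time constants in timesteps (1 / 10).
#' @param refrac_E,refrac_I absolute refractory lengths in timesteps (5 / 3).
#' @param rate_max maximal afferent spike probability per timestep.
#' @param w_init,v_init ranges of the uniform initial distributions of the
#'   plastic feedforward and lateral weights. `w_init` defaults to
#'   (0.001, 1); `v_init` defaults to (0.001, 0.1): at a dense lateral-weight
#'   initialization the recurrent excitation (which scales with K) immovably
#'   exceeds the refractory-capped inhibition (which cannot), so the circuit
#'   locks into an all-active state before any competition can form; starting
#'   the lateral weights low lets winner assemblies emerge first (see the
#'   methods vignette).
#' @return a `network_config` list.
#' @export
network_config <- function(K = 100, J = 50, N = 900,
                           p_EI = 0.6, p_IE = 0.575, p_II = 0.55,
                           v_EI = 4, v_IE = 0.5, v_II = 0.5,
                           tau_r = 1, tau_f = 10,
                           refrac_E = 5, refrac_I = 3, rate_max = 0.12,
                           w_init = c(0.001, 1), v_init = c(0.001, 0.1)) {
  for (p in c(p_EI = p_EI, p_IE = p_IE, p_II = p_II))
    check_number(p, "connection probability", 0, 1)
  for (v in c(v_EI = v_EI, v_IE = v_IE, v_II = v_II))
    check_number(v, "fixed weight", 0, Inf)
  check_number(refrac_E, "refrac_E", 0, Inf)
  check_number(refrac_I, "refrac_I", 0, Inf)
  if (tau_f <= tau_r || tau_r <= 0) stop_param("need tau_f > tau_r > 0")
  structure(list(K = as.integer(K), J = as.integer(J), N = as.integer(N),
                 p_EI = p_EI, p_IE = p_IE, p_II = p_II,
                 v_EI = v_EI, v_IE = v_IE, v_II = v_II,
                 tau_r = tau_r, tau_f = tau_f,
                 refrac_E = as.integer(refrac_E),
                 refrac_I = as.integer(refrac_I),
                 rate_max = rate_max,
                 w_init = w_init, v_init = v_init),
            class = "network_config")
}

#' Sample connectivity masks and excitabilities
#'
#' Independent Bernoulli masks: `M_IE` (K x J, inhibitory j -> excitatory k,
#' probability `p_EI`), `M_EI` (J x K, excitatory -> inhibitory, `p_IE`),
#' `M_II` (J x J, inhibitory -> inhibitory, `p_II`, no self-connection).
#' Excitabilities `b_k ~ Uniform(0, 1)`. Masks and `b` are fixed for the
#' lifetime of a network.
#'
#' @param config a [network_config()].
#' @param seed optional integer seed.
#' @return list with `M_IE`, `M_EI`, `M_II` (integer 0/1 matrices) and `b`.
#' @export
sample_connectivity <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- config$K; J <- config$J
  M_IE <- matrix(as.integer(runif(K * J) < config$p_EI), K, J)
  M_EI <- matrix(as.integer(runif(J * K) < config$p_IE), J, K)
  M_II <- matrix(as.integer(runif(J * J) < config$p_II), J, J)
  diag(M_II) <- 0L
  b <- runif(K)
  list(M_IE = M_IE, M_EI = M_EI, M_II = M_II, b = b)
}

#' Initialize a network state
#'
#' Plastic weights `W` (K x N) and `V` (K x K, zero diagonal) are drawn
#' independently from uniform distributions over the configured init ranges;
#' masks and excitabilities from [sample_connectivity()].
#'
#' @param config a [network_config()].
#' @param seed optional integer seed.
#' @return a `wta_network`: config, weights, masks, excitabilities.
#' @export
init_network <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conn <- sample_connectivity(config)
  W <- matrix(runif(config$K * config$N, config$w_init[1], config$w_init[2]),
              config$K, config$N)
  V <- matrix(runif(config$K * config$K, config$v_init[1], config$v_init[2]),
              config$K, config$K)
  diag(V) <- 0
  structure(c(list(config = config, W = W, V = V), conn),
            class = "wta_network")
}

#' @export
print.wta_network <- function(x, ...) {
  cat(sprintf("<wta_network> K=%d excitatory, J=%d inhibitory, N=%d afferent\n",
              x$config$K, x$config$J, x$config$N))
  invisible(x)
}

#' Excitatory membrane potential
#'
#' @param state a `wta_network`.
#' @param k excitatory neuron index.
#' @param traces list with `x` (afferent), `z` (lateral excitatory), `y`
#'   (inhibitory) trace vectors at the current timestep.
#' @return the scalar potential `u_k`.
#' @export
excitatory_potential <- function(state, k, traces) {
  if (k < 1 || k > state$config$K) stop_param("neuron index out of range")
  sum(state$W[k, ] * traces$x) + sum(state$V[k, ] * traces$z) -
    state$config$v_EI * sum(state$M_IE[k, ] * traces$y) + state$b[k]
}

#' Sample an excitatory spike
#'
#' Spike probability is the logistic of the membrane potential; a refractory
#' neuron returns 0 without consuming a random draw.
#'
#' @param u membrane potential.
#' @param refractory logical; is the neuron inside its refractory period?
#' @return 0 or 1.
#' @export
excitatory_spike <- function(u, refractory = FALSE) {
  if (!is.finite(u)) stop_param("potential must be finite")
  if (refractory) return(0L)
  as.integer(runif(1) < 1 / (1 + exp(-u)))
}

#' Inhibitory instantaneous firing rate
#'
#' @param state a `wta_network`.
#' @param j inhibitory neuron index.
#' @param traces list with `z` and `y` trace vectors.
#' @return the rectified rate `rho_j >= 0`.
#' @export
inhibitory_rate <- function(state, j, traces) {
  if (j < 1 || j > state$config$J) stop_param("neuron index out of range")
  u <- state$config$v_IE * sum(state$M_EI[j, ] * traces$z) -
    state$config$v_II * sum(state$M_II[j, ] * traces$y)
  max(u, 0)
}

#' Sample an inhibitory spike
#'
#' Poisson discretization: spike probability `1 - exp(-rho)` per timestep,
#' capped at one spike; refractory neurons return 0 without sampling.
#'
#' @param rho instantaneous rate (>= 0).
#' @param refractory logical.
#' @return 0 or 1.
#' @export
inhibitory_spike <- function(rho, refractory = FALSE) {
  if (refractory) return(0L)
  as.integer(runif(1) < 1 - exp(-rho))
}
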