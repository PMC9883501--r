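# Trial simulation ------------------------------------------------------------

#' Simulate one stimulus presentation
#'
#' Runs the second-layer circuit for `T` timesteps driven by afferent
#' Bernoulli spikes at the given rates, with optional identification and
#' reward-gated plasticity. Uses the compiled engine; `run_trial_r()` is the
#' pure-R reference that reproduces it draw for draw.
#'
#' @param net a [init_network()] state.
#' @param rates length-N afferent spike probabilities (see [stimulus_rates()]).
#' @param clusters list of S [clustering_set()]s (or K x m matrices); required
#'   when `mode` is `"learn"` or `"test"`.
#' @param label presented stimulus index in 1..S.
#' @param T presentation length in timesteps.
#' @param mode `"warmup"` (no identification, no learning), `"learn"`
#'   (identification + reward-gated updates) or `"test"` (identification with
#'   all parameters frozen).
#' @param learning a [learning_config()].
#' @param ident an [ident_config()].
#' @param collect_x return the full afferent raster as well.
#' @param reward_override testing hook: force every reward to 0 or 1
#'   (default `-1`, no override).
#' @return list with updated `W`, `V`, `clusters` (member matrices), spike
#'   rasters `z` (K x T), `y` (J x T), `x_count` (length N), per-timestep
#'   `rewards` (-1 when no identification ran), `actions`, and membership
#'   probabilities `p` (S x T).
#' @export
run_trial <- function(net, rates, clusters = list(), label = 1L, T = 100L,
                      mode = c("learn", "test", "warmup"),
                      learning = learning_config(), ident = ident_config(),
                      collect_x = FALSE, reward_override = -1L) {
  mode <- match.arg(mode)
  cfg <- net$config
  if (length(rates) != cfg$N) stop_param("rates length must equal N")
  cl_mats <- lapply(clusters, cluster_members)
  opts <- list(v_EI = cfg$v_EI, v_IE = cfg$v_IE, v_II = cfg$v_II,
               tau_r = cfg$tau_r, tau_f = cfg$tau_f,
               refrac_E = cfg$refrac_E, refrac_I = cfg$refrac_I,
               gamma = learning$gamma, eta = learning$eta,
               clip_eps = learning$clip_eps,
               alpha_sig = ident$alpha_sig, R = ident$R,
               n_cluster = ident$n_cluster,
               do_ident = mode != "warmup", do_learn = mode == "learn",
               collect_x = collect_x,
               reward_override = as.integer(reward_override))
  .run_trial_engine(net$W, net$V, net$M_IE, net$M_EI, net$M_II, net$b,
                    as.numeric(rates), cl_mats, as.integer(label),
                    as.integer(T), opts)
}

#' @rdname run_trial
#' @details `run_trial_r()` exists as an independent reference path: it is
#'   composed from the exported single-operation functions and consumes the
#'   RNG stream in exactly the same order as the compiled engine, so both
#'   produce bitwise-identical trajectories from the same seed. It is
#'   practical only at small scale.
#' @export
run_trial_r <- function(net, rates, clusters = list(), label = 1L, T = 100L,
                        mode = c("learn", "test", "warmup"),
                        learning = learning_config(), ident = ident_config(),
                        collect_x = FALSE, reward_override = -1L) {
  mode <- match.arg(mode)
  cfg <- net$config
  do_ident <- mode != "warmup"
  do_learn <- mode == "learn"
  K <- cfg$K; N <- cfg$N; J <- cfg$J
  W <- net$W; V <- net$V
  cl_mats <- lapply(clusters, cluster_members)
  S <- length(cl_mats)
  if (do_ident && (S == 0 || any(vapply(cl_mats, ncol, 1L) < 2)))
    stop_param("all clustering sets must have >= 2 members before identification")

  df <- exp(-1 / cfg$tau_f); drr <- exp(-1 / cfg$tau_r)
  xf <- xr <- rep(0, N); zf <- zr <- rep(0, K); yf <- yr <- rep(0, J)
  x_prev <- rep(0L, N); z_prev <- rep(0L, K); y_prev <- rep(0L, J)
  rc_e <- rep(0L, K); rc_i <- rep(0L, J)
  elig <- eligibility_init(K, N)

  zras <- matrix(0L, K, T); yras <- matrix(0L, J, T)
  xras <- if (collect_x) matrix(0L, N, T) else NULL
  x_count <- rep(0, N)
  rewards <- rep(-1L, T); actions <- rep(0L, T)
  pmat <- matrix(0, max(S, 1L), T)

  for (t in seq_len(T)) {
    xf <- (xf + x_prev) * df; xr <- (xr + x_prev) * drr; xt <- xf - xr
    zf <- (zf + z_prev) * df; zr <- (zr + z_prev) * drr; zt <- zf - zr
    yf <- (yf + y_prev) * df; yr <- (yr + y_prev) * drr; yt <- yf - yr

    xspk <- as.integer(runif(N) < rates)
    traces <- list(x = xt, z = zt, y = yt)

    # same grouping as the engine: feedforward drive via %*% (BLAS dgemm),
    # lateral and inhibitory terms as plain sums
    ffw <- as.vector(W %*% xt)
    u <- vapply(seq_len(K), function(k)
      (ffw[k] + sum(V[k, ] * zt)) - cfg$v_EI * sum(net$M_IE[k, ] * yt) + net$b[k],
      numeric(1))
    zspk <- integer(K)
    for (k in seq_len(K)) {
      if (rc_e[k] > 0L) { rc_e[k] <- rc_e[k] - 1L }
      else {
        zspk[k] <- excitatory_spike(u[k])
        if (zspk[k] == 1L) rc_e[k] <- cfg$refrac_E
      }
    }

    rho <- vapply(seq_len(J), function(j) inhibitory_rate(net, j, traces), numeric(1))
    yspk <- integer(J)
    for (j in seq_len(J)) {
      if (rc_i[j] > 0L) { rc_i[j] <- rc_i[j] - 1L }
      else {
        yspk[j] <- inhibitory_spike(rho[j])
        if (yspk[j] == 1L) rc_i[j] <- cfg$refrac_I
      }
    }

    r_t <- -1L; a_t <- 0L
    if (do_ident) {
      mp <- membership_probability(as.numeric(zspk), cl_mats,
                                   alpha_sig = ident$alpha_sig, R = ident$R)
      pmat[, t] <- mp$p
      a_t <- sample_action(mp$p)
      r_t <- as.integer(a_t == label)
      if (reward_override >= 0) r_t <- as.integer(reward_override)
    }

    if (do_learn) {
      elig <- accumulate_eligibility(elig, zspk, xt, zt, W, V, learning$gamma)
      if (r_t == 1L) {
        upd <- apply_update(W, V, elig, 1, learning$eta, learning$clip_eps)
        W <- upd$W; V <- upd$V
        if (sum(zspk) > 0L) {  # empty response vectors are not collected
          members <- cbind(cl_mats[[label]], as.numeric(zspk))
          while (ncol(members) > ident$n_cluster)
            members <- members[, -1, drop = FALSE]
          cl_mats[[label]] <- members
        }
      }
    }

    zras[, t] <- zspk; yras[, t] <- yspk
    x_count <- x_count + xspk
    if (collect_x) xras[, t] <- xspk
    rewards[t] <- r_t; actions[t] <- a_t
    x_prev <- xspk; z_prev <- zspk; y_prev <- yspk
  }

  out <- list(W = W, V = V, clusters = cl_mats, z = zras, y = yras,
              x_count = x_count, rewards = rewards, actions = actions,
              p = if (do_ident) pmat else matrix(0, 0, 0))
  if (collect_x) out$x <- xras
  out
}

# lightweight view of the network with updated plastic weights
net0_with <- function(net, W, V) {
  net$W <- W; net$V <- V
  net
}
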