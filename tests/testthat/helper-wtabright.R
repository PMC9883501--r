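# Shared fixtures, all built in code.

tiny_config <- function(K = 5, J = 3, N = 16, ...) {
  network_config(K = K, J = J, N = N, rate_max = 0.3, ...)
}

tiny_net <- function(seed = 11, ...) {
  init_network(tiny_config(...), seed = seed)
}

# deterministic binary cluster members (K x m)
binary_members <- function(K, m, seed, p = 0.4) {
  set.seed(seed)
  matrix(as.numeric(runif(K * m) < p), K, m)
}

rand_raster <- function(n, T, rate, seed) {
  set.seed(seed)
  matrix(as.integer(runif(n * T) < rate), n, T)
}

# brute-force energy distance of a point to a set of column vectors
bf_energy <- function(z, members) {
  m <- ncol(members)
  s1 <- 0
  for (i in seq_len(m)) s1 <- s1 + sqrt(sum((z - members[, i])^2))
  s2 <- 0
  for (i in seq_len(m)) for (j in seq_len(m))
    s2 <- s2 + sqrt(sum((members[, i] - members[, j])^2))
  (2 / m) * s1 - s2 / m^2
}

# desk-scale experiment shrunk for unit tests
micro_experiment_spec <- function(name = "sbc", seed = 1, n_learn = 3,
                                  n_test = 2, T = 30, K = 8, J = 4) {
  experiment_spec(build_stimulus_set(name), n_learn = n_learn, n_test = n_test,
                  T_per_stimulus = T, network = network_config(K = K, J = J),
                  seed = seed, T_warm = 25L)
}
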