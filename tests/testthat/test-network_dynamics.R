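test_that("connectivity sampling matches the Bernoulli densities", {
  cfg <- network_config(K = 100, J = 50, N = 10, p_EI = 1)
  expect_true(all(sample_connectivity(cfg, seed = 1)$M_IE == 1L))
  cfg2 <- network_config(K = 100, J = 50, N = 10)
  conn <- sample_connectivity(cfg2, seed = 2)
  se <- sqrt(0.6 * 0.4 / (100 * 50))
  expect_lt(abs(mean(conn$M_IE) - 0.6), 3 * se)
  expect_true(all(diag(conn$M_II) == 0L))
  expect_true(all(conn$b > 0 & conn$b < 1))
  expect_identical(conn, sample_connectivity(cfg2, seed = 2))
  expect_error(network_config(p_EI = 1.2), "probability")
})

test_that("initial weights fall in the configured ranges, V diagonal zero", {
  net <- init_network(network_config(K = 20, J = 10, N = 50), seed = 4)
  expect_true(all(net$W >= 0.001 & net$W <= 1))
  expect_true(all(diag(net$V) == 0))
  offdiag <- net$V[row(net$V) != col(net$V)]
  expect_true(all(offdiag >= 0.001 & offdiag <= 0.1))
})

test_that("excitatory potential is the stated linear combination", {
  net <- tiny_net()
  net$W[] <- 0; net$V[] <- 0; net$M_IE[] <- 0L
  net$W[2, 3] <- 0.5
  net$b[2] <- 0.1
  traces <- list(x = rep(0, 16), z = rep(0, 5), y = rep(0, 3))
  expect_equal(excitatory_potential(net, 2, traces), 0.1)
  traces$x[3] <- 0.6
  expect_equal(excitatory_potential(net, 2, traces), 0.5 * 0.6 + 0.1)
  # one inhibitory trace through the mask lowers u by exactly v_EI
  net$M_IE[2, 1] <- 1L
  traces$y[1] <- 1
  expect_equal(excitatory_potential(net, 2, traces),
               0.5 * 0.6 - net$config$v_EI + 0.1)
  expect_error(excitatory_potential(net, 99, traces), "out of range")
})

test_that("excitatory spiking is logistic in the potential", {
  set.seed(1)
  expect_lt(abs(mean(replicate(4000, excitatory_spike(0))) - 0.5),
            3 * sqrt(0.25 / 4000))
  expect_equal(excitatory_spike(-50), 0L)  # logistic(-50) ~ 2e-22
  expect_equal(excitatory_spike(10, refractory = TRUE), 0L)
  expect_error(excitatory_spike(NaN), "finite")
  # u = ln 3 -> p = 0.75
  set.seed(2)
  phat <- mean(replicate(10000, excitatory_spike(log(3))))
  expect_lt(abs(phat - 0.75), 3 * sqrt(0.75 * 0.25 / 10000))
  # a refractory neuron does not consume randomness
  set.seed(3); r1 <- runif(1)
  set.seed(3); expect_equal(excitatory_spike(2, refractory = TRUE), 0L)
  expect_identical(runif(1), r1)
})

test_that("inhibitory rates rectify and discretize as 1 - exp(-rho)", {
  net <- tiny_net()
  net$M_EI[] <- 0L; net$M_II[] <- 0L
  traces <- list(z = rep(0, 5), y = rep(0, 3))
  expect_equal(inhibitory_rate(net, 1, traces), 0)
  net$M_EI[1, c(2, 4)] <- 1L
  traces$z[c(2, 4)] <- 1
  expect_equal(inhibitory_rate(net, 1, traces), net$config$v_IE * 2)
  net$M_II[1, 2] <- 1L
  traces$y[2] <- 100  # drives u below zero -> rectified
  expect_equal(inhibitory_rate(net, 1, traces), 0)
  set.seed(4)
  phat <- mean(replicate(8000, inhibitory_spike(1)))
  p <- 1 - exp(-1)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 8000))
})

test_that("trials are deterministic given the seed and near-silent when clamped", {
  net <- tiny_net()
  rates <- seq(0.01, 0.2, length.out = 16)
  set.seed(5); a <- run_trial(net, rates, mode = "warmup", T = 80)
  set.seed(5); b <- run_trial(net, rates, mode = "warmup", T = 80)
  expect_identical(a$z, b$z); expect_identical(a$y, b$y)
  # clamped config: zero weights and b = -10 silence the network
  mute <- net
  mute$W[] <- 0; mute$V[] <- 0; mute$b[] <- -10
  set.seed(6)
  res <- run_trial(mute, rates, mode = "warmup", T = 300)
  expect_equal(sum(res$z), 0)
})

test_that("forced inhibition strictly lowers excitatory spiking (paired)", {
  cfg <- tiny_config(K = 10, J = 5, N = 16, v_EI = 5)
  net <- init_network(cfg, seed = 7)
  net$M_IE[] <- 1L
  rates <- rep(0.15, 16)
  set.seed(8)
  base <- run_trial(net, rates, mode = "warmup", T = 400)
  # drive inhibitory neurons hard via full E->I connectivity and high v_IE
  hot <- net; hot$config$v_IE <- 10; hot$M_EI[] <- 1L
  set.seed(8)
  inhibited <- run_trial(hot, rates, mode = "warmup", T = 400)
  expect_lt(sum(inhibited$z), sum(base$z))
})

test_that("refractory invariant holds on simulated rasters", {
  net <- init_network(tiny_config(K = 12, J = 6, N = 16), seed = 9)
  net$b[] <- 2  # high firing pressure
  set.seed(10)
  res <- run_trial(net, rep(0.2, 16), mode = "warmup", T = 500)
  gaps_ok <- function(raster, refrac) {
    all(apply(raster, 1, function(row) {
      s <- which(row == 1L)
      length(s) < 2 || min(diff(s)) > refrac
    }))
  }
  expect_true(gaps_ok(res$z, net$config$refrac_E))
  expect_true(gaps_ok(res$y, net$config$refrac_I))
})

test_that("compiled engine and R reference produce bitwise-identical trials", {
  cfg <- tiny_config()
  net <- init_network(cfg, seed = 11)
  set.seed(12)
  rates <- runif(16, 0, 0.3)
  cl <- list(clustering_set(binary_members(5, 4, 1), 1, 6),
             clustering_set(binary_members(5, 4, 2), 2, 6))
  lc <- learning_config(eta = 0.05)
  ic <- ident_config(S = 2, n_cluster = 6)
  for (mode in c("learn", "test", "warmup")) {
    set.seed(123)
    a <- run_trial(net, rates, cl, label = 1, T = 40, mode = mode,
                   learning = lc, ident = ic, collect_x = TRUE)
    set.seed(123)
    b <- run_trial_r(net, rates, cl, label = 1, T = 40, mode = mode,
                     learning = lc, ident = ic, collect_x = TRUE)
    expect_identical(a$z, b$z)
    expect_identical(a$y, b$y)
    expect_identical(a$x, b$x)
    expect_identical(a$rewards, b$rewards)
    expect_identical(a$actions, b$actions)
    expect_identical(a$W, b$W)
    expect_identical(a$V, b$V)
    expect_identical(lapply(a$clusters, unname), lapply(b$clusters, unname))
  }
})
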