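test_that("sub-sequence weights are the discounted geometric series", {
  expect_equal(subsequence_weight(1, 0.9), 0.1, tolerance = 1e-12)
  expect_equal(sum(subsequence_weight(1:2000, 0.9)), 1, tolerance = 1e-12)
  expect_equal(subsequence_weight(1, 1e-9), 1, tolerance = 1e-8)
  expect_error(subsequence_weight(0), ">= 1")
  expect_error(subsequence_weight(1, 1.1), "gamma")
})

test_that("weight penalty matches the closed form and stays in its band", {
  expect_equal(weight_penalty(0.5), 1 - 2 + 1 / (exp(0.5) - 1), tolerance = 1e-12)
  expect_equal(weight_penalty(0.5), 0.5414941, tolerance = 1e-6)
  w <- seq(1e-6, 1 - 1e-6, length.out = 2000)
  h <- weight_penalty(w)
  expect_true(all(diff(h) > 0))          # monotone increasing
  # the 1/w poles cancel: h -> 1/2 as w -> 0+, bounded above by h(1) < 0.582
  expect_equal(weight_penalty(1e-8), 0.5, tolerance = 1e-6)
  expect_true(all(h > 0.5 - 1e-9 & h < 0.582))
  expect_error(weight_penalty(0), "inside")
  expect_error(weight_penalty(1), "inside")
})

test_that("recursive eligibility equals the explicit discounted sum", {
  gamma <- 0.9
  set.seed(21)
  K <- 3; N <- 4; T <- 200
  W <- matrix(runif(K * N, 0.2, 0.8), K, N)
  V <- matrix(runif(K * K, 0.2, 0.8), K, K); diag(V) <- 0
  z <- rand_raster(K, T, 0.15, 22)
  xt <- matrix(runif(N * T), N, T)
  zt <- matrix(runif(K * T), K, T)
  elig <- eligibility_init(K, N)
  for (t in seq_len(T))
    elig <- accumulate_eligibility(elig, z[, t], xt[, t], zt[, t], W, V, gamma)
  # explicit sum: E[k, n] = sum_t' gamma^(T - t') z[k, t'] (x[n, t'] - h(w_kn))
  E_W <- matrix(0, K, N)
  for (k in 1:K) for (n in 1:N)
    E_W[k, n] <- sum(gamma^(T - 1:T) * z[k, ] * (xt[n, ] - weight_penalty(W[k, n])))
  expect_lt(max(abs(elig$E_W - E_W)), 1e-10)
  E_V <- matrix(0, K, K)
  for (k in 1:K) for (k2 in 1:K) if (k != k2)
    E_V[k, k2] <- sum(gamma^(T - 1:T) * z[k, ] * (zt[k2, ] - weight_penalty(V[k, k2])))
  expect_lt(max(abs(elig$E_V - E_V)), 1e-10)
  expect_true(all(diag(elig$E_V) == 0))
  # single spike at t', queried at T: gamma^(T - t') (x - h(w))
  e1 <- eligibility_init(1, 1)
  for (t in 1:10)
    e1 <- accumulate_eligibility(e1, as.integer(t == 4), 0.7, 0, matrix(0.3), matrix(0), gamma)
  expect_equal(e1$E_W[1, 1], gamma^6 * (0.7 - weight_penalty(0.3)), tolerance = 1e-12)
  # no spikes ever -> zero
  e0 <- eligibility_init(2, 3)
  for (t in 1:20) e0 <- accumulate_eligibility(e0, c(0, 0), runif(3), runif(2),
                                               matrix(0.5, 2, 3), matrix(0.5, 2, 2), gamma)
  expect_true(all(e0$E_W == 0) && all(e0$E_V == 0))
})

test_that("analytic update direction matches finite differences of the likelihood", {
  # emission model whose log-likelihood gradient is z (x~ - h(w)):
  # p(x~_n | z_k = 1) proportional to exp(w_kn x~_n) on [0, 1], with
  # log-partition log((exp(w) - 1) / w), so d/dw log p = x~ - h(w).
  gamma <- 0.9
  K <- 2; N <- 4; T <- 60
  set.seed(31)
  W <- matrix(runif(K * N, 0.2, 0.8), K, N)
  z <- rand_raster(K, T, 0.2, 32)
  xt <- matrix(runif(N * T), N, T)
  loglik <- function(Wm) {
    tot <- 0
    for (tt in seq_len(T)) {
      lp <- sum(vapply(1:K, function(k) {
        if (z[k, tt] == 0) return(0)
        sum(Wm[k, ] * xt[, tt] - log((exp(Wm[k, ]) - 1) / Wm[k, ]))
      }, numeric(1)))
      tot <- tot + gamma^(T - tt) * lp
    }
    tot
  }
  elig <- eligibility_init(K, N)
  for (tt in seq_len(T))
    elig <- accumulate_eligibility(elig, z[, tt], xt[, tt], rep(0, K), W,
                                   matrix(0.5, K, K), gamma)
  eps <- 1e-5
  for (k in 1:K) for (n in 1:N) {
    Wp <- W; Wp[k, n] <- W[k, n] + eps
    Wm <- W; Wm[k, n] <- W[k, n] - eps
    fd <- (loglik(Wp) - loglik(Wm)) / (2 * eps)
    expect_equal(elig$E_W[k, n], fd, tolerance = 1e-4)
  }
})

test_that("updates are reward-gated, sign-correct and clipped", {
  set.seed(41)
  W <- matrix(runif(6, 0.3, 0.7), 2, 3)
  V <- matrix(runif(4, 0.3, 0.7), 2, 2); diag(V) <- 0
  elig <- list(E_W = matrix(rnorm(6), 2, 3), E_V = matrix(rnorm(4), 2, 2))
  elig$E_V[cbind(1:2, 1:2)] <- 0
  # r = 0: bitwise identity
  upd0 <- apply_update(W, V, elig, 0, eta = 0.1)
  expect_identical(upd0$W, W); expect_identical(upd0$V, V)
  # zero eligibility: identity up to clipping (weights already inside)
  upd1 <- apply_update(W, V, eligibility_init(2, 3), 1, eta = 0.1)
  expect_equal(upd1$W, W)
  # small step moves each weight in the sign of its eligibility
  upd2 <- apply_update(W, V, elig, 1, eta = 1e-4)
  expect_true(all(sign(upd2$W - W) == sign(elig$E_W)))
  expect_true(all(diag(upd2$V) == 0))
  expect_error(apply_update(W, V, elig, 0.5), "0 or 1")
  # clipping invariant after many aggressive updates
  for (i in 1:200) {
    upd <- apply_update(W, V, list(E_W = matrix(rnorm(6, sd = 5), 2, 3),
                                   E_V = matrix(rnorm(4, sd = 5), 2, 2)),
                        1, eta = 1, clip_eps = 1e-6)
    W <- upd$W; V <- upd$V
    expect_true(all(W > 0 & W < 1))
    offd <- V[row(V) != col(V)]
    expect_true(all(offd > 0 & offd < 1) && all(diag(V) == 0))
  }
})

test_that("with reward forced to zero the whole learning phase is a no-op", {
  net <- tiny_net()
  set.seed(51)
  rates <- runif(16, 0, 0.25)
  cl <- list(clustering_set(binary_members(5, 4, 1), 1),
             clustering_set(binary_members(5, 4, 2), 2))
  set.seed(52)
  res <- run_trial(net, rates, cl, label = 1, T = 120, mode = "learn",
                   ident = ident_config(S = 2), reward_override = 0L)
  expect_identical(res$W, net$W)
  expect_identical(res$V, net$V)
  expect_true(all(res$rewards == 0L))
  expect_identical(lapply(res$clusters, unname),
                   lapply(cl, function(c) unname(c$members)))
})
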