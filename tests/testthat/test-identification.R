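test_that("energy distance matches brute force and its degenerate cases", {
  z <- c(1, 0)
  cl <- matrix(c(0, 0, 1, 1), 2, 2)
  # (2/2)(1+1) - (1/4)(2 sqrt 2) = 2 - sqrt(2)/2
  expect_equal(energy_distance(z, cl), 2 - sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(energy_distance(z, cl), 1.2928932, tolerance = 1e-6)
  expect_equal(energy_distance(z, cl), bf_energy(z, cl), tolerance = 1e-12)
  # zero iff all members equal z
  expect_equal(energy_distance(z, cbind(z, z, z)), 0)
  expect_equal(energy_distance(c(0, 0), cbind(c(0, 0), c(0, 0))), 0)
  expect_error(energy_distance(z, matrix(numeric(0), 2, 0)), "empty")
  # invariant to member order, brute-force agreement on random cases
  for (seed in 1:5) {
    m <- binary_members(6, 8, seed)
    zz <- binary_members(6, 1, seed + 100)[, 1]
    expect_equal(energy_distance(zz, m), bf_energy(zz, m), tolerance = 1e-10)
    perm <- m[, sample(8)]
    expect_equal(energy_distance(zz, perm), energy_distance(zz, m),
                 tolerance = 1e-12)
    expect_gte(energy_distance(zz, m), 0)
  }
})

test_that("acceptance threshold equals an independent brute-force recomputation", {
  m <- binary_members(6, 4, 7)
  # independent brute force with the same draw convention
  bf_threshold <- function(members, alpha, R) {
    mm <- ncol(members)
    loo <- vapply(seq_len(mm), function(i)
      bf_energy(members[, i], members[, -i, drop = FALSE]), numeric(1))
    idx <- 1L + floor(runif(R) * mm)
    sort(loo[idx])[ceiling((1 - alpha) * R)]
  }
  set.seed(77); got <- acceptance_threshold(m, 0.05, R = 50)
  set.seed(77); want <- bf_threshold(m, 0.05, 50)
  expect_equal(got, want, tolerance = 1e-12)
  # identical members -> threshold 0
  same <- cbind(c(1, 0, 1), c(1, 0, 1), c(1, 0, 1))
  expect_equal(acceptance_threshold(same, 0.05, R = 20, seed = 1), 0)
  # alpha -> 1 gives the minimum of the resampled distances
  set.seed(5)
  thr_min <- acceptance_threshold(m, 1 - 1e-12, R = 50)
  loo_all <- vapply(1:4, function(i) bf_energy(m[, i], m[, -i]), numeric(1))
  expect_equal(thr_min, min(loo_all[1L + floor({set.seed(5); runif(50)} * 4)]),
               tolerance = 1e-12)
  expect_error(acceptance_threshold(m[, 1, drop = FALSE]), ">= 2")
})

test_that("membership probabilities use the common threshold and match brute force", {
  K <- 6
  near <- cbind(c(1, 1, 0, 0, 0, 0), c(1, 1, 0, 0, 0, 0))
  far <- cbind(rep(1, K), c(1, 1, 1, 1, 1, 0))
  z <- near[, 1]
  mp <- membership_probability(z, list(near, far), seed = 3)
  expect_equal(mp$p[1], 1)
  expect_equal(mp$p[2], 0)
  # brute-force recomputation, same seed and draw order
  bf_membership <- function(z, clusters, alpha, R) {
    thr <- vapply(clusters, function(members) {
      mm <- ncol(members)
      loo <- vapply(seq_len(mm), function(i)
        bf_energy(members[, i], members[, -i, drop = FALSE]), numeric(1))
      idx <- 1L + floor(runif(R) * mm)
      sort(loo[idx])[ceiling((1 - alpha) * R)]
    }, numeric(1))
    e_acc <- min(thr)
    p <- vapply(clusters, function(members) {
      mm <- ncol(members)
      hits <- 0L
      for (r in seq_len(R)) {
        idx <- 1L + floor(runif(mm) * mm)
        if (bf_energy(z, members[, idx, drop = FALSE]) <= e_acc)
          hits <- hits + 1L
      }
      hits / R
    }, numeric(1))
    list(p = p, e_accept = e_acc)
  }
  cl <- list(binary_members(6, 5, 11), binary_members(6, 5, 12))
  zz <- binary_members(6, 1, 13)[, 1]
  set.seed(21); got <- membership_probability(zz, cl, 0.05, R = 50)
  set.seed(21); want <- bf_membership(zz, cl, 0.05, 50)
  expect_equal(got$e_accept, want$e_accept, tolerance = 1e-12)
  expect_equal(got$p, want$p)
  expect_true(all(got$p >= 0 & got$p <= 1))
  # symmetric clusters equidistant from z get equal p up to resampling noise
  sym <- list(cbind(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 1)),
              cbind(c(0, 1, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 1)))
  set.seed(9)
  ps <- rowMeans(replicate(40, membership_probability(rep(0, 6), sym, R = 50)$p))
  expect_lt(abs(ps[1] - ps[2]), 0.1)
  expect_error(membership_probability(zz, list(cl[[1]], cl[[2]][, 1, drop = FALSE])),
               "seeded")
})

test_that("action sampling is the softmax of the membership probabilities", {
  # equal p -> uniform actions
  set.seed(31)
  acts <- replicate(6000, sample_action(c(0.4, 0.4, 0.4)))
  for (s in 1:3)
    expect_lt(abs(mean(acts == s) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 6000))
  # S = 2, p = (1, 0): P(a = 1) = e/(1 + e)
  p1 <- exp(1) / (1 + exp(1))
  expect_equal(p1, 0.7310586, tolerance = 1e-6)
  set.seed(32)
  a2 <- replicate(8000, sample_action(c(1, 0)))
  expect_lt(abs(mean(a2 == 1) - p1), 3 * sqrt(p1 * (1 - p1) / 8000))
  expect_equal(sum(wtabright:::softmax(c(0.2, 0.9, 0.5))), 1, tolerance = 1e-12)
  expect_error(sample_action(c(-0.1, 0.5)), ">= 0")
})

test_that("reward emission and FIFO updates follow the contract", {
  cl <- list(clustering_set(binary_members(4, 3, 1), 1, capacity = 20),
             clustering_set(binary_members(4, 3, 2), 2, capacity = 20))
  z <- c(1, 0, 1, 0)
  wrong <- reward_and_update(2, 1, z, cl)
  expect_equal(wrong$r_t, 0L)
  expect_identical(wrong$clusters, cl)
  right <- reward_and_update(1, 1, z, cl)
  expect_equal(right$r_t, 1L)
  expect_equal(ncol(right$clusters[[1]]$members), 4)
  expect_equal(right$clusters[[1]]$members[, 4], z)
  # 25 consecutive correct updates: size capped at 20, members the most recent
  cur <- cl
  appended <- list()
  for (i in 1:25) {
    zi <- as.numeric(1:4 == (i %% 4 + 1))
    appended[[i]] <- zi
    cur <- reward_and_update(1, 1, zi, cur)$clusters
  }
  expect_equal(ncol(cur[[1]]$members), 20)
  recent <- do.call(cbind, appended[6:25])  # 3 seeds evicted first, then 2 more
  expect_equal(unname(cur[[1]]$members), recent)
  expect_error(reward_and_update(5, 1, z, cl), "invalid label")
})

test_that("cluster sizes never exceed capacity during simulated learning", {
  net <- tiny_net()
  set.seed(61)
  rates <- runif(16, 0.05, 0.3)
  ic <- ident_config(S = 2, n_cluster = 6)
  cl <- list(clustering_set(binary_members(5, 5, 1), 1, 6),
             clustering_set(binary_members(5, 5, 2), 2, 6))
  set.seed(62)
  res <- run_trial(net, rates, cl, label = 1, T = 300, mode = "learn",
                   ident = ic, reward_override = 1L)
  for (m in res$clusters) expect_lte(ncol(m), 6)
  expect_equal(ncol(res$clusters[[1]]), 6)  # filled to capacity
})
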