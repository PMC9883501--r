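# Unsupervised identification -------------------------------------------------
#
# Each stimulus owns a FIFO clustering set of previously accepted second-layer
# excitatory response vectors. A new response vector z is compared to each set
# by the energy distance
#   e(z, c) = (2/m) sum_i ||z - c_i||  -  (1/m^2) sum_ij ||c_i - c_j||.
# Per-cluster acceptance thresholds come from R leave-one-out resamples (the
# (1 - alpha) empirical quantile of held-out member distances); the common
# threshold is the minimum over clusters. Membership probabilities are the
# fraction of R bootstrap resamples of each cluster whose energy distance to z
# stays below the common threshold, and the action is a categorical sample
# from the softmax of those probabilities. A correct action yields reward 1
# and appends z to the matching cluster (FIFO-evicting beyond capacity).

#' Identification configuration
#'
#' @param alpha_sig significance level alpha in (0, 1); default 0.05.
#' @param R resample count (>= 1); default 50.
#' @param S number of stimuli.
#' @param n_seed warm-up seeding size per cluster (>= 2 so thresholds exist).
#' @param n_cluster FIFO capacity; default 20.
#' @return an `ident_config` list.
#' @export
ident_config <- function(alpha_sig = 0.05, R = 50, S = 2, n_seed = 5,
                         n_cluster = 20) {
  if (!(alpha_sig > 0 && alpha_sig < 1)) stop_param("alpha_sig must be in (0, 1)")
  if (R < 1) stop_param("R must be >= 1")
  if (n_seed < 2) stop_param("n_seed must be >= 2")
  structure(list(alpha_sig = alpha_sig, R = as.integer(R), S = as.integer(S),
                 n_seed = as.integer(n_seed), n_cluster = as.integer(n_cluster)),
            class = "ident_config")
}

#' FIFO clustering set
#'
#' @param members K x m matrix of binary response vectors, oldest column first.
#' @param label stimulus index the set belongs to.
#' @param capacity maximal size `n_cluster`.
#' @return a `clustering_set`.
#' @export
clustering_set <- function(members, label = 1L, capacity = 20L) {
  members <- as.matrix(members)
  if (ncol(members) > capacity) stop_param("more members than capacity")
  if (length(members) && !all(members %in% c(0, 1)))
    stop_param("members must be binary vectors")
  structure(list(members = members, label = as.integer(label),
                 capacity = as.integer(capacity)),
            class = "clustering_set")
}

#' @export
print.clustering_set <- function(x, ...) {
  cat(sprintf("<clustering_set> label=%d size=%d/%d (K=%d)\n", x$label,
              ncol(x$members), x$capacity, nrow(x$members)))
  invisible(x)
}

cluster_members <- function(cluster) {
  if (inherits(cluster, "clustering_set")) cluster$members else as.matrix(cluster)
}

# Euclidean distances from z to each column of members. Accumulation grouping
# (sum over a plain vector / column-major matrix) is mirrored bit-for-bit by
# the C++ engine, which matters only for the engine-equivalence test.
dist_to_members <- function(z, members) {
  sqrt(colSums((members - z)^2))
}

pairwise_dist <- function(members) {
  m <- ncol(members)
  D <- matrix(0, m, m)
  if (m > 1) for (i in 1:(m - 1)) for (j in (i + 1):m) {
    d <- sqrt(sum((members[, i] - members[, j])^2))
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Energy distance between a response vector and a clustering set
#'
#' @param z binary length-K vector.
#' @param cluster a [clustering_set()] or K x m member matrix (non-empty).
#' @return nonnegative scalar; 0 iff every member equals `z`.
#' @export
energy_distance <- function(z, cluster) {
  members <- cluster_members(cluster)
  m <- ncol(members)
  if (m == 0) stop_param("empty clustering set: seed it first")
  dz <- dist_to_members(z, members)
  D <- pairwise_dist(members)
  (2 / m) * sum(dz) - (1 / m^2) * sum(D)
}

loo_distances <- function(D) {
  # energy distance of member i to the remaining members, for every i,
  # from the cached pairwise matrix: O(m) each via row sums.
  m <- nrow(D)
  rs <- vapply(seq_len(m), function(i) sum(D[i, ]), numeric(1))
  tot <- sum(rs)
  vapply(seq_len(m), function(i)
    (2 / (m - 1)) * rs[i] - (tot - 2 * rs[i]) / (m - 1)^2, numeric(1))
}

#' Acceptance threshold of a clustering set
#'
#' For each of `R` resamples, one member is held out uniformly at random and
#' its energy distance to the remainder computed; the threshold is the
#' `(1 - alpha_sig)` empirical quantile (type 1) of those distances.
#'
#' @param cluster a clustering set with at least 2 members.
#' @param alpha_sig significance level.
#' @param R resample count.
#' @param seed optional integer seed.
#' @return the scalar threshold `e_accept`.
#' @export
acceptance_threshold <- function(cluster, alpha_sig = 0.05, R = 50, seed = NULL) {
  members <- cluster_members(cluster)
  m <- ncol(members)
  if (m < 2) stop_param("cluster must have >= 2 members")
  if (!is.null(seed)) set.seed(seed)
  D <- pairwise_dist(members)
  loo <- loo_distances(D)
  idx <- 1L + as.integer(floor(runif(R) * m))
  quantile_type1(loo[idx], 1 - alpha_sig)
}

bootstrap_energy <- function(dz, D, idx) {
  m <- length(dz)
  s1 <- sum(dz[idx])
  s2 <- sum(D[idx, idx])
  (2 / m) * s1 - s2 / m^2
}

#' Membership probabilities of a response vector
#'
#' Uses the common threshold `min_s e_accept(alpha, c_s)`; `p_s` is the
#' fraction of `R` bootstrap resamples (with replacement) of cluster `s`
#' whose energy distance to `z` is at most the common threshold.
#'
#' @param z binary response vector.
#' @param clusters list of clustering sets, all with >= 2 members.
#' @param alpha_sig,R as in [acceptance_threshold()].
#' @param seed optional integer seed.
#' @return list with `p` (length-S probabilities) and `e_accept` (common
#'   threshold).
#' @export
membership_probability <- function(z, clusters, alpha_sig = 0.05, R = 50,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(clusters)
  mem <- lapply(clusters, cluster_members)
  if (any(vapply(mem, ncol, 1L) < 2)) stop_param("all clusters must be seeded")
  thr <- vapply(seq_len(S), function(s)
    acceptance_threshold(clusters[[s]], alpha_sig, R), numeric(1))
  e_accept <- min(thr)
  p <- numeric(S)
  for (s in seq_len(S)) {
    members <- mem[[s]]
    m <- ncol(members)
    dz <- dist_to_members(z, members)
    D <- pairwise_dist(members)
    hit <- 0L
    for (r in seq_len(R)) {
      idx <- 1L + as.integer(floor(runif(m) * m))
      if (bootstrap_energy(dz, D, idx) <= e_accept) hit <- hit + 1L
    }
    p[s] <- hit / R
  }
  list(p = p, e_accept = e_accept)
}

softmax <- function(p) {
  ex <- exp(p)
  ex / sum(ex)
}

#' Sample an identification action
#'
#' Categorical draw from the softmax of the membership probabilities.
#'
#' @param p_vector membership probabilities in \[0, 1\].
#' @param seed optional integer seed.
#' @return an integer action in 1..length(p_vector).
#' @export
sample_action <- function(p_vector, seed = NULL) {
  stopifnot(all(p_vector >= 0), all(p_vector <= 1))
  if (!is.null(seed)) set.seed(seed)
  ex <- exp(p_vector)
  cum <- cumsum(ex)
  u <- runif(1) * cum[length(cum)]
  which(cum >= u)[1]
}

#' Reward emission and FIFO cluster update
#'
#' Reward is 1 iff the action matches the true label; on reward the response
#' vector is appended to the end of the matching cluster, evicting from the
#' front while the size exceeds capacity. On zero reward the clusters are
#' returned unchanged.
#'
#' @param a_t sampled action.
#' @param true_label presented stimulus index.
#' @param z binary response vector.
#' @param clusters list of clustering sets.
#' @return list with `r_t` (0/1) and `clusters`.
#' @export
reward_and_update <- function(a_t, true_label, z, clusters) {
  if (a_t < 1 || a_t > length(clusters) || true_label < 1 ||
      true_label > length(clusters)) stop_param("invalid label")
  r_t <- as.integer(a_t == true_label)
  if (r_t == 1L) {
    cl <- clusters[[true_label]]
    members <- cbind(cl$members, as.numeric(z))
    while (ncol(members) > cl$capacity) members <- members[, -1, drop = FALSE]
    clusters[[true_label]] <- clustering_set(members, cl$label, cl$capacity)
  }
  list(r_t = r_t, clusters = clusters)
}
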