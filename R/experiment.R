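# Experiment orchestration -----------------------------------------------------
#
# Protocol: a warm-up pass seeds each stimulus's clustering set with a few
# labeled response vectors (no weight updates), then n_learn learning
# simulations present the stimuli in a freshly shuffled order and update
# weights and clustering sets at every rewarded timestep, and n_test testing
# simulations run with all parameters frozen. A master seed derives
# independent streams for receptive fields, wiring/initial weights, warm-up,
# learning and testing.

#' Experiment specification
#'
#' @param stimuli list of `stimulus_image`s (labels 1..S in order).
#' @param n_learn,n_test numbers of learning / testing simulations
#'   (paper scale: 200 / 100).
#' @param T_per_stimulus presentation length per image per simulation, in
#'   timesteps.
#' @param network a [network_config()].
#' @param learning a [learning_config()].
#' @param ident an [ident_config()]; its `S` is set from the stimuli.
#' @param seed master seed.
#' @param T_warm warm-up presentation length (timesteps).
#' @param rf_sampler receptive-field parameter sampler.
#' @param spacing afferent grid spacing in px.
#' @return an `experiment_spec`.
#' @export
experiment_spec <- function(stimuli, n_learn = 200, n_test = 100,
                            T_per_stimulus = 200,
                            network = network_config(),
                            learning = learning_config(),
                            ident = ident_config(),
                            seed = 1L, T_warm = 30L,
                            rf_sampler = default_rf_sampler(), spacing = 2) {
  if (n_learn < 1 || n_test < 1) stop_param("n_learn and n_test must be >= 1")
  if (T_per_stimulus < 1) stop_param("T_per_stimulus must be >= 1")
  sz <- nrow(stimuli[[1]]$pixels)
  ident$S <- length(stimuli)
  network$N <- as.integer((sz / spacing)^2)
  structure(list(stimuli = stimuli, n_learn = as.integer(n_learn),
                 n_test = as.integer(n_test),
                 T_per_stimulus = as.integer(T_per_stimulus),
                 network = network, learning = learning, ident = ident,
                 seed = as.integer(seed), T_warm = as.integer(T_warm),
                 rf_sampler = rf_sampler, spacing = spacing,
                 image_size = sz),
            class = "experiment_spec")
}

#' Scale profiles
#'
#' `"paper"`: K = 100, J = 50, 200 learning and 100 testing simulations,
#' 200 timesteps per presentation. `"desk"`: K = 30, J = 15, 50 / 30
#' simulations, 100 timesteps — a scaled-down profile for interactive use and
#' CI. Both keep the full 60x60 image and 900 afferents.
#'
#' @param profile `"paper"` or `"desk"`.
#' @return list of protocol sizes.
#' @export
profile_sizes <- function(profile = c("desk", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper")
    list(K = 100L, J = 50L, n_learn = 200L, n_test = 100L, T = 200L)
  else
    list(K = 30L, J = 15L, n_learn = 50L, n_test = 30L, T = 100L)
}

#' Built-in stimulus sets of the four experiments
#'
#' `"sbc"`: the uniform dark/light background pair. `"combined"`: the split
#' background pair. `"anchoring"`: dark background plus 0.8/0.9/1 lighter
#' backgrounds. `"distance"`, `"grayscale"`, `"size"`: the combined-background
#' pair (Sti. 1/2) plus two distractor stimuli (Sti. 3/4) — a centered target
#' straddling the split background, four boundary distractors aligned to the
#' target sides — varying, respectively, distance to the target (flush with the boundary vs
#' one 5-px step inward), distractor gray value (0.9 vs 1) and distractor
#' size (5 vs 10 px). The grayscale and size pairs sit one step inward, so
#' the distractors lie within the afferent surround reach of the target;
#' every modulation channel in this architecture is local.
#'
#' @param name experiment name.
#' @return list of `stimulus_image`s.
#' @export
build_stimulus_set <- function(name = c("sbc", "combined", "anchoring",
                                        "distance", "grayscale", "size")) {
  name <- match.arg(name)
  base <- make_combined_background_pair()
  dist_pair <- function(values, sizes, offsets) {
    list(make_distractor_image(distractor_value = values[1],
                               distractor_size = sizes[1],
                               distractor_offsets = offsets[1], label = 3L),
         make_distractor_image(distractor_value = values[2],
                               distractor_size = sizes[2],
                               distractor_offsets = offsets[2], label = 4L))
  }
  switch(name,
    sbc = make_sbc_pair(),
    combined = base,
    anchoring = make_anchoring_set(),
    distance = c(base, dist_pair(c(1, 1), c(10, 10), c(0, 5))),
    grayscale = c(base, dist_pair(c(0.9, 1), c(10, 10), c(5, 5))),
    size = c(base, dist_pair(c(1, 1), c(5, 10), c(5, 5))))
}

prepare_inputs <- function(spec) {
  pop <- build_grid(spec$image_size, spec$spacing, spec$rf_sampler,
                    seed = derive_seed(spec$seed, 1L))
  Fm <- dog_filter_matrix(pop)
  enc <- encode_stimulus_set(pop, spec$stimuli, spec$network$rate_max,
                             filter_matrix = Fm)
  list(population = pop, filter_matrix = Fm, rates = enc$rates, a = enc$a)
}

#' Run the learning phase
#'
#' Initializes plastic weights from Uniform(0.001, 1), seeds each clustering
#' set with `n_seed` labeled warm-up responses, then runs `n_learn`
#' simulations, each presenting all stimuli in a freshly shuffled random
#' order with identification, rewards and weight updates at every timestep.
#'
#' @param spec an [experiment_spec()].
#' @param inputs optional precomputed encodings (internal reuse).
#' @return list with the trained `net`, `clusters`, `population`,
#'   `filter_matrix`, per-stimulus afferent responses `a` and `rates`, and a
#'   per-simulation `log` of mean rewards.
#' @export
run_learning <- function(spec, inputs = NULL) {
  if (is.null(inputs)) inputs <- prepare_inputs(spec)
  S <- length(spec$stimuli)
  net <- init_network(spec$network, seed = derive_seed(spec$seed, 2L))

  # warm-up: labeled seeding of the clustering sets, no identification,
  # no plasticity; the last n_seed response vectors become the members
  set.seed(derive_seed(spec$seed, 3L))
  clusters <- vector("list", S)
  for (s in seq_len(S)) {
    Tw <- max(spec$T_warm, 4L * spec$ident$n_seed)
    res <- run_trial(net, inputs$rates[[s]], mode = "warmup", T = Tw,
                     learning = spec$learning, ident = spec$ident)
    # seed with the most recent non-empty response vectors (an empty vector
    # identifies nothing); fall back to the last columns if there are not
    # enough spiking timesteps
    nz <- which(colSums(res$z) > 0)
    keep <- if (length(nz) >= spec$ident$n_seed)
      utils::tail(nz, spec$ident$n_seed)
    else utils::tail(seq_len(Tw), spec$ident$n_seed)
    clusters[[s]] <- clustering_set(res$z[, keep, drop = FALSE] * 1.0,
                                    label = s, capacity = spec$ident$n_cluster)
  }
  cl_mats <- lapply(clusters, cluster_members)

  set.seed(derive_seed(spec$seed, 4L))
  log <- data.frame(simulation = seq_len(spec$n_learn), mean_reward = NA_real_)
  for (sim in seq_len(spec$n_learn)) {
    ord <- sample.int(S)
    rew <- 0; ntot <- 0
    for (s in ord) {
      res <- run_trial(net, inputs$rates[[s]], clusters = cl_mats,
                       label = s, T = spec$T_per_stimulus, mode = "learn",
                       learning = spec$learning, ident = spec$ident)
      net$W <- res$W; net$V <- res$V
      cl_mats <- res$clusters
      rew <- rew + sum(res$rewards)
      ntot <- ntot + length(res$rewards)
    }
    log$mean_reward[sim] <- rew / ntot
  }
  clusters <- lapply(seq_len(S), function(s)
    clustering_set(cl_mats[[s]], s, spec$ident$n_cluster))
  list(net = net, clusters = clusters, population = inputs$population,
       filter_matrix = inputs$filter_matrix, rates = inputs$rates,
       a = inputs$a, log = log)
}

#' Run the testing phase
#'
#' `n_test` simulations per stimulus with weights and clustering sets frozen;
#' identification still runs so testing reward rates are observable. The
#' function asserts that the trained parameters are bitwise unchanged.
#'
#' @param spec an [experiment_spec()].
#' @param trained the result of [run_learning()].
#' @return list with per-stimulus raster lists `z`, mean excitatory rates
#'   `z_bar`, mean afferent rates `x_bar`, spike counts, and reward rates.
#' @export
run_testing <- function(spec, trained) {
  S <- length(spec$stimuli)
  cl_mats <- lapply(trained$clusters, cluster_members)
  net <- trained$net
  set.seed(derive_seed(spec$seed, 5L))
  z <- lapply(seq_len(S), function(s) vector("list", spec$n_test))
  counts <- matrix(0, spec$network$K, S)
  x_tot <- matrix(0, spec$network$N, S)
  rew <- matrix(NA_real_, spec$n_test, S)
  for (sim in seq_len(spec$n_test)) {
    for (s in seq_len(S)) {
      res <- run_trial(net, trained$rates[[s]], clusters = cl_mats,
                       label = s, T = spec$T_per_stimulus, mode = "test",
                       learning = spec$learning, ident = spec$ident)
      if (!identical(res$W, net$W) || !identical(res$V, net$V) ||
          !identical(res$clusters, cl_mats))
        stop("invariant violation: parameters mutated during testing")
      z[[s]][[sim]] <- res$z
      counts[, s] <- counts[, s] + rowSums(res$z)
      x_tot[, s] <- x_tot[, s] + res$x_count
      rew[sim, s] <- mean(res$rewards)
    }
  }
  Ttot <- spec$n_test * spec$T_per_stimulus
  list(z = z, counts = counts,
       z_bar = counts / Ttot, x_bar = x_tot / Ttot,
       reward_rate = colMeans(rew), reward_by_sim = rew)
}

#' Run a full named experiment
#'
#' Builds the stimulus set, runs learning and testing, and computes the
#' analysis layer: pooled-normalized reconstructions with target-region means,
#' CMI histograms and cross-correlation differences against Sti. 1, rate maps,
#' and testing reward rates.
#'
#' @param name one of `"sbc"`, `"combined"`, `"anchoring"`, `"distance"`,
#'   `"grayscale"`, `"size"`.
#' @param profile `"desk"` or `"paper"` (see [profile_sizes()]).
#' @param seed master seed.
#' @param ... overrides for [experiment_spec()] fields (`n_learn`, `n_test`,
#'   `T_per_stimulus`, `network`, `learning`, `ident`, `T_warm`).
#' @return a `wta_experiment` object.
#' @export
run_experiment <- function(name, profile = "desk", seed = 1L, ...) {
  stimuli <- build_stimulus_set(name)
  sizes <- profile_sizes(profile)
  args <- list(...)
  network <- args$network %||% network_config(K = sizes$K, J = sizes$J)
  spec <- experiment_spec(
    stimuli,
    n_learn = args$n_learn %||% sizes$n_learn,
    n_test = args$n_test %||% sizes$n_test,
    T_per_stimulus = args$T_per_stimulus %||% sizes$T,
    network = network,
    learning = args$learning %||% learning_config(),
    ident = args$ident %||% ident_config(),
    seed = seed, T_warm = args$T_warm %||% 30L,
    rf_sampler = args$rf_sampler %||% default_rf_sampler(),
    spacing = args$spacing %||% 2)

  trained <- run_learning(spec)
  test <- run_testing(spec, trained)
  S <- length(stimuli)

  recs <- lapply(seq_len(S), function(s)
    reconstruct(stimuli[[s]], trained$net$W, test$z_bar[, s], test$x_bar[, s],
                trained$population, filter_matrix = trained$filter_matrix))
  normed <- normalize_set(recs)
  target_means <- vapply(seq_len(S), function(s)
    target_region_mean(normed[[s]], stimuli[[s]]), numeric(1))

  cmis <- if (S >= 2) lapply(2:S, function(s) cmi(test$counts[, 1], test$counts[, s]))
  xdiffs <- if (S >= 2) lapply(2:S, function(s) xcorr_diff(test$z[[1]], test$z[[s]]))
  maps <- lapply(test$z, rate_map)

  structure(list(name = name, profile = profile, seed = seed, spec = spec,
                 trained = trained, test = test,
                 reconstructions = recs, normalized = normed,
                 target_means = target_means,
                 cmi = cmis, xcorr_diff = xdiffs, rate_maps = maps,
                 reward_rate = mean(test$reward_rate),
                 learning_log = trained$log),
            class = "wta_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wta_experiment <- function(x, ...) {
  cat(sprintf("<wta_experiment '%s'> profile=%s seed=%d\n", x$name, x$profile, x$seed))
  cat(sprintf("  testing reward rate: %.3f\n", x$reward_rate))
  cat("  normalized target means:\n")
  for (s in seq_along(x$target_means))
    cat(sprintf("    Sti. %d: %8.4f\n", s, x$target_means[s]))
  invisible(x)
}

#' Save / load a run checkpoint
#'
#' Weights, clustering sets and the spec (minus the sampler closure) with the
#' master seed, for exact resumption of testing/analysis.
#'
#' @param trained a [run_learning()] result.
#' @param path file path.
#' @return `path` invisibly / the restored object.
#' @export
save_checkpoint <- function(trained, path) {
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
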