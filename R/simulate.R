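#' Random Markov-modulated Poisson process specification
#'
#' Draws a random ground-truth model of the kind used for surrogate spike
#' data: a row-stochastic transition matrix with diagonal elements uniform in
#' `diag_range` (off-diagonal mass split by normalized uniform draws),
#' referenced to a bin width `dt_ref`, and firing rates uniform in
#' `rate_range` spikes/s. The surrogate study conditions are 50 trials of
#' 14 s each.
#'
#' @param m number of hidden states (at least 2).
#' @param n_neurons ensemble size.
#' @param n_trials,trial_duration trials per dataset and duration (s).
#' @param dt_ref bin width (s) the transition matrix refers to.
#' @param diag_range,rate_range sampling ranges for the self-transition
#'   probabilities and firing rates.
#' @param seed optional integer seed.
#' @return object of class `mmpp_spec`.
#' @export
random_mmpp_spec <- function(m, n_neurons, n_trials = 50L,
                             trial_duration = 14, dt_ref = 0.05,
                             diag_range = c(0.8, 1), rate_range = c(0, 30),
                             seed = NULL) {
  if (m < 2L) stop("'m' must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  Gamma <- matrix(0, m, m)
  for (i in seq_len(m)) {
    d <- stats::runif(1L, diag_range[1L], diag_range[2L])
    off <- stats::runif(m - 1L)
    Gamma[i, -i] <- (1 - d) * off / sum(off)
    Gamma[i, i] <- d
  }
  Lambda <- matrix(stats::runif(n_neurons * m, rate_range[1L], rate_range[2L]),
                   n_neurons, m)
  mmpp_spec(Gamma = Gamma, Lambda = Lambda, dt_ref = dt_ref,
            n_trials = n_trials, trial_duration = trial_duration)
}

#' Markov-modulated Poisson process specification
#'
#' Container for a ground-truth MMPP: the per-bin transition matrix `Gamma`
#' (referenced to `dt_ref`), the `N x m` rate matrix `Lambda`, and the trial
#' layout. Use [random_mmpp_spec()] for the randomized variant or build one
#' from a fitted model's `Gamma`/`Lambda` to emulate a recorded session.
#'
#' @param Gamma `m x m` row-stochastic matrix.
#' @param Lambda `N x m` rate matrix (spikes/s).
#' @param dt_ref reference bin width in seconds.
#' @param n_trials,trial_duration trial layout.
#' @return object of class `mmpp_spec`.
#' @export
mmpp_spec <- function(Gamma, Lambda, dt_ref = 0.05, n_trials = 50L,
                      trial_duration = 14) {
  Gamma <- as.matrix(Gamma); Lambda <- as.matrix(Lambda)
  if (max(abs(rowSums(Gamma) - 1)) > 1e-10)
    stop("rows of 'Gamma' must sum to 1")
  if (any(Lambda < 0)) stop("rates must be non-negative")
  structure(list(Gamma = Gamma, Lambda = Lambda, dt_ref = dt_ref,
                 m = nrow(Gamma), n_neurons = nrow(Lambda),
                 n_trials = as.integer(n_trials),
                 trial_duration = trial_duration),
            class = "mmpp_spec")
}

# Poisson spike times on [t0, t0 + dur) at rate lambda, via exponential
# inter-spike intervals (the clock restarts at each state switch, which is
# exact by memorylessness).
.poisson_times <- function(lambda, t0, dur) {
  if (lambda <= 0 || dur <= 0) return(numeric(0))
  out <- numeric(0)
  t <- t0
  end <- t0 + dur
  repeat {
    n_draw <- max(16L, ceiling(lambda * (end - t) * 1.5))
    t_new <- t + cumsum(stats::rexp(n_draw, rate = lambda))
    keep <- t_new < end
    out <- c(out, t_new[keep])
    if (!all(keep)) break
    t <- t_new[n_draw]
  }
  out
}

#' Simulate a Markov-modulated Poisson process
#'
#' Gillespie simulation of the continuous-time chain implied by the per-bin
#' transition matrix: from state `i` the chain dwells for an exponential time
#' with rate `(1 - gamma_ii) / dt_ref` and then jumps to `j != i` with
#' probability `gamma_ij / (1 - gamma_ii)`. Within a dwell, each neuron emits
#' Poisson spikes at its state rate. The initial state of each trial is drawn
#' from the stationary distribution of `Gamma`.
#'
#' @param spec an [mmpp_spec()].
#' @param seed optional integer seed.
#' @return list with `dataset` (a [spike_dataset()]) and `paths`, a data
#'   frame of the true piecewise-constant state path with columns `trial`,
#'   `start_s`, `end_s`, `state`.
#' @export
generate_mmpp <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "mmpp_spec"))
  if (!is.null(seed)) set.seed(seed)
  absorbing <- diag(spec$Gamma) >= 1 - 1e-12
  if (any(absorbing))
    warning("absorbing state(s) present: dwell times capped at trial end")
  pi0 <- if (spec$m == 1L) 1 else stationary_distribution(spec$Gamma)
  trials <- vector("list", spec$n_trials)
  paths <- vector("list", spec$n_trials)
  for (k in seq_len(spec$n_trials)) {
    t <- 0
    s <- sample.int(spec$m, 1L, prob = pi0)
    seg <- list()
    nrn <- integer(0); tms <- numeric(0)
    while (t < spec$trial_duration) {
      dwell <- if (absorbing[s]) Inf
               else stats::rexp(1L, rate = (1 - spec$Gamma[s, s]) / spec$dt_ref)
      t_end <- min(t + dwell, spec$trial_duration)
      seg[[length(seg) + 1L]] <- c(t, t_end, s)
      for (n in seq_len(spec$n_neurons)) {
        st <- .poisson_times(spec$Lambda[n, s], t, t_end - t)
        if (length(st)) {
          nrn <- c(nrn, rep(n, length(st)))
          tms <- c(tms, st)
        }
      }
      t <- t_end
      if (t < spec$trial_duration) {
        p <- spec$Gamma[s, ]
        p[s] <- 0
        s <- sample.int(spec$m, 1L, prob = p)
      }
    }
    trials[[k]] <- data.frame(neuron = nrn, time_s = tms)
    sm <- do.call(rbind, seg)
    paths[[k]] <- data.frame(trial = k, start_s = sm[, 1L], end_s = sm[, 2L],
                             state = as.integer(sm[, 3L]))
  }
  list(dataset = spike_dataset(trials, n_neurons = spec$n_neurons,
                               trial_duration = spec$trial_duration),
       paths = do.call(rbind, paths))
}

#' True state per bin from an MMPP path
#'
#' Maps the piecewise-constant ground-truth path onto bin centers so a
#' decoded sequence can be scored bin by bin.
#'
#' @param paths the `paths` data frame of [generate_mmpp()].
#' @param dt bin width in seconds.
#' @param n_bins bins per trial (scalar or per-trial vector).
#' @return list of integer vectors, one per trial.
#' @export
states_per_bin <- function(paths, dt, n_bins) {
  trials <- sort(unique(paths$trial))
  n_bins <- rep_len(n_bins, length(trials))
  lapply(seq_along(trials), function(k) {
    p <- paths[paths$trial == trials[k], , drop = FALSE]
    centers <- (seq_len(n_bins[k]) - 0.5) * dt
    idx <- findInterval(centers, p$start_s)
    as.integer(p$state[idx])
  })
}

#' Random initial guess for HMM training
#'
#' Builds the standard random initialization: the transition matrix is
#' `theta * I + (1 - theta) * U` where `U` has rows `u_ij / sum_j u_ij` built
#' from symmetric uniform draws (`u_ij = u_ji`), with `theta = 0.8` for
#' Poisson models and 0.9 for the Multinoulli model. For Poisson models the
#' initial rates are sampled uniformly between the smallest and largest
#' empirical per-neuron mean rates in the training data and the initial
#' distribution is uniform; for the Multinoulli model the emission rows put
#' nearly all mass on the no-spike symbol and the chain starts in state 1.
#'
#' @param binned a `binned_counts` (Poisson) or `symbol_sequence`
#'   (Multinoulli) object.
#' @param m number of hidden states.
#' @param model_kind `"poisson"` or `"mhmm"`.
#' @param seed optional integer seed.
#' @param theta initialization diagonal weight; defaults to 0.8 (Poisson) or
#'   0.9 (Multinoulli).
#' @return an [hmm_params()] or [mhmm_params()].
#' @export
random_init <- function(binned, m, model_kind = c("poisson", "mhmm"),
                        seed = NULL, theta = NULL) {
  model_kind <- match.arg(model_kind)
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m)
  if (is.null(theta)) theta <- if (model_kind == "poisson") 0.8 else 0.9
  if (m == 1L) {
    Gamma <- matrix(1, 1L, 1L)
  } else {
    u <- matrix(stats::runif(m * m), m, m)
    u[lower.tri(u)] <- t(u)[lower.tri(u)]
    U <- u / rowSums(u)
    Gamma <- theta * diag(m) + (1 - theta) * U
  }
  if (model_kind == "poisson") {
    stopifnot(inherits(binned, "binned_counts"))
    tot <- rowSums(do.call(cbind, binned$counts))
    rate <- tot / (sum(binned$n_bins) * binned$dt)
    Lambda <- matrix(stats::runif(binned$n_neurons * m, min(rate), max(rate)),
                     binned$n_neurons, m)
    hmm_params(pi = rep(1 / m, m), Gamma = Gamma,
               Lambda = pmax(Lambda, .RATE_FLOOR), dt = binned$dt)
  } else {
    stopifnot(inherits(binned, "symbol_sequence"))
    N <- binned$n_neurons
    silent <- stats::runif(m, 0.95, 0.999)
    E <- matrix(stats::runif(m * N), m, N)
    E <- E / rowSums(E) * (1 - silent)
    E <- cbind(E, silent)
    mhmm_params(pi = c(1, rep(0, m - 1L)), Gamma = Gamma, E = E,
                dt = binned$dt)
  }
}

#' Shuffle controls for spike data
#'
#' `circular_shuffle` independently shifts each neuron's spike train in each
#' trial by a uniform random offset, wrapping around the trial: single-neuron
#' statistics are preserved but cross-neuron coordination (and hence the
#' state transitions) is destroyed. `swap_shuffle` applies a random
#' permutation of the bin order of each trial jointly to all neurons: the
#' count vectors (states) survive but are scattered into short non-adjacent
#' fragments.
#'
#' @param dataset a [spike_dataset()].
#' @param binned a `binned_counts` object.
#' @param seed optional integer seed.
#' @return the same type as the input, shuffled.
#' @export
circular_shuffle <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!is.null(seed)) set.seed(seed)
  trials <- lapply(seq_along(dataset$trials), function(k) {
    tr <- dataset$trials[[k]]
    dur <- dataset$trial_duration[k]
    off <- stats::runif(dataset$n_neurons, 0, dur)
    tr$time_s <- (tr$time_s + off[tr$neuron]) %% dur
    tr
  })
  spike_dataset(trials, dataset$n_neurons, dataset$trial_duration)
}

#' @rdname circular_shuffle
#' @export
swap_shuffle <- function(binned, seed = NULL) {
  stopifnot(inherits(binned, "binned_counts"))
  if (!is.null(seed)) set.seed(seed)
  out <- binned
  out$counts <- lapply(binned$counts, function(K)
    K[, sample.int(ncol(K)), drop = FALSE])
  out
}

#' Clustered spiking network configuration
#'
#' Parameters of the clustered leaky integrate-and-fire network used as a
#' biologically grounded surrogate: excitatory and inhibitory populations
#' with random connectivity, a fraction `f` of the excitatory neurons
#' organized into `Q` clusters with potentiated within-cluster weights
#' (`j_plus`) and correspondingly depressed between-cluster weights
#' (`j_minus = max(1 - gamma_depress * (j_plus - 1) * f / Q, 0)`). Times are
#' in seconds, potentials in mV, currents in nA, capacitance in nF.
#'
#' @param n_e,n_i population sizes.
#' @param duration simulated time in seconds (desk-scale by default; the
#'   full-scale regime of thousands of seconds is a cluster job).
#' @param euler_dt forward-Euler step in seconds (default 5e-6, i.e.
#'   0.005 ms).
#' @param ... override any other named default.
#' @return object of class `snn_config`.
#' @export
snn_config <- function(n_e = 4000L, n_i = 1000L, duration = 10,
                       euler_dt = 5e-6, ...) {
  cfg <- list(
    n_e = as.integer(n_e), n_i = as.integer(n_i),
    p_ee = 0.2, p_ei = 0.5, p_ie = 0.5, p_ii = 0.5,
    w_ee = 0.0416, w_ie = 0.0212, w_ei = -0.0882, w_ii = -0.0848,
    sd_ee_ei = 0.0028, sd_ie_ii = 0.0020,
    q_clusters = 10L, j_plus = 2.2, gamma_depress = 0.5, f_clustered = 0.9,
    v_th_e = -55, v_th_i = -58, v_r = -60, v_l = -60,
    tau_e = 0.020, tau_i = 0.010, tau_syn_e = 0.008, tau_syn_i = 0.005,
    capacitance = 1, i_ext_e = 0.3217, i_ext_i = 0.2080,
    refractory = 0.005, euler_dt = euler_dt, duration = duration)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown snn_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$j_minus <- max(1 - cfg$gamma_depress * (cfg$j_plus - 1) *
                       cfg$f_clustered / cfg$q_clusters, 0)
  structure(cfg, class = "snn_config")
}

#' Simulate the clustered spiking network
#'
#' Forward-Euler integration of the leaky integrate-and-fire network with
#' exponential synaptic currents (each presynaptic spike injects a total
#' charge equal to its weight, decaying with the synaptic time constant),
#' threshold-reset-refractory spiking, and the clustered excitatory weight
#' structure of [snn_config()]. Returns the spikes of a recorded subset of
#' neurons as a single-trial [spike_dataset()].
#'
#' @param config an [snn_config()].
#' @param seed optional integer seed.
#' @param record integer indices of neurons to record; by default 9
#'   excitatory neurons drawn from 5 distinct clusters, the ensemble size
#'   used when treating the network as a surrogate recording session.
#' @return list with `dataset` (recorded neurons renumbered `1..length(record)`),
#'   `record` (original indices), and `cluster` (cluster label of each
#'   recorded neuron; 0 = background/inhibitory).
#' @export
simulate_snn <- function(config, seed = NULL, record = NULL) {
  stopifnot(inherits(config, "snn_config"))
  if (!is.null(seed)) set.seed(seed)
  csize <- floor(config$f_clustered * config$n_e / config$q_clusters)
  if (is.null(record)) {
    cl <- sample.int(min(5L, config$q_clusters))
    per <- rep_len(c(2L, 2L, 2L, 2L, 1L), length(cl))
    record <- unlist(lapply(seq_along(cl), function(i)
      (cl[i] - 1L) * csize + sample.int(csize, per[i])))
  }
  record <- sort(as.integer(record))
  res <- snn_cpp(config$n_e, config$n_i, config$q_clusters,
                 config$f_clustered,
                 config$p_ee, config$p_ei, config$p_ie, config$p_ii,
                 config$w_ee, config$w_ie, config$w_ei, config$w_ii,
                 config$sd_ee_ei, config$sd_ie_ii,
                 config$j_plus, config$j_minus,
                 config$v_th_e, config$v_th_i, config$v_r, config$v_l,
                 config$tau_e * 1e3, config$tau_i * 1e3,
                 config$tau_syn_e * 1e3, config$tau_syn_i * 1e3,
                 config$capacitance, config$i_ext_e, config$i_ext_i,
                 config$refractory * 1e3, config$euler_dt * 1e3,
                 config$duration * 1e3, record - 1L)
  neuron <- match(res$neuron + 1L, record)
  tr <- data.frame(neuron = neuron, time_s = res$time_ms / 1e3)
  tr <- tr[tr$time_s < config$duration, , drop = FALSE]
  list(dataset = spike_dataset(list(tr), n_neurons = length(record),
                               trial_duration = config$duration),
       record = record,
       cluster = res$cluster_of[record])
}
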