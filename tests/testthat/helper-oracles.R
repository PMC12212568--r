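# Independent brute-force oracles used to pin down the recursive
# implementations on tiny instances, plus small fixture builders.

# enumerate all m^T state paths; exact posteriors, pairwise posteriors and
# log-likelihood by direct summation of path probabilities
enum_forward_backward <- function(logB, Gamma, pi) {
  m <- nrow(logB); T <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), T)))
  logp <- apply(paths, 1L, function(s) {
    lp <- log(pi[s[1L]]) + logB[s[1L], 1L]
    if (T > 1L) for (t in 2:T)
      lp <- lp + log(Gamma[s[t - 1L], s[t]]) + logB[s[t], t]
    lp
  })
  M <- max(logp)
  w <- exp(logp - M)
  lik <- sum(w)
  loglik <- M + log(lik)
  q <- matrix(0, m, T)
  for (t in seq_len(T))
    for (i in seq_len(m))
      q[i, t] <- sum(w[paths[, t] == i]) / lik
  xi <- if (T > 1L) array(0, c(m, m, T - 1L)) else NULL
  if (T > 1L)
    for (t in seq_len(T - 1L))
      for (i in seq_len(m))
        for (j in seq_len(m))
          xi[i, j, t] <- sum(w[paths[, t] == i & paths[, t + 1L] == j]) / lik
  list(q = q, xi = xi, loglik = loglik,
       best_path = paths[which.max(logp), ], best_logp = max(logp))
}

# min-cost assignment by exhaustive permutation search (square cost matrix)
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1L, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  costs <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(assignment = perms[which.min(costs), ], cost = min(costs))
}

# tiny deterministic spike dataset builders
toy_dataset <- function(times_by_trial, n_neurons, duration) {
  spike_dataset(lapply(times_by_trial, function(x)
    data.frame(neuron = x$neuron, time_s = x$time_s)),
    n_neurons = n_neurons, trial_duration = duration)
}

# Poisson counts drawn from a known HMM path (sticky chain), for recovery and
# decoding round trips
sample_from_hmm <- function(params, n_trials, n_bins, seed) {
  set.seed(seed)
  pi0 <- if (params$m == 1L) 1 else stationary_distribution(params$Gamma)
  counts <- list(); states <- list()
  for (k in seq_len(n_trials)) {
    s <- integer(n_bins)
    s[1L] <- sample.int(params$m, 1L, prob = pi0)
    if (n_bins > 1L) for (t in 2:n_bins)
      s[t] <- sample.int(params$m, 1L, prob = params$Gamma[s[t - 1L], ])
    K <- matrix(stats::rpois(params$N * n_bins,
                             params$Lambda[, s] * params$dt),
                params$N, n_bins)
    counts[[k]] <- K
    states[[k]] <- s
  }
  list(counts = structure(list(counts = counts, dt = params$dt,
                               n_bins = rep(n_bins, n_trials),
                               n_neurons = params$N),
                          class = "binned_counts"),
       states = states)
}

# small random row-stochastic matrix with a given diagonal floor
random_sticky_gamma <- function(m, diag_min = 0.85, diag_max = 0.95) {
  G <- matrix(0, m, m)
  for (i in seq_len(m)) {
    d <- stats::runif(1L, diag_min, diag_max)
    off <- stats::runif(m - 1L)
    G[i, -i] <- (1 - d) * off / sum(off)
    G[i, i] <- d
  }
  G
}
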