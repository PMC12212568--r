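#' Multinoulli (categorical) HMM parameter set
#'
#' Benchmark model in which each short time bin emits one of `N + 1` symbols:
#' symbol `n <= N` when neuron `n` fires the bin's single spike, symbol
#' `N + 1` when no neuron fires. `E` is the `m x (N + 1)` row-stochastic
#' emission matrix `e_i(n)`.
#'
#' @param pi initial state probabilities (vector or per-trial matrix).
#' @param Gamma `m x m` row-stochastic transition matrix.
#' @param E `m x (N + 1)` emission matrix; rows sum to 1.
#' @param dt bin width in seconds (default 0.005; the single-spike encoding
#'   breaks down above 0.01).
#' @return object of class `mhmm_params`.
#' @export
mhmm_params <- function(pi, Gamma, E, dt = 0.005) {
  Gamma <- as.matrix(Gamma); E <- as.matrix(E)
  m <- nrow(Gamma)
  if (ncol(Gamma) != m || nrow(E) != m)
    stop("'Gamma' must be m x m and 'E' must have m rows")
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1L)
  pi <- as.matrix(pi)
  if (any(E < 0) || any(E > 1)) stop("emission entries must lie in [0, 1]")
  if (max(abs(rowSums(E) - 1)) > 1e-10) stop("rows of 'E' must sum to 1")
  if (max(abs(rowSums(Gamma) - 1)) > 1e-10)
    stop("rows of 'Gamma' must sum to 1")
  if (max(abs(rowSums(pi) - 1)) > 1e-10) stop("rows of 'pi' must sum to 1")
  structure(list(pi = pi, Gamma = Gamma, E = E, dt = dt, m = m,
                 N = ncol(E) - 1L),
            class = "mhmm_params")
}

#' Train a Multinoulli-HMM by Baum-Welch
#'
#' Categorical Baum-Welch on per-trial symbol sequences: the transition
#' update is the usual pooled ratio of pairwise to single posteriors, and the
#' emission update is the expected number of observations of each symbol
#' while in each state divided by the expected occupancy of that state,
#' pooled over trials. Convergence requires the transition matrix, emission
#' matrix and log-likelihood to all change by less than their tolerances.
#'
#' @param symbols a `symbol_sequence` (see [encode_symbols()]).
#' @param init an [mhmm_params()] initial guess (see [random_init()]).
#' @param maxiter maximum number of EM iterations.
#' @param tol length-3 tolerances: max transition change, max emission
#'   change, relative log-likelihood change.
#' @param fixed_pi keep per-trial initial distributions at their initial
#'   value.
#' @param verbose log progress per iteration.
#' @return a `train_result` whose `params` is an `mhmm_params`.
#' @export
train_mhmm <- function(symbols, init, maxiter = 1000L,
                       tol = c(1e-6, 1e-6, 1e-6), fixed_pi = FALSE,
                       verbose = FALSE) {
  stopifnot(inherits(symbols, "symbol_sequence"),
            inherits(init, "mhmm_params"))
  n_sym <- init$N + 1L
  n_trials <- length(symbols$symbols)
  params <- init
  if (nrow(params$pi) == 1L && n_trials > 1L)
    params$pi <- matrix(rep(params$pi, each = n_trials), n_trials, params$m)
  eps <- 1e-300
  traj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    g_num <- matrix(0, params$m, params$m); g_den <- numeric(params$m)
    e_num <- matrix(0, params$m, n_sym); e_den <- numeric(params$m)
    pi_new <- params$pi
    ll <- 0
    logE <- log(pmax(params$E, eps))
    for (k in seq_len(n_trials)) {
      s <- symbols$symbols[[k]]
      logB <- logE[, s, drop = FALSE]
      fb <- fb_cpp(logB, params$Gamma,
                   params$pi[min(k, nrow(params$pi)), ], FALSE)
      ll <- ll + fb$loglik
      Tk <- length(s)
      pi_new[k, ] <- fb$q[, 1L]
      if (Tk > 1L) {
        g_num <- g_num + fb$xi_sum
        g_den <- g_den + rowSums(fb$q[, -Tk, drop = FALSE])
      }
      for (n in seq_len(n_sym)) {
        idx <- s == n
        if (any(idx))
          e_num[, n] <- e_num[, n] + rowSums(fb$q[, idx, drop = FALSE])
      }
      e_den <- e_den + rowSums(fb$q)
    }
    traj <- c(traj, ll)
    Gamma_new <- g_num / pmax(g_den, eps)
    Gamma_new <- Gamma_new / rowSums(Gamma_new)
    E_new <- e_num / pmax(e_den, eps)
    E_new <- E_new / rowSums(E_new)
    dG <- max(abs(Gamma_new - params$Gamma))
    dE <- max(abs(E_new - params$E))
    prev <- if (length(traj) > 1L) traj[length(traj) - 1L] else -Inf
    rel <- abs(ll - prev) / max(1, abs(prev))
    if (verbose)
      message(sprintf("iter %d: LL = %.6f, dGamma = %.3g, dE = %.3g",
                      iter, ll, dG, dE))
    params$Gamma <- Gamma_new
    params$E <- E_new
    if (!fixed_pi) params$pi <- pi_new
    if (is.finite(prev) && dG < tol[1L] && dE < tol[2L] && rel < tol[3L]) {
      converged <- TRUE
      break
    }
  }
  logE <- log(pmax(params$E, eps))
  final_ll <- 0
  for (k in seq_len(n_trials))
    final_ll <- final_ll +
      fb_cpp(logE[, symbols$symbols[[k]], drop = FALSE], params$Gamma,
             params$pi[min(k, nrow(params$pi)), ], FALSE)$loglik
  structure(list(params = params, loglik = final_ll,
                 log_posterior = final_ll, loglik_trajectory = traj,
                 converged = converged, n_iterations = iter, n_resets = 0L,
                 min_self_transition = min(diag(params$Gamma))),
            class = "train_result")
}

#' Firing rates implied by Multinoulli emissions
#'
#' Inverts the parameterization `e_i(n) = 1 - exp(-lambda_ni dt)` of the
#' spiking symbols, giving `lambda_ni = -log(1 - e_i(n)) / dt` for
#' `n <= N`. The no-spike symbol (column `N + 1`) carries no rate.
#'
#' @param params an [mhmm_params()].
#' @return `N x m` matrix of firing rates in spikes/s.
#' @export
rates_from_emissions <- function(params) {
  stopifnot(inherits(params, "mhmm_params"))
  Es <- params$E[, seq_len(params$N), drop = FALSE]
  if (any(Es >= 1))
    stop("emission probability 1 for a spiking symbol implies an infinite rate")
  t(-log(1 - Es) / params$dt)
}

#' Probability that several neurons spike in the same bin
#'
#' For `N` conditionally independent Poisson neurons firing at a common rate,
#' the per-neuron probability of at least one spike in a bin of width `dt` is
#' `p = 1 - exp(-rate * dt)`; the probability that two or more neurons spike
#' in the same bin is `1 - (1-p)^N - N p (1-p)^(N-1)`. This quantifies when
#' the single-spike symbol encoding of the Multinoulli model breaks down
#' (e.g. about 0.26 for 100 neurons at 5 spikes/s in 2 ms bins).
#'
#' @param n_neurons ensemble size `N`.
#' @param rate common firing rate in spikes/s.
#' @param dt bin width in seconds.
#' @return a probability.
#' @export
multi_spike_probability <- function(n_neurons, rate, dt) {
  if (rate < 0 || dt <= 0) stop("'rate' must be >= 0 and 'dt' > 0")
  N <- as.integer(n_neurons)
  p <- 1 - exp(-rate * dt)
  1 - (1 - p)^N - N * p * (1 - p)^(N - 1)
}
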