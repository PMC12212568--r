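#' Poisson-HMM parameter set
#'
#' Parameters of a Poisson hidden Markov model over an ensemble of `N`
#' neurons: an initial state distribution (one row per trial, or a single
#' shared row), an `m x m` row-stochastic transition matrix `Gamma`, and an
#' `N x m` firing-rate matrix `Lambda` in spikes/s whose columns are the
#' hidden states.
#'
#' @param pi initial state probabilities: a length-`m` vector or a
#'   `n_trials x m` matrix (rows sum to 1).
#' @param Gamma `m x m` transition matrix; rows sum to 1.
#' @param Lambda `N x m` matrix of non-negative firing rates (spikes/s).
#' @param dt bin width in seconds the model is referenced to.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(pi, Gamma, Lambda, dt) {
  Gamma <- as.matrix(Gamma); Lambda <- as.matrix(Lambda)
  m <- nrow(Gamma)
  if (ncol(Gamma) != m) stop("'Gamma' must be square")
  if (is.null(dim(pi))) pi <- matrix(pi, nrow = 1L)
  pi <- as.matrix(pi)
  if (ncol(pi) != m || ncol(Lambda) != m)
    stop("'pi' and 'Lambda' must have m columns")
  if (any(Gamma < 0) || any(Gamma > 1) || any(pi < 0) || any(pi > 1))
    stop("probabilities must lie in [0, 1]")
  if (max(abs(rowSums(Gamma) - 1)) > 1e-10)
    stop("rows of 'Gamma' must sum to 1")
  if (max(abs(rowSums(pi) - 1)) > 1e-10)
    stop("rows of 'pi' must sum to 1")
  if (any(Lambda < 0)) stop("'Lambda' must be non-negative")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  structure(list(pi = pi, Gamma = Gamma, Lambda = Lambda, dt = dt,
                 m = m, N = nrow(Lambda)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: m = %d states, N = %d neurons, dt = %g s, min self-transition = %.4f\n",
              x$m, x$N, x$dt, min(diag(x$Gamma))))
  invisible(x)
}

# smallest admissible firing rate (spikes/s), applied after every M-step
.RATE_FLOOR <- 0.001

#' Poisson log emission probabilities
#'
#' Log-probability of a spike-count observation under each hidden state,
#' using the factorized product of per-neuron Poisson pmfs with means
#' `lambda * dt`: entry `i` equals
#' `sum_n [ k_n log(lambda_ni dt) - lambda_ni dt - log(k_n!) ]`.
#' The `log(k!)` constant is included, so summed emissions equal the exact
#' log-likelihood contributions.
#'
#' @param counts a length-`N` count vector or an `N x T` count matrix.
#' @param params an [hmm_params()].
#' @return a length-`m` vector (vector input) or `m x T` matrix.
#' @export
poisson_log_emission <- function(counts, params) {
  stopifnot(inherits(params, "hmm_params"))
  K <- if (is.null(dim(counts))) matrix(counts, ncol = 1L) else as.matrix(counts)
  if (nrow(K) != params$N) stop("counts must have N rows")
  if (any(K < 0)) stop("counts must be non-negative")
  Ldt <- pmax(params$Lambda * params$dt, .RATE_FLOOR * params$dt)
  logB <- crossprod(log(Ldt), K) - colSums(Ldt) - rep(colSums(lgamma(K + 1)),
                                                      each = params$m)
  if (is.null(dim(counts))) drop(logB) else logB
}

#' Forward-backward E-step for one trial
#'
#' Computes the per-bin state posteriors `q_i(t)`, the pairwise posteriors
#' `xi_ij(t)` and the exact log-likelihood of one observation sequence, using
#' per-bin scaling of the forward variables with accumulated log scale
#' factors (numerically safe for long trials).
#'
#' @param log_emissions `m x T` matrix of log emission probabilities (e.g.
#'   from [poisson_log_emission()]).
#' @param Gamma `m x m` row-stochastic transition matrix.
#' @param pi length-`m` initial state distribution.
#' @param want_xi keep the full `m x m x (T-1)` pairwise posterior array
#'   (the `m x m` sum over bins is always returned).
#' @return object of class `fb_result`: list with `q` (`m x T`), `xi`
#'   (`m x m x (T-1)` or `NULL`), `xi_sum`, and `loglik`.
#' @export
forward_backward <- function(log_emissions, Gamma, pi, want_xi = TRUE) {
  log_emissions <- as.matrix(log_emissions)
  Gamma <- as.matrix(Gamma)
  if (nrow(log_emissions) != nrow(Gamma))
    stop("'log_emissions' must have m rows")
  if (max(abs(rowSums(Gamma) - 1)) > 1e-8)
    stop("'Gamma' must be row-stochastic")
  res <- fb_cpp(log_emissions, Gamma, as.numeric(pi), want_xi)
  structure(list(q = res$q,
                 xi = if (want_xi && ncol(log_emissions) > 1L) res$xi else NULL,
                 xi_sum = res$xi_sum, loglik = res$loglik),
            class = "fb_result")
}

#' Baum-Welch M-step for Poisson-HMMs
#'
#' Re-estimates the parameters from per-trial posteriors: the initial
#' distribution of each trial is its `q(1)`; transition and rate updates pool
#' numerators and denominators over all trials. Rates are clamped from below
#' at 0.001 spikes/s. With a Dirichlet prior the transition update becomes
#' the maximum-a-posteriori formula (see [map_transition_update()]).
#'
#' @param fb_per_trial list of [forward_backward()] results, one per trial.
#' @param counts a `binned_counts` object aligned with `fb_per_trial`.
#' @param prior optional [dirichlet_prior()] for the MAP transition update.
#' @return an [hmm_params()] with per-trial `pi` rows.
#' @export
m_step <- function(fb_per_trial, counts, prior = NULL) {
  stopifnot(inherits(counts, "binned_counts"))
  m <- nrow(fb_per_trial[[1L]]$q)
  N <- counts$n_neurons
  g_num <- matrix(0, m, m); g_den <- numeric(m)
  l_num <- matrix(0, N, m); l_den <- numeric(m)
  pi <- matrix(0, length(fb_per_trial), m)
  for (k in seq_along(fb_per_trial)) {
    fb <- fb_per_trial[[k]]
    Tk <- ncol(fb$q)
    pi[k, ] <- fb$q[, 1L]
    if (Tk > 1L) {
      g_num <- g_num + fb$xi_sum
      g_den <- g_den + rowSums(fb$q[, -Tk, drop = FALSE])
    }
    l_num <- l_num + counts$counts[[k]] %*% t(fb$q)
    l_den <- l_den + rowSums(fb$q)
  }
  if (is.null(prior)) {
    Gamma <- g_num / g_den
    dead <- g_den <= 0
    if (any(dead)) Gamma[dead, ] <- diag(m)[dead, , drop = FALSE]
  } else {
    A <- prior$A
    Gamma <- sweep(g_num + A - 1, 1L, g_den + rowSums(A - 1), "/")
  }
  Gamma <- Gamma / rowSums(Gamma)  # exact row normalization
  if (any(l_den <= .Machine$double.eps)) {
    warning("state never visited: rates of collapsed state set to the floor")
    l_den[l_den <= .Machine$double.eps] <- Inf
  }
  Lambda <- pmax(sweep(l_num, 2L, l_den, "/") / counts$dt, .RATE_FLOOR)
  hmm_params(pi = pi, Gamma = Gamma, Lambda = Lambda, dt = counts$dt)
}

# total data log-likelihood of 'params' on 'counts' (forward pass only).
# 'pi' overrides the per-trial initial distributions (e.g. stationary).
.poisson_loglik <- function(counts, params, pi = NULL) {
  ll <- 0
  for (k in seq_along(counts$counts)) {
    logB <- poisson_log_emission(counts$counts[[k]], params)
    p0 <- if (!is.null(pi)) pi
          else params$pi[min(k, nrow(params$pi)), ]
    ll <- ll + fb_cpp(as.matrix(logB), params$Gamma, p0, FALSE)$loglik
  }
  ll
}

# Shared Baum-Welch training loop for the PHMM, DPHMM (prior) and sPHMM
# (sticky). Monitors the log-likelihood -- or the log-posterior when a prior
# is given -- together with the maximum absolute parameter change. Counts
# are concatenated across trials so each iteration costs one emission
# matmul and one rate-numerator matmul.
.train_poisson <- function(counts, init, maxiter = 1000L,
                           tol = c(1e-6, 1e-6), prior = NULL,
                           sticky = NULL, fixed_pi = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(counts, "binned_counts"), inherits(init, "hmm_params"))
  n_trials <- length(counts$counts)
  params <- init
  if (nrow(params$pi) == 1L && n_trials > 1L)
    params$pi <- matrix(rep(params$pi, each = n_trials), n_trials, params$m)
  Kall <- do.call(cbind, counts$counts)
  Tk <- vapply(counts$counts, ncol, 1L)
  off <- cumsum(c(0L, Tk))
  clg_all <- colSums(lgamma(Kall + 1))
  m <- params$m
  logprior <- function(Gamma) {
    if (is.null(prior)) 0 else sum((prior$A - 1) * log(Gamma))
  }
  # rolling snapshot for the sticky reset (qualifies iff all diagonals >= theta)
  snap <- NULL
  if (!is.null(sticky)) {
    if (min(diag(params$Gamma)) >= sticky$theta)
      snap <- list(Gamma = params$Gamma, Lambda = params$Lambda)
  }
  traj <- numeric(0)
  n_resets <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < maxiter) {
    iter <- iter + 1L
    Ldt <- pmax(params$Lambda * params$dt, .RATE_FLOOR * params$dt)
    logB_all <- crossprod(log(Ldt), Kall) - colSums(Ldt) -
      rep(clg_all, each = m)
    qall <- matrix(0, m, ncol(Kall))
    g_num <- matrix(0, m, m); g_den <- numeric(m)
    pi_new <- params$pi
    ll <- 0
    for (k in seq_len(n_trials)) {
      cols <- (off[k] + 1L):off[k + 1L]
      r <- fb_cpp(logB_all[, cols, drop = FALSE], params$Gamma,
                  params$pi[min(k, nrow(params$pi)), ], FALSE)
      ll <- ll + r$loglik
      qall[, cols] <- r$q
      pi_new[k, ] <- r$q[, 1L]
      if (Tk[k] > 1L) {
        g_num <- g_num + r$xi_sum
        g_den <- g_den + rowSums(r$q[, -Tk[k], drop = FALSE])
      }
    }
    obj <- ll + logprior(params$Gamma)
    traj <- c(traj, obj)
    if (is.null(prior)) {
      Gamma_new <- g_num / g_den
      dead <- g_den <= 0
      if (any(dead)) Gamma_new[dead, ] <- diag(m)[dead, , drop = FALSE]
    } else {
      Gamma_new <- sweep(g_num + prior$A - 1, 1L,
                         g_den + rowSums(prior$A - 1), "/")
    }
    Gamma_new <- Gamma_new / rowSums(Gamma_new)
    l_den <- rowSums(qall)
    if (any(l_den <= .Machine$double.eps)) {
      warning("state never visited: rates of collapsed state set to the floor")
      l_den[l_den <= .Machine$double.eps] <- Inf
    }
    Lambda_new <- pmax(sweep(Kall %*% t(qall), 2L, l_den, "/") / counts$dt,
                       .RATE_FLOOR)
    new <- params
    new$Gamma <- Gamma_new
    new$Lambda <- Lambda_new
    if (!fixed_pi) new$pi <- pi_new
    dpar <- max(abs(new$Gamma - params$Gamma), abs(new$Lambda - params$Lambda))
    if (verbose)
      message(sprintf("iter %d: %s = %.6f, max param delta = %.3g",
                      iter, if (is.null(prior)) "LL" else "LP", obj, dpar))
    if (!is.null(sticky)) {
      dd <- diag(new$Gamma)
      offending <- dd < sticky$theta &
        abs(dd - diag(params$Gamma)) < sticky$epsilon
      if (any(offending)) {
        if (is.null(snap))
          stop("sticky reset fired before any snapshot qualified; ",
               "initialize with self-transitions >= theta")
        perm <- sample.int(params$m)
        params$Gamma <- snap$Gamma
        params$Lambda <- snap$Lambda[, perm, drop = FALSE]
        n_resets <- n_resets + 1L
        next
      }
      if (min(dd) >= sticky$theta)
        snap <- list(Gamma = new$Gamma, Lambda = new$Lambda)
    }
    prev_obj <- if (length(traj) > 1L) traj[length(traj) - 1L] else -Inf
    rel <- abs(obj - prev_obj) / max(1, abs(prev_obj))
    params <- new
    if (is.finite(prev_obj) && rel < tol[1L] && dpar < tol[2L]) {
      converged <- TRUE
      break
    }
  }
  if (!is.null(sticky) && converged &&
      min(diag(params$Gamma)) < sticky$theta)
    converged <- FALSE  # unreachable by construction (tol2 < epsilon), kept as a guard
  final_ll <- .poisson_loglik(counts, params)
  structure(list(params = params,
                 loglik = final_ll,
                 log_posterior = final_ll + logprior(params$Gamma),
                 loglik_trajectory = traj,
                 converged = converged,
                 n_iterations = iter,
                 n_resets = n_resets,
                 min_self_transition = min(diag(params$Gamma))),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "train_result: m = %d, %s after %d iterations (LL = %.3f, min self-transition = %.4f%s)\n",
    x$params$m, if (x$converged) "converged" else "NOT converged",
    x$n_iterations, x$loglik, x$min_self_transition,
    if (x$n_resets > 0L) sprintf(", %d sticky resets", x$n_resets) else ""))
  invisible(x)
}

#' Train a Poisson-HMM by Baum-Welch
#'
#' Multi-trial expectation-maximization for the vanilla Poisson-HMM:
#' alternates the scaled forward-backward E-step and the pooled M-step until
#' both the relative log-likelihood change falls below `tol[1]` and the
#' largest absolute parameter change falls below `tol[2]`, or `maxiter` is
#' reached. A separate initial state distribution is re-estimated for each
#' trial (set `fixed_pi = TRUE` to keep the initial distribution fixed).
#'
#' @param counts a `binned_counts` object.
#' @param init an [hmm_params()] initial guess (see [random_init()]).
#' @param maxiter maximum number of EM iterations.
#' @param tol length-2 tolerances: relative log-likelihood change and maximum
#'   absolute parameter change.
#' @param fixed_pi keep the initial state distribution at its initial value.
#' @param verbose log iteration, objective and parameter delta.
#' @return object of class `train_result` with elements `params`, `loglik`,
#'   `loglik_trajectory`, `converged`, `n_iterations`, `min_self_transition`.
#' @export
train_phmm <- function(counts, init, maxiter = 1000L, tol = c(1e-6, 1e-6),
                       fixed_pi = FALSE, verbose = FALSE) {
  .train_poisson(counts, init, maxiter = maxiter, tol = tol,
                 fixed_pi = fixed_pi, verbose = verbose)
}
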