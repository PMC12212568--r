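# per-trial log emission matrix for either model family
.log_emissions <- function(obs, params, trial) {
  if (inherits(params, "hmm_params")) {
    as.matrix(poisson_log_emission(obs$counts[[trial]], params))
  } else {
    logE <- log(pmax(params$E, 1e-300))
    logE[, obs$symbols[[trial]], drop = FALSE]
  }
}

.n_trials_obs <- function(obs) {
  if (inherits(obs, "binned_counts")) length(obs$counts)
  else length(obs$symbols)
}

# initial distribution used for decoding
.decode_pi <- function(params, init) {
  if (init == "stationary") stationary_distribution(params$Gamma)
  else c(1, rep(0, params$m - 1L))
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi' (I - Gamma + 1) = 1` for the stationary distribution of an
#' ergodic chain, i.e. the `pi` with `pi' Gamma = pi'` and `sum(pi) = 1`.
#'
#' @param Gamma `m x m` row-stochastic matrix.
#' @return length-`m` probability vector.
#' @export
stationary_distribution <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  m <- nrow(Gamma)
  if (max(abs(rowSums(Gamma) - 1)) > 1e-8)
    stop("'Gamma' must be row-stochastic")
  A <- diag(m) - Gamma + matrix(1, m, m)
  pi <- tryCatch(solve(t(A), rep(1, m)), error = function(e)
    stop("stationary distribution solve failed (reducible or periodic chain): ",
         conditionMessage(e)))
  resid <- max(abs(drop(pi %*% Gamma) - pi))
  if (resid > 1e-8 || any(pi < -1e-12))
    stop(sprintf("stationary distribution invalid (residual %.3g)", resid))
  pmax(pi, 0) / sum(pmax(pi, 0))
}

#' Posterior state decoding with an undecided-bin rule
#'
#' Assigns each bin to the state with the largest posterior probability
#' `q_i(t)` given the whole trial; bins whose maximal posterior falls below
#' `threshold` are left undecided (`NA`). Ties are broken by the lowest state
#' index. The decoding initial distribution defaults to the stationary
#' distribution of the fitted chain; `init = "state1"` starts deterministically
#' in state 1, in which case the first `pre_roll` seconds are treated as
#' burn-in and marked undecided.
#'
#' @param obs a `binned_counts` (Poisson models) or `symbol_sequence`
#'   (Multinoulli) object.
#' @param params an [hmm_params()] or [mhmm_params()].
#' @param threshold posterior probability below which a bin is undecided;
#'   set to 0 to force a decision in every bin.
#' @param init `"stationary"` or `"state1"`.
#' @param pre_roll burn-in in seconds applied when `init = "state1"`.
#' @return object of class `decode_result`: `states` (list of integer
#'   vectors, `NA` = undecided), `posteriors` (list of `m x T` matrices),
#'   `method`, `threshold`.
#' @export
posterior_decode <- function(obs, params, threshold = 0.8,
                             init = c("stationary", "state1"),
                             pre_roll = 0.4) {
  init <- match.arg(init)
  pi <- .decode_pi(params, init)
  states <- list(); posteriors <- list()
  for (k in seq_len(.n_trials_obs(obs))) {
    logB <- .log_emissions(obs, params, k)
    q <- fb_cpp(logB, params$Gamma, pi, FALSE)$q
    # argmax with a tiny tolerance so numerically tied posteriors resolve
    # deterministically to the lowest state index
    s <- apply(q, 2L, function(col) which(col >= max(col) - 1e-9)[1L])
    s[apply(q, 2L, max) < threshold] <- NA_integer_
    if (init == "state1" && pre_roll > 0) {
      burn <- min(floor(pre_roll / params$dt), length(s))
      if (burn > 0L) s[seq_len(burn)] <- NA_integer_
    }
    states[[k]] <- as.integer(s)
    posteriors[[k]] <- q
  }
  structure(list(states = states, posteriors = posteriors,
                 method = "posterior", threshold = threshold),
            class = "decode_result")
}

#' Viterbi state decoding
#'
#' Computes the single most probable state path for each trial; every bin is
#' assigned a state (no undecided bins) and the joint log-probability of each
#' path is reported.
#'
#' @inheritParams posterior_decode
#' @return a `decode_result` with `states`, `path_logp` (per trial),
#'   `method = "viterbi"`.
#' @export
viterbi_decode <- function(obs, params, init = c("stationary", "state1")) {
  init <- match.arg(init)
  pi <- .decode_pi(params, init)
  states <- list(); logp <- numeric(0)
  for (k in seq_len(.n_trials_obs(obs))) {
    logB <- .log_emissions(obs, params, k)
    v <- viterbi_cpp(logB, params$Gamma, pi)
    states[[k]] <- as.integer(v$path)
    logp[k] <- v$logp
  }
  structure(list(states = states, path_logp = logp, method = "viterbi",
                 threshold = NA_real_),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  und <- mean(is.na(unlist(x$states)))
  cat(sprintf("decode_result (%s): %d trials, %.1f%% undecided bins\n",
              x$method, length(x$states), 100 * und))
  invisible(x)
}
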