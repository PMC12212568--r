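#' Sticky training configuration
#'
#' Settings for the sticky Poisson-HMM: the self-transition threshold
#' `theta`, and the tolerance `epsilon` that decides when a self-transition
#' probability has *converged* below the threshold (a reset only fires once
#' the offending diagonal has settled, so transient dips do not interrupt
#' training).
#'
#' @param theta self-transition threshold in (0, 1); 0.8 corresponds to mean
#'   state durations of at least 5 bins (250 ms at 50 ms bins).
#' @param epsilon convergence tolerance for an individual self-transition
#'   probability.
#' @param maxiter,tol as in [train_phmm()]; the iteration budget is shared
#'   across resets.
#' @return object of class `sticky_config`.
#' @export
sticky_config <- function(theta = 0.8, epsilon = 5e-5, maxiter = 1000L,
                          tol = c(1e-6, 1e-6)) {
  if (!(theta > 0 && theta < 1)) stop("'theta' must lie in (0, 1)")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  structure(list(theta = theta, epsilon = epsilon,
                 maxiter = as.integer(maxiter), tol = tol),
            class = "sticky_config")
}

#' Train a sticky Poisson-HMM
#'
#' Runs Baum-Welch while monitoring the self-transition probabilities. A
#' rolling snapshot of `(Gamma, Lambda)` is kept at the most recent iteration
#' (including the initial guess) where all diagonals of `Gamma` were at least
#' `theta`. Whenever some diagonal converges (changes by less than `epsilon`)
#' to a value below `theta`, the snapshot is restored, the columns of the
#' snapshot rate matrix are randomly permuted across states, and training
#' resumes -- in effect drawing a fresh initial guess that preserves the
#' firing rates found so far. A result with `converged = TRUE` therefore
#' guarantees that every final self-transition probability is at least
#' `theta`; if the iteration budget is exhausted first, `converged = FALSE`.
#'
#' @param counts a `binned_counts` object.
#' @param init an [hmm_params()] whose `Gamma` diagonals are all `>= theta`
#'   (the standard random initialization guarantees this).
#' @param config a [sticky_config()].
#' @param fixed_pi,verbose as in [train_phmm()].
#' @return a `train_result`; `n_resets` counts snapshot restorations.
#' @export
train_sphmm <- function(counts, init, config = sticky_config(),
                        fixed_pi = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "sticky_config"))
  if (min(diag(init$Gamma)) < config$theta)
    stop("initial self-transition probabilities must all be >= theta")
  .train_poisson(counts, init, maxiter = config$maxiter, tol = config$tol,
                 sticky = config, fixed_pi = fixed_pi, verbose = verbose)
}

#' Self-transition threshold for a target mean state duration
#'
#' In a Markov chain observed at bin width `dt`, a state with self-transition
#' probability `gamma` dwells for a geometric number of bins with mean
#' `dt / (1 - gamma)`. Inverting this identity, enforcing a mean state
#' duration of at least `mean_duration` requires the threshold
#' `theta = 1 - dt / mean_duration`.
#'
#' @param dt bin width in seconds.
#' @param mean_duration target mean state duration in seconds (must exceed
#'   `dt`).
#' @return the threshold `theta` in (0, 1).
#' @examples
#' theta_for_duration(0.05, 0.25)  # 0.8
#' theta_for_duration(0.10, 0.25)  # 0.6
#' @export
theta_for_duration <- function(dt, mean_duration) {
  if (!(dt > 0) || !(dt < mean_duration))
    stop("'dt' must be positive and smaller than 'mean_duration'")
  1 - dt / mean_duration
}
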