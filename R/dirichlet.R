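#' Dirichlet prior on the transition rows
#'
#' An independent Dirichlet prior on each row of the transition matrix,
#' parameterized so that the prior mode has a chosen diagonal value. With
#' off-diagonal concentrations all equal to `a_bar` and a target diagonal
#' mode `gamma_bar`, the diagonal concentration follows from inverting the
#' Dirichlet mode formula:
#' `a_ii = 1 + gamma_bar * (m - 1) * (a_bar - 1) / (1 - gamma_bar)`.
#' At the defaults (`gamma_bar = 0.9`, `a_bar = 1.1`) this gives
#' `a_ii = 1 + 0.9 (m - 1)`, e.g. 4.6 for five states.
#'
#' @param m number of hidden states (at least 2).
#' @param gamma_bar target diagonal mode in (0, 1).
#' @param a_bar off-diagonal concentration, greater than 1.
#' @return object of class `dirichlet_prior` with the `m x m` concentration
#'   matrix `A`.
#' @export
dirichlet_prior <- function(m, gamma_bar = 0.9, a_bar = 1.1) {
  m <- as.integer(m)
  if (m < 2L) stop("'m' must be at least 2")
  if (!(gamma_bar > 0 && gamma_bar < 1))
    stop("'gamma_bar' must lie in (0, 1)")
  if (!(a_bar > 1)) stop("'a_bar' must exceed 1")
  a_ii <- 1 + gamma_bar * (m - 1) * (a_bar - 1) / (1 - gamma_bar)
  A <- matrix(a_bar, m, m)
  diag(A) <- a_ii
  structure(list(A = A, m = m, gamma_bar = gamma_bar, a_bar = a_bar),
            class = "dirichlet_prior")
}

#' Uninformative Dirichlet prior (all concentrations 1)
#'
#' Under this prior the maximum-a-posteriori transition update coincides with
#' the maximum-likelihood update and the log-posterior equals the
#' log-likelihood.
#'
#' @param m number of hidden states.
#' @return a `dirichlet_prior` with `A` all ones.
#' @export
flat_prior <- function(m) {
  structure(list(A = matrix(1, m, m), m = as.integer(m),
                 gamma_bar = NA_real_, a_bar = NA_real_),
            class = "dirichlet_prior")
}

#' Mode of a Dirichlet prior
#'
#' Row-wise mode `mu_ij = (a_ij - 1) / (sum_k a_ik - m)`, defined when every
#' concentration exceeds 1.
#'
#' @param prior a [dirichlet_prior()].
#' @return `m x m` matrix whose rows are the modal transition rows.
#' @export
prior_mode <- function(prior) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  if (any(prior$A <= 1))
    stop("the mode requires all concentration parameters > 1")
  den <- rowSums(prior$A) - prior$m
  if (any(den <= 0)) stop("degenerate prior: row concentration sum <= m")
  (prior$A - 1) / den
}

#' Maximum-a-posteriori transition update
#'
#' The Baum-Welch transition update with Dirichlet pseudo-counts:
#' `gamma_ij = [sum_t xi_ij(t) + a_ij - 1] / [sum_t q_i(t) + sum_j (a_ij - 1)]`,
#' with the sums pooled over trials. Rows sum to 1 by construction. With an
#' uninformative prior this is exactly the maximum-likelihood update.
#'
#' @param fb_per_trial list of [forward_backward()] results.
#' @param prior a [dirichlet_prior()].
#' @return the updated `m x m` transition matrix.
#' @export
map_transition_update <- function(fb_per_trial, prior) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  m <- prior$m
  num <- matrix(0, m, m); den <- numeric(m)
  for (fb in fb_per_trial) {
    Tk <- ncol(fb$q)
    if (Tk > 1L) {
      num <- num + fb$xi_sum
      den <- den + rowSums(fb$q[, -Tk, drop = FALSE])
    }
  }
  G <- sweep(num + prior$A - 1, 1L, den + rowSums(prior$A - 1), "/")
  G / rowSums(G)
}

#' Log-posterior of a Poisson-HMM under a Dirichlet transition prior
#'
#' `LP = LL + sum_ij (a_ij - 1) log gamma_ij`, omitting the normalizing
#' constant of the prior (a term that does not depend on the model
#' parameters, so comparisons at a fixed prior are unaffected). If some
#' `gamma_ij = 0` where `a_ij > 1`, the log-posterior is `-Inf`.
#'
#' @param loglik the data log-likelihood of the model.
#' @param Gamma the model's transition matrix.
#' @param prior a [dirichlet_prior()].
#' @return the (unnormalized) log-posterior, a scalar.
#' @export
log_posterior <- function(loglik, Gamma, prior) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  terms <- (prior$A - 1) * log(Gamma)
  terms[prior$A == 1] <- 0  # 0 * log(0) treated as 0 for flat entries
  lp <- loglik + sum(terms)
  if (is.nan(lp)) lp <- -Inf
  lp
}

#' Train a Poisson-HMM by maximum a posteriori (Dirichlet prior)
#'
#' Baum-Welch with the MAP transition update in place of the
#' maximum-likelihood one; the (unnormalized) log-posterior, rather than the
#' log-likelihood, is monitored for convergence and is non-decreasing across
#' iterations. With an uninformative prior the trajectory coincides with
#' [train_phmm()].
#'
#' @param counts a `binned_counts` object.
#' @param init an [hmm_params()] initial guess.
#' @param prior a [dirichlet_prior()]; defaults to the target-mode prior at
#'   `gamma_bar = 0.9`, `a_bar = 1.1`.
#' @param maxiter,tol,fixed_pi,verbose as in [train_phmm()].
#' @return a `train_result`; `loglik_trajectory` stores the log-posterior and
#'   `log_posterior` the final value.
#' @export
train_dphmm <- function(counts, init, prior = dirichlet_prior(init$m),
                        maxiter = 1000L, tol = c(1e-6, 1e-6),
                        fixed_pi = FALSE, verbose = FALSE) {
  stopifnot(inherits(prior, "dirichlet_prior"))
  if (prior$m != init$m) stop("prior and init disagree on m")
  .train_poisson(counts, init, maxiter = maxiter, tol = tol, prior = prior,
                 fixed_pi = fixed_pi, verbose = verbose)
}
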