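# Jonker-Volgenant shortest-augmenting-path solver for the square linear
# assignment problem; O(n^3). Returns, for each row, the assigned column.
.lsap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)       # row potentials (u[i + 1] for row i, u[1] virtual)
  v <- numeric(n + 1L)       # column potentials (v[j + 1], v[1] virtual col 0)
  p <- integer(n + 1L)       # p[j + 1] = row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Match the states of two models by firing-rate similarity
#'
#' One-to-one assignment (Hungarian algorithm) of the state columns of two
#' rate matrices minimizing the total Euclidean distance between matched
#' firing-rate vectors. When the models have different numbers of states,
#' `min(m1, m2)` pairs are matched and the surplus states of the larger model
#' are listed unmatched -- in an over-segmented fit these are typically
#' near-duplicates of already-matched states.
#'
#' @param lambda1,lambda2 `N x m1` and `N x m2` rate matrices (same `N`).
#' @return list with `pairs` (data frame `state1`, `state2`, `distance` in
#'   spikes/s), `unmatched1`, `unmatched2`, and `total_distance`.
#' @export
match_states <- function(lambda1, lambda2) {
  lambda1 <- as.matrix(lambda1); lambda2 <- as.matrix(lambda2)
  if (nrow(lambda1) != nrow(lambda2))
    stop("rate matrices must describe the same neurons")
  m1 <- ncol(lambda1); m2 <- ncol(lambda2)
  d <- matrix(0, m1, m2)
  for (i in seq_len(m1))
    for (j in seq_len(m2))
      d[i, j] <- sqrt(sum((lambda1[, i] - lambda2[, j])^2))
  n <- max(m1, m2)
  pad <- max(d) + 1
  cost <- matrix(pad, n, n)
  cost[seq_len(m1), seq_len(m2)] <- d
  a <- .lsap(cost)
  pairs <- data.frame(state1 = seq_len(m1), state2 = a[seq_len(m1)])
  pairs <- pairs[pairs$state2 <= m2 & pairs$state1 <= m1, , drop = FALSE]
  pairs$distance <- d[cbind(pairs$state1, pairs$state2)]
  pairs <- pairs[order(pairs$state1), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched1 = setdiff(seq_len(m1), pairs$state1),
       unmatched2 = setdiff(seq_len(m2), pairs$state2),
       total_distance = sum(pairs$distance))
}

#' Decoded squared-error distance of a model on data
#'
#' Decodes every bin by the maximum-posterior state (no undecided threshold)
#' and accumulates the squared difference between the observed spike count
#' and the decoded state's expected count `lambda * dt`, over all trials,
#' bins and neurons. This quantifies the residual variability of the data
#' under the model, combining the fitted firing-rate vectors with the
#' decoded state transitions; it should be evaluated on trials not used for
#' training.
#'
#' @param counts a `binned_counts` object (validation trials).
#' @param params an [hmm_params()].
#' @return the total squared error `D` (counts squared).
#' @export
model_distance <- function(counts, params) {
  stopifnot(inherits(counts, "binned_counts"), inherits(params, "hmm_params"))
  dec <- posterior_decode(counts, params, threshold = 0)
  D <- 0
  for (k in seq_along(counts$counts)) {
    f <- params$Lambda[, dec$states[[k]], drop = FALSE] * params$dt
    D <- D + sum((counts$counts[[k]] - f)^2)
  }
  D
}

#' Comparison index between two HMMs on shared data
#'
#' The ratio `rho = D(theta1) / D(theta2)` of the decoded squared-error
#' distances ([model_distance()]) of two models on the same validation data.
#' Models implying the same states, state transitions and transition times
#' give `rho` close to 1. When `theta2` is the model that generated the data,
#' `rho >= 1` is expected and the smallest `m` with `rho(m)` near 1 marks the
#' correct number of states.
#'
#' @param counts validation `binned_counts`.
#' @param theta1,theta2 fitted [hmm_params()] (by convention `theta2` is the
#'   reference/true model).
#' @return object of class `comparison_report`: `rho`, `D1`, `D2`, and the
#'   state `matching` between the two rate matrices.
#' @export
rho <- function(counts, theta1, theta2) {
  D1 <- model_distance(counts, theta1)
  D2 <- model_distance(counts, theta2)
  if (D2 == 0) stop("degenerate denominator: D(theta2) = 0")
  structure(list(rho = D1 / D2, D1 = D1, D2 = D2,
                 matching = match_states(theta1$Lambda, theta2$Lambda)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: rho = %.4f (D1 = %.1f, D2 = %.1f)\n",
              x$rho, x$D1, x$D2))
  invisible(x)
}

#' Shuffled null distribution for the comparison index
#'
#' Chance level for [rho()]: each shuffle randomly permutes the first model's
#' firing rates across states -- independently for each neuron, so every
#' neuron keeps its own set of rates but the composition of the state rate
#' vectors is destroyed -- and independently permutes the off-diagonal
#' entries within each row of its transition matrix (diagonals and row sums
#' preserved, so the shuffled matrix is still row-stochastic and keeps the
#' same dwell times), then recomputes `rho` against `theta2`. A pure
#' relabeling of intact state columns would leave the decoded squared error
#' nearly invariant (the decoder simply follows the relabeled states), so the
#' per-neuron shuffle is what gives the null its power. A genuinely matching
#' model sits in the left tail of this distribution.
#'
#' @inheritParams rho
#' @param n_shuffles number of shuffled models.
#' @param seed optional integer seed.
#' @return list with `rho_observed`, `rho_shuffled` (length `n_shuffles`),
#'   and `p_below`, the fraction of shuffles with `rho` at or below the
#'   observed value.
#' @export
shuffled_rho_null <- function(counts, theta1, theta2, n_shuffles = 100L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- rho(counts, theta1, theta2)$rho
  m <- theta1$m
  out <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    G <- theta1$Gamma
    if (m > 1L) {
      for (i in seq_len(m)) {
        off <- setdiff(seq_len(m), i)
        G[i, off] <- G[i, sample(off)]
      }
    }
    L <- if (m > 1L)
      t(apply(theta1$Lambda, 1L, function(r) r[sample.int(m)]))
    else theta1$Lambda
    shuf <- hmm_params(pi = theta1$pi, Gamma = G, Lambda = L, dt = theta1$dt)
    out[s] <- rho(counts, shuf, theta2)$rho
  }
  list(rho_observed = obs, rho_shuffled = out,
       p_below = mean(out <= obs))
}
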