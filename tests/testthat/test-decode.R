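tiny_counts <- function(K, dt = 0.05) {
  structure(list(counts = list(K), dt = dt, n_bins = ncol(K),
                 n_neurons = nrow(K)), class = "binned_counts")
}

test_that("posterior decoding applies the undecided-bin threshold", {
  p1 <- hmm_params(1, matrix(1), matrix(c(5, 10), 2, 1), dt = 0.05)
  cts <- tiny_counts(matrix(rpois(10, 0.5), 2, 5))
  d <- posterior_decode(cts, p1)
  expect_equal(d$states[[1]], rep(1L, 5))

  # symmetric two-state model with identical emissions: q = (0.5, 0.5)
  psym <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                     cbind(c(4, 4), c(4, 4)), dt = 0.05)
  cts2 <- tiny_counts(matrix(1L, 2, 4))
  expect_true(all(is.na(posterior_decode(cts2, psym, 0.8)$states[[1]])))
  low <- posterior_decode(cts2, psym, 0.4)$states[[1]]
  expect_true(all(!is.na(low)))
  # exact tie on a one-bin trial is broken toward the lowest state index
  cts1 <- tiny_counts(matrix(1L, 2, 1))
  expect_equal(posterior_decode(cts1, psym, 0.4)$states[[1]], 1L)

  # undecided count is monotone in the threshold
  tp <- hmm_params(rep(1 / 2, 2), random_sticky_gamma(2),
                   cbind(c(3, 14), c(12, 2)), dt = 0.05)
  sim <- sample_from_hmm(tp, 3, 150, seed = 61)
  n_und <- sapply(c(0, 0.5, 0.8, 0.95, 0.999), function(th)
    sum(is.na(unlist(posterior_decode(sim$counts, tp, th)$states))))
  expect_true(all(diff(n_und) >= 0))
})

test_that("decoding recovers the generating path of a sticky model", {
  G <- matrix(0.025, 3, 3); diag(G) <- 0.95
  Lam <- cbind(c(2, 2, 2, 2, 2, 2, 2, 2),
               c(12, 12, 12, 2, 2, 12, 12, 2),
               c(24, 2, 24, 24, 24, 2, 24, 24))
  tp <- hmm_params(rep(1 / 3, 3), G, Lam, dt = 0.05)
  sim <- sample_from_hmm(tp, 10, 200, seed = 7)
  dec <- posterior_decode(sim$counts, tp)
  hits <- unlist(Map(function(a, b) !is.na(a) & a == b,
                     dec$states, sim$states))
  expect_gt(mean(hits), 0.90)
})

test_that("Viterbi equals path enumeration and dominates posterior paths", {
  set.seed(71)
  p <- hmm_params(rep(1 / 2, 2), random_sticky_gamma(2, 0.6, 0.9),
                  cbind(c(3, 18, 7), c(15, 2, 22)), dt = 0.05)
  cts <- tiny_counts(matrix(rpois(15, 1), 3, 5))
  v <- viterbi_decode(cts, p)
  pst <- stationary_distribution(p$Gamma)
  or <- enum_forward_backward(poisson_log_emission(cts$counts[[1]], p),
                              p$Gamma, pst)
  expect_equal(v$states[[1]], unname(or$best_path))
  expect_equal(v$path_logp[1], or$best_logp)

  # Viterbi path log-probability >= that of the argmax-posterior path
  path_logp <- function(s, logB, G, pi) {
    lp <- log(pi[s[1]]) + logB[s[1], 1]
    for (t in 2:length(s)) lp <- lp + log(G[s[t - 1], s[t]]) + logB[s[t], t]
    lp
  }
  sim <- sample_from_hmm(p, 4, 80, seed = 72)
  for (k in 1:4) {
    ck <- tiny_counts(sim$counts$counts[[k]])
    logB <- poisson_log_emission(ck$counts[[1]], p)
    vp <- viterbi_decode(ck, p)
    pp <- posterior_decode(ck, p, threshold = 0)
    expect_gte(vp$path_logp[1] + 1e-9,
               path_logp(pp$states[[1]], logB, p$Gamma, pst))
  }

  # one-state model: constant path
  p1 <- hmm_params(1, matrix(1), matrix(c(5, 2), 2, 1), dt = 0.05)
  expect_equal(viterbi_decode(tiny_counts(matrix(0L, 2, 6)), p1)$states[[1]],
               rep(1L, 6))
})

test_that("the stationary distribution solves pi' Gamma = pi'", {
  G <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(stationary_distribution(G), c(2 / 3, 1 / 3))
  # doubly stochastic -> uniform
  Gd <- matrix(c(0.6, 0.3, 0.1, 0.3, 0.5, 0.2, 0.1, 0.2, 0.7), 3,
               byrow = TRUE)
  expect_equal(stationary_distribution(Gd), rep(1 / 3, 3))
  set.seed(73)
  for (m in c(2, 4, 6)) {
    G <- random_sticky_gamma(m, 0.7, 0.95)
    pi <- stationary_distribution(G)
    expect_lt(max(abs(drop(pi %*% G) - pi)), 1e-10)
    expect_equal(sum(pi), 1)
  }
})

test_that("decoding is invariant under simultaneous state relabeling", {
  tp <- hmm_params(rep(1 / 2, 2), random_sticky_gamma(2),
                   cbind(c(3, 20), c(15, 2)), dt = 0.05)
  sim <- sample_from_hmm(tp, 3, 100, seed = 74)
  perm <- c(2L, 1L)
  tp2 <- hmm_params(tp$pi[, perm, drop = FALSE],
                    tp$Gamma[perm, perm], tp$Lambda[, perm], dt = tp$dt)
  d1 <- posterior_decode(sim$counts, tp)
  d2 <- posterior_decode(sim$counts, tp2)
  relabel <- function(s) ifelse(is.na(s), NA_integer_, perm[s])
  expect_equal(lapply(d2$states, relabel), d1$states)
  v1 <- viterbi_decode(sim$counts, tp)
  v2 <- viterbi_decode(sim$counts, tp2)
  expect_equal(lapply(v2$states, relabel), v1$states)
})

test_that("state-1 initialization marks the burn-in window undecided", {
  tp <- hmm_params(rep(1 / 2, 2), random_sticky_gamma(2),
                   cbind(c(3, 20), c(15, 2)), dt = 0.05)
  sim <- sample_from_hmm(tp, 2, 100, seed = 75)
  d <- posterior_decode(sim$counts, tp, init = "state1", pre_roll = 0.4)
  expect_true(all(is.na(d$states[[1]][1:8])))
})
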