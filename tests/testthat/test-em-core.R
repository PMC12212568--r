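make_counts <- function(K_list, dt) {
  structure(list(counts = K_list, dt = dt,
                 n_bins = vapply(K_list, ncol, 1L),
                 n_neurons = nrow(K_list[[1]])),
            class = "binned_counts")
}

test_that("Poisson log emissions match the factorized pmf product", {
  p <- hmm_params(pi = c(0.5, 0.5),
                  Gamma = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                  Lambda = cbind(c(2, 8, 15), c(20, 1, 5)), dt = 0.05)
  # empty bin: entry i = -sum_n lambda_ni dt
  expect_equal(poisson_log_emission(c(0, 0, 0), p),
               -colSums(p$Lambda * p$dt))
  # single neuron, lambda dt = 1, k = 1 -> log(e^-1) = -1
  p1 <- hmm_params(1, matrix(1), matrix(20), dt = 0.05)
  expect_equal(poisson_log_emission(1L, p1), -1.0)
  # arbitrary instance vs dpois product
  set.seed(5)
  K <- matrix(rpois(30, 1.2), 3, 10)
  le <- poisson_log_emission(K, p)
  oracle <- sapply(seq_len(10), function(t)
    sapply(1:2, function(i)
      sum(dpois(K[, t], p$Lambda[, i] * p$dt, log = TRUE))))
  expect_lt(max(abs(le - oracle)), 1e-12)
})

test_that("forward-backward equals brute-force path enumeration", {
  set.seed(17)
  for (m in 2:3) {
    Gamma <- random_sticky_gamma(m, 0.6, 0.9)
    pi <- rep(1 / m, m)
    logB <- matrix(rnorm(m * 6, sd = 2), m, 6)
    fb <- forward_backward(logB, Gamma, pi)
    or <- enum_forward_backward(logB, Gamma, pi)
    expect_lt(max(abs(fb$q - or$q)), 1e-10)
    expect_lt(max(abs(fb$xi - or$xi)), 1e-10)
    expect_lt(abs(fb$loglik - or$loglik), 1e-10)
    # posterior normalization and marginalization of pairwise posteriors
    expect_lt(max(abs(colSums(fb$q) - 1)), 1e-8)
    marg <- apply(fb$xi, c(1, 3), sum)
    expect_lt(max(abs(marg - fb$q[, 1:5])), 1e-8)
  }
})

test_that("forward-backward handles single-state and uniform-emission cases", {
  logB <- matrix(c(-1.3, -0.2, -4.1), 1, 3)
  fb <- forward_backward(logB, matrix(1), 1)
  expect_equal(as.numeric(fb$q), c(1, 1, 1))
  expect_equal(fb$loglik, sum(logB))
  # identical emissions: posteriors come from the chain alone, and with a
  # symmetric doubly-stochastic chain plus uniform start they are uniform
  G <- matrix(c(0.7, 0.3, 0.3, 0.7), 2)
  fb2 <- forward_backward(matrix(-1, 2, 5), G, c(0.5, 0.5))
  expect_lt(max(abs(fb2$q - 0.5)), 1e-12)
})

test_that("the M-step reproduces hand-computed re-estimation formulae", {
  # degenerate posteriors: state 1 certain everywhere
  K <- rbind(c(2L, 0L, 4L), c(1L, 1L, 1L))
  counts <- make_counts(list(K), dt = 0.1)
  q <- rbind(rep(1, 3), rep(0, 3))
  xi <- array(0, c(2, 2, 2)); xi[1, 1, ] <- 1
  fb <- list(structure(list(q = q, xi = xi, xi_sum = apply(xi, 1:2, sum),
                            loglik = 0), class = "fb_result"))
  # the never-visited state triggers the collapse warning and floors rates
  expect_warning(up <- m_step(fb, counts), "never visited")
  expect_equal(up$Lambda[, 1], rowMeans(K) / 0.1)
  expect_equal(up$Gamma[1, ], c(1, 0))
  expect_equal(up$Lambda[, 2], c(0.001, 0.001))

  # soft posteriors on a 3-bin instance vs manual arithmetic
  q2 <- rbind(c(0.9, 0.4, 0.2), c(0.1, 0.6, 0.8))
  xi2 <- array(0, c(2, 2, 2))
  xi2[, , 1] <- rbind(c(0.35, 0.55), c(0.05, 0.05))
  xi2[, , 2] <- rbind(c(0.15, 0.25), c(0.05, 0.55))
  fb2 <- list(structure(list(q = q2, xi = xi2, xi_sum = apply(xi2, 1:2, sum),
                             loglik = 0), class = "fb_result"))
  up2 <- m_step(fb2, counts)
  expect_equal(up2$Gamma[1, ], c(0.5, 0.8) / 1.3)
  expect_equal(up2$Gamma[2, ], c(0.1, 0.6) / 0.7)
  lam11 <- sum(q2[1, ] * K[1, ]) / sum(q2[1, ]) / 0.1
  expect_equal(up2$Lambda[1, 1], lam11)
  expect_equal(as.numeric(up2$pi), as.numeric(q2[, 1]))

  # duplicated trials leave the ratio estimates unchanged
  up_dup <- m_step(c(fb2, fb2), make_counts(list(K, K), dt = 0.1))
  expect_equal(up_dup$Gamma, up2$Gamma)
  expect_equal(up_dup$Lambda, up2$Lambda)
})

test_that("PHMM training is monotone and recovers a one-state model", {
  set.seed(23)
  lam_true <- 7
  counts <- make_counts(lapply(1:4, function(k)
    matrix(rpois(500, lam_true * 0.05), 1, 500)), dt = 0.05)
  init <- hmm_params(1, matrix(1), matrix(3), dt = 0.05)
  fit <- train_phmm(counts, init)
  expect_true(fit$converged)
  emp <- sum(sapply(counts$counts, sum)) / (2000 * 0.05)
  se <- sqrt(emp / (2000 * 0.05))
  expect_lt(abs(fit$params$Lambda[1, 1] - emp), 1e-8)
  expect_lt(abs(emp - lam_true), 2 * se)
  # starting at the fixed point, convergence is immediate
  fit_fp <- train_phmm(counts, hmm_params(1, matrix(1), matrix(emp),
                                          dt = 0.05))
  expect_true(fit_fp$converged)
  expect_lte(fit_fp$n_iterations, 2L)

  # monotone likelihood trajectory on a harder instance
  set.seed(31)
  tp <- hmm_params(rep(1 / 2, 2), random_sticky_gamma(2),
                   cbind(c(3, 20, 8), c(15, 2, 25)), dt = 0.05)
  sim <- sample_from_hmm(tp, 5, 120, seed = 3)
  init2 <- random_init(sim$counts, 2, seed = 9)
  fit2 <- train_phmm(sim$counts, init2, maxiter = 200)
  d <- diff(fit2$loglik_trajectory)
  expect_true(all(d >= -1e-8 * pmax(1, abs(fit2$loglik_trajectory[-1]))))
})

test_that("PHMM recovers MMPP rates after Hungarian matching", {
  spec <- random_mmpp_spec(3, 10, n_trials = 20, trial_duration = 14,
                           diag_range = c(0.85, 0.97), seed = 101)
  sim <- generate_mmpp(spec, seed = 102)
  counts <- bin_spikes(sim$dataset, 0.05)
  fits <- lapply(1:8, function(g)
    suppressWarnings(  # some inits transiently collapse a state
      train_phmm(counts, random_init(counts, 3, seed = 200 + g),
                 maxiter = 500)))
  best <- fits[[which.max(vapply(fits, `[[`, 1, "loglik"))]]
  mt <- match_states(best$params$Lambda, spec$Lambda)
  mae <- mean(abs(best$params$Lambda[, mt$pairs$state1] -
                    spec$Lambda[, mt$pairs$state2]))
  expect_lt(mae, 1)
})
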