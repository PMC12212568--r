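test_that("random MMPP specifications respect their sampling laws", {
  s1 <- random_mmpp_spec(4, 10, seed = 1)
  expect_lt(max(abs(rowSums(s1$Gamma) - 1)), 1e-12)
  expect_true(all(diag(s1$Gamma) >= 0.8 & diag(s1$Gamma) <= 1))
  expect_true(all(s1$Lambda >= 0 & s1$Lambda <= 30))
  expect_equal(s1$n_trials, 50L)
  expect_equal(s1$trial_duration, 14)
  s2 <- random_mmpp_spec(4, 10, seed = 1)
  expect_identical(s1, s2)  # seeded determinism
  expect_error(random_mmpp_spec(1, 5), "at least 2")
})

test_that("single-state MMPP is a homogeneous Poisson ensemble", {
  spec <- mmpp_spec(matrix(1), matrix(c(4, 12, 25), 3, 1), n_trials = 6,
                    trial_duration = 20)
  sim <- suppressWarnings(generate_mmpp(spec, seed = 2))
  total_t <- 6 * 20
  for (n in 1:3) {
    cnt <- sum(vapply(sim$dataset$trials, function(tr)
      sum(tr$neuron == n), 1L))
    se <- sqrt(spec$Lambda[n, 1] * total_t)
    expect_lt(abs(cnt - spec$Lambda[n, 1] * total_t), 3 * se)
  }
})

test_that("Gillespie dwell times are exponential with mean dt/(1 - gamma)", {
  G <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  spec <- mmpp_spec(G, cbind(c(5, 5), c(5, 5)), dt_ref = 0.05,
                    n_trials = 60, trial_duration = 25)
  sim <- generate_mmpp(spec, seed = 3)
  # interior dwells only (first and last segments are censored)
  p <- sim$paths
  dw <- unlist(lapply(split(p, p$trial), function(pk) {
    d <- pk$end_s - pk$start_s
    if (length(d) > 2) d[2:(length(d) - 1)] else numeric(0)
  }))
  expect_gt(length(dw), 2000)
  expect_lt(abs(mean(dw) - 0.5) / 0.5, 0.05)
  ks <- ks.test(dw, "pexp", rate = 1 / 0.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("within-state binned counts are Poisson-dispersed", {
  G <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
  spec <- mmpp_spec(G, cbind(c(10, 20), c(20, 10)), n_trials = 30,
                    trial_duration = 12)
  sim <- generate_mmpp(spec, seed = 4)
  counts <- bin_spikes(sim$dataset, 0.05)
  truth <- states_per_bin(sim$paths, 0.05, counts$n_bins)
  # bins fully inside a state-1 dwell, neuron 1 (rate 10)
  x <- unlist(lapply(seq_along(truth), function(k) {
    s <- truth[[k]]
    inside <- s == 1 & c(FALSE, s[-length(s)] == 1) &
      c(s[-1] == 1, FALSE)
    counts$counts[[k]][1, inside]
  }))
  expect_gt(length(x), 2000)
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)
})

test_that("random initial guesses follow the prescribed construction", {
  spec <- random_mmpp_spec(3, 8, n_trials = 4, trial_duration = 5, seed = 5)
  counts <- bin_spikes(generate_mmpp(spec, seed = 6)$dataset, 0.05)
  init <- random_init(counts, 4, seed = 7)
  expect_lt(max(abs(rowSums(init$Gamma) - 1)), 1e-12)
  # theta I + (1 - theta) U with row-normalized U keeps diagonals >= theta
  expect_true(all(diag(init$Gamma) >= 0.8))
  expect_equal(as.numeric(init$pi), rep(0.25, 4))
  # rates within the empirical per-neuron range
  tot <- rowSums(do.call(cbind, counts$counts))
  emp <- tot / (sum(counts$n_bins) * counts$dt)
  expect_true(all(init$Lambda >= min(emp) & init$Lambda <= max(emp)))
  expect_identical(random_init(counts, 4, seed = 7), init)
  expect_equal(random_init(counts, 1, seed = 8)$Gamma, matrix(1))

  syms <- encode_symbols(bin_spikes(generate_mmpp(spec, seed = 6)$dataset,
                                    0.005), seed = 9)
  mi <- random_init(syms, 3, "mhmm", seed = 10)
  expect_true(all(diag(mi$Gamma) >= 0.9))
  expect_true(all(mi$E[, 9] >= 0.95))  # no-spike symbol carries the mass
  expect_equal(as.numeric(mi$pi), c(1, 0, 0))
})

test_that("shuffle controls obey their conservation laws", {
  spec <- random_mmpp_spec(3, 6, n_trials = 5, trial_duration = 8, seed = 11)
  sim <- generate_mmpp(spec, seed = 12)
  shuf <- circular_shuffle(sim$dataset, seed = 13)
  # per-trial, per-neuron spike counts preserved exactly
  for (k in 1:5) {
    expect_equal(table(factor(shuf$trials[[k]]$neuron, levels = 1:6)),
                 table(factor(sim$dataset$trials[[k]]$neuron, levels = 1:6)))
  }
  counts <- bin_spikes(sim$dataset, 0.05)
  sw <- swap_shuffle(counts, seed = 14)
  # multiset of count vectors preserved per trial
  for (k in 1:5) {
    a <- apply(counts$counts[[k]], 2, paste, collapse = ",")
    b <- apply(sw$counts[[k]], 2, paste, collapse = ",")
    expect_equal(sort(a), sort(b))
  }
  # circular shuffling destroys the fitted sticky structure far less than
  # swap shuffling destroys dwell structure -- both must differ from source
  expect_false(identical(counts$counts, sw$counts))
})

test_that("the LIF integrator matches closed-form single-neuron dynamics", {
  # leak only: no input, no recurrence -> no spikes
  cfg0 <- snn_config(n_e = 1L, n_i = 0L, duration = 0.3,
                     p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
                     i_ext_e = 0, q_clusters = 1L, f_clustered = 1)
  out0 <- simulate_snn(cfg0, seed = 21, record = 1L)
  expect_equal(nrow(out0$dataset$trials[[1]]), 0L)

  # suprathreshold constant drive: ISI equals the analytic LIF period
  cfg1 <- snn_config(n_e = 1L, n_i = 0L, duration = 1.5,
                     p_ee = 0, p_ei = 0, p_ie = 0, p_ii = 0,
                     q_clusters = 1L, f_clustered = 1)
  out1 <- simulate_snn(cfg1, seed = 22, record = 1L)
  st <- out1$dataset$trials[[1]]$time_s
  expect_gt(length(st), 10)
  isi <- diff(st)
  v_inf <- -60 + 0.020 * (0.3217 / 1) * 1e3  # mV
  t_star <- 0.020 * log((v_inf + 60) / (v_inf + 55))
  expect_lt(abs(median(isi) - (t_star + 0.005)) / (t_star + 0.005), 0.01)
})

test_that("the clustered network shows metastable cluster switching", {
  cfg <- snn_config(duration = 3)
  csize <- 360L
  record <- as.integer(outer(0:39, (0:4) * csize, "+") + 1L)
  out <- simulate_snn(cfg, seed = 23, record = record)
  tr <- out$dataset$trials[[1]]
  cl <- out$cluster
  # cluster-averaged rates in 100 ms windows
  win <- 0.1
  nb <- floor(cfg$duration / win)
  rates <- sapply(1:5, function(c) {
    idx <- which(cl == c)
    h <- hist(tr$time_s[tr$neuron %in% idx],
              breaks = seq(0, nb * win, by = win), plot = FALSE)
    h$counts / (length(idx) * win)
  })
  expect_gt(sum(rates), 0)
  # at least 2 of the recorded clusters alternate between high (> 15
  # spikes/s) and low (< 5 spikes/s) epochs
  alternates <- colSums(rates > 15) > 0 & colSums(rates < 5) > 0
  expect_gte(sum(alternates), 2)
})
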