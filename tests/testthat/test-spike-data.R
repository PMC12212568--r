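test_that("bin_spikes places spikes in half-open bins and conserves counts", {
  ds <- toy_dataset(list(list(neuron = 1L, time_s = 0.07)), 1L, 1.0)
  b <- bin_spikes(ds, 0.05)
  expect_equal(b$counts[[1]][1, 2], 1L)
  expect_equal(sum(b$counts[[1]]), 1L)

  empty <- toy_dataset(list(list(neuron = integer(0), time_s = numeric(0))),
                       3L, 2.0)
  expect_true(all(bin_spikes(empty, 0.1)$counts[[1]] == 0L))

  # conservation against a direct histogram when duration is a multiple of dt
  set.seed(11)
  tt <- runif(1000, 0, 2)
  ds2 <- toy_dataset(list(list(neuron = rep(1L, 1000), time_s = tt)), 1L, 2.0)
  b2 <- bin_spikes(ds2, 0.05)
  expect_equal(sum(b2$counts[[1]]), 1000L)
  h <- hist(tt, breaks = seq(0, 2, by = 0.05), plot = FALSE, right = FALSE)
  expect_equal(as.integer(b2$counts[[1]][1, ]), h$counts)

  expect_error(bin_spikes(ds, 0), "positive")
})

test_that("the silent-neuron filter uses the strict peak-rate rule", {
  # at dt = 1 s, peak binned rates are 1, 1, 30 -> threshold 1 keeps all
  b <- structure(list(counts = list(rbind(c(0L, 1L), c(1L, 1L), c(30L, 2L))),
                      dt = 1, n_bins = 2L, n_neurons = 3L),
                 class = "binned_counts")
  expect_equal(filter_silent_neurons(b, 1)$kept, c(1L, 2L, 3L))

  # at dt = 2 s, peaks 0.5, 1.0, 30: strictly-below-1 neuron is dropped,
  # the exactly-1 neuron is retained
  b2 <- structure(list(counts = list(rbind(c(1L, 0L), c(2L, 1L),
                                           c(60L, 5L))),
                       dt = 2, n_bins = 2L, n_neurons = 3L),
                  class = "binned_counts")
  f <- filter_silent_neurons(b2, 1)
  expect_equal(f$kept, c(2L, 3L))
  expect_equal(f$binned$n_neurons, 2L)

  # zero-spike neuron always removed; single spike at dt = 0.05 retained
  bz <- structure(list(counts = list(rbind(rep(0L, 10), c(1L, rep(0L, 9)))),
                       dt = 0.05, n_bins = 10L, n_neurons = 2L),
                  class = "binned_counts")
  expect_equal(filter_silent_neurons(bz)$kept, 2L)
  bz$counts[[1]][2, ] <- 0L
  expect_error(filter_silent_neurons(bz), "threshold")
})

test_that("symbol encoding maps single/empty/multi-spike bins correctly", {
  K <- cbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(1L, 1L, 0L))
  b <- structure(list(counts = list(K), dt = 0.005, n_bins = 3L,
                      n_neurons = 3L), class = "binned_counts")
  s <- encode_symbols(b, seed = 1)$symbols[[1]]
  expect_equal(s[1], 4L)          # no spikes -> N + 1
  expect_equal(s[2], 2L)          # multiplicity collapses to one symbol
  expect_true(s[3] %in% c(1L, 2L))

  # collision tie-break is uniform across seeds
  draws <- vapply(1:2000, function(g)
    encode_symbols(b, seed = g)$symbols[[1]][3], integer(1))
  expect_gt(mean(draws == 1L), 0.5 - 0.05)
  expect_lt(mean(draws == 1L), 0.5 + 0.05)

  # deterministic for single-spike bins regardless of seed
  expect_equal(encode_symbols(b, seed = 5)$symbols[[1]][1:2],
               encode_symbols(b, seed = 99)$symbols[[1]][1:2])

  bwide <- b; bwide$dt <- 0.05
  expect_warning(encode_symbols(bwide, seed = 1), "10 ms")
})

test_that("spike and parameter files round-trip exactly", {
  set.seed(3)
  ds <- toy_dataset(list(list(neuron = sample(1:4, 20, TRUE),
                              time_s = sort(runif(20, 0, 3))),
                         list(neuron = integer(0), time_s = numeric(0))),
                    4L, c(3, 2.5))
  f <- tempfile(fileext = ".csv")
  write_spikes(ds, f)
  back <- read_spikes(f)
  expect_equal(back$n_neurons, ds$n_neurons)
  expect_equal(back$trial_duration, ds$trial_duration)
  expect_equal(back$trials, ds$trials)

  p <- hmm_params(pi = c(0.25, 0.75),
                  Gamma = matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE),
                  Lambda = matrix(runif(6, 0, 30), 3, 2), dt = 0.05)
  fp <- tempfile()
  write_hmm_params(p, fp)
  q <- read_hmm_params(fp)
  expect_equal(q$Gamma, p$Gamma)
  expect_equal(q$Lambda, p$Lambda)
  expect_equal(as.numeric(q$pi), as.numeric(p$pi))
  expect_equal(q$dt, p$dt)

  mp <- mhmm_params(pi = c(1, 0), Gamma = p$Gamma,
                    E = rbind(c(0.01, 0.02, 0.97), c(0.05, 0.05, 0.9)),
                    dt = 0.005)
  write_hmm_params(mp, fp)
  mq <- read_hmm_params(fp)
  expect_s3_class(mq, "mhmm_params")
  expect_equal(mq$E, mp$E)
})

test_that("dataset constructors validate their invariants", {
  expect_error(spike_dataset(list(), 3, 1), "non-empty")
  expect_error(spike_dataset(list(data.frame(neuron = 5L, time_s = 0.1)),
                             3, 1), "neuron indices")
  expect_error(spike_dataset(list(data.frame(neuron = 1L, time_s = 1.0)),
                             3, 1), "trial_duration")
})
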