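#' Spike dataset container
#'
#' Bundles per-trial spike times for an ensemble of simultaneously recorded
#' neurons. Each trial is a data frame with columns `neuron` (integer in
#' `1:n_neurons`) and `time_s` (seconds from trial onset, in `[0,
#' trial_duration)`). Trial durations may differ across trials.
#'
#' @param trials list of data frames, one per trial, each with columns
#'   `neuron` and `time_s`.
#' @param n_neurons number of neurons `N` in the ensemble.
#' @param trial_duration numeric vector of trial durations in seconds
#'   (recycled to the number of trials).
#' @return an object of class `spike_dataset`.
#' @export
spike_dataset <- function(trials, n_neurons, trial_duration) {
  if (length(trials) == 0L) stop("'trials' must be non-empty")
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) stop("'n_neurons' must be positive")
  trial_duration <- rep_len(as.numeric(trial_duration), length(trials))
  trials <- lapply(seq_along(trials), function(k) {
    tr <- as.data.frame(trials[[k]])
    if (!all(c("neuron", "time_s") %in% names(tr)))
      stop("each trial needs columns 'neuron' and 'time_s'")
    tr <- tr[order(tr$time_s), c("neuron", "time_s"), drop = FALSE]
    tr$neuron <- as.integer(tr$neuron)
    if (nrow(tr) > 0L) {
      if (any(tr$neuron < 1L | tr$neuron > n_neurons))
        stop("neuron indices must lie in [1, n_neurons]")
      if (any(tr$time_s < 0 | tr$time_s >= trial_duration[k]))
        stop("spike times must lie in [0, trial_duration)")
    }
    rownames(tr) <- NULL
    tr
  })
  structure(list(trials = trials, n_neurons = n_neurons,
                 trial_duration = trial_duration),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("spike_dataset: %d trials, %d neurons, %.3g s mean duration, %d spikes\n",
              length(x$trials), x$n_neurons, mean(x$trial_duration),
              sum(vapply(x$trials, nrow, 1L))))
  invisible(x)
}

#' Bin spike times into count matrices
#'
#' Discretizes each trial into half-open bins `[t*dt, (t+1)*dt)` (0-based bin
#' index `t`) and counts the spikes of each neuron per bin. Spikes at or
#' beyond `n_bins * dt` are dropped, where `n_bins = floor(trial_duration /
#' dt)`.
#'
#' @param dataset a [spike_dataset()].
#' @param dt bin width in seconds (the customary choice for Poisson models
#'   is 0.05 s).
#' @return an object of class `binned_counts`: a list with `counts` (list of
#'   `n_neurons x n_bins` integer matrices, one per trial), `dt`, `n_bins`
#'   (per trial), and `n_neurons`.
#' @export
bin_spikes <- function(dataset, dt) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive scalar")
  n_bins <- as.integer(floor(dataset$trial_duration / dt))
  counts <- lapply(seq_along(dataset$trials), function(k) {
    tr <- dataset$trials[[k]]
    Tk <- n_bins[k]
    K <- matrix(0L, dataset$n_neurons, Tk)
    if (nrow(tr) > 0L && Tk > 0L) {
      b <- floor(tr$time_s / dt) + 1
      keep <- b <= Tk
      if (any(keep)) {
        tab <- table(factor(tr$neuron[keep], levels = seq_len(dataset$n_neurons)),
                     factor(b[keep], levels = seq_len(Tk)))
        K <- matrix(as.integer(tab), dataset$n_neurons, Tk)
      }
    }
    K
  })
  structure(list(counts = counts, dt = dt, n_bins = n_bins,
                 n_neurons = dataset$n_neurons),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("binned_counts: %d trials, %d neurons, dt = %g s, %d total bins\n",
              length(x$counts), x$n_neurons, x$dt, sum(x$n_bins)))
  invisible(x)
}

#' Remove silent neurons
#'
#' Drops neurons whose peak binned firing rate -- the maximum over all trials
#' and bins of `count / dt` -- is strictly below `min_rate`. This mirrors the
#' usual preprocessing step of excluding neurons with peak firing rate lower
#' than 1 spikes/s before HMM training.
#'
#' @param binned a [bin_spikes()] result.
#' @param min_rate threshold in spikes/s; a neuron is kept iff its peak rate
#'   is `>= min_rate`.
#' @return list with `binned` (filtered counts) and `kept` (original indices
#'   of retained neurons).
#' @export
filter_silent_neurons <- function(binned, min_rate = 1.0) {
  stopifnot(inherits(binned, "binned_counts"))
  peak <- apply(do.call(cbind, binned$counts), 1L, max) / binned$dt
  kept <- which(peak >= min_rate)
  if (length(kept) == 0L)
    stop("all neurons fall below the peak-rate threshold")
  out <- binned
  out$counts <- lapply(binned$counts, function(K) K[kept, , drop = FALSE])
  out$n_neurons <- length(kept)
  list(binned = out, kept = kept)
}

#' Encode binned counts as categorical symbols
#'
#' Maps each bin to one of `N + 1` symbols for the Multinoulli model: symbol
#' `n <= N` when neuron `n` is the (single) firing neuron, symbol `N + 1`
#' when no neuron fires. Bins where several neurons fire are assigned to one
#' of the firing neurons uniformly at random, so the bin width should be
#' short enough (a few ms) that such collisions are rare; a warning is issued
#' above 10 ms.
#'
#' @param binned a [bin_spikes()] result, ideally at `dt <= 0.01` s.
#' @param seed optional integer seed for the collision tie-breaks.
#' @return object of class `symbol_sequence`: list with `symbols` (list of
#'   integer vectors per trial, values in `1:(N+1)`), `dt`, `n_neurons`.
#' @export
encode_symbols <- function(binned, seed = NULL) {
  stopifnot(inherits(binned, "binned_counts"))
  if (binned$dt > 0.01)
    warning("bin width above 10 ms: the single-spike symbol encoding is unreliable")
  if (!is.null(seed)) set.seed(seed)
  N <- binned$n_neurons
  symbols <- lapply(binned$counts, function(K) {
    s <- integer(ncol(K))
    for (t in seq_len(ncol(K))) {
      firing <- which(K[, t] > 0L)
      s[t] <- if (length(firing) == 0L) N + 1L
              else if (length(firing) == 1L) firing
              else firing[sample.int(length(firing), 1L)]
    }
    s
  })
  structure(list(symbols = symbols, dt = binned$dt, n_neurons = N),
            class = "symbol_sequence")
}

#' Read and write spike datasets as delimited text
#'
#' The on-disk format is a CSV with header `trial,neuron,time_s` (times in
#' seconds) preceded by comment lines `# n_neurons: N` and
#' `# trial_duration: d1 d2 ...` carrying the metadata, so a round trip
#' preserves the dataset exactly, including empty trials.
#'
#' @param dataset a [spike_dataset()].
#' @param path file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns a
#'   `spike_dataset`.
#' @export
write_spikes <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_neurons: %d", dataset$n_neurons),
               sprintf("# trial_duration: %s",
                       paste(format(dataset$trial_duration, digits = 17),
                             collapse = " ")),
               "trial,neuron,time_s"), con)
  for (k in seq_along(dataset$trials)) {
    tr <- dataset$trials[[k]]
    if (nrow(tr) > 0L)
      writeLines(sprintf("%d,%d,%s", k, tr$neuron,
                         format(tr$time_s, digits = 17)), con)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  hdr <- readLines(path, n = 2L)
  n_neurons <- as.integer(sub("# n_neurons: *", "", hdr[1L]))
  dur <- as.numeric(strsplit(sub("# trial_duration: *", "", hdr[2L]),
                             " +")[[1L]])
  df <- utils::read.csv(path, comment.char = "#")
  trials <- lapply(seq_along(dur), function(k) {
    df[df$trial == k, c("neuron", "time_s"), drop = FALSE]
  })
  spike_dataset(trials, n_neurons = n_neurons, trial_duration = dur)
}

#' Read and write HMM parameter files
#'
#' Structured plain text storing `m`, `N`, `dt`, the initial distribution, the
#' transition matrix and the rate (or emission) matrix at full precision.
#'
#' @param params an `hmm_params` or `mhmm_params` object.
#' @param path file path.
#' @export
write_hmm_params <- function(params, path) {
  is_m <- inherits(params, "mhmm_params")
  stopifnot(is_m || inherits(params, "hmm_params"))
  emis <- if (is_m) params$E else params$Lambda
  lines <- c(sprintf("# kind: %s", if (is_m) "mhmm" else "poisson"),
             sprintf("# m: %d", params$m),
             sprintf("# N: %d", params$N),
             sprintf("# dt: %s", format(params$dt, digits = 17)),
             sprintf("# pi_rows: %d", nrow(params$pi)),
             "# pi:",
             apply(params$pi, 1L, function(r)
               paste(format(r, digits = 17), collapse = " ")),
             "# Gamma:",
             apply(params$Gamma, 1L, function(r)
               paste(format(r, digits = 17), collapse = " ")),
             if (is_m) "# E:" else "# Lambda:",
             apply(emis, 1L, function(r)
               paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  ln <- readLines(path)
  val <- function(key) sub(sprintf("# %s: *", key), "",
                           grep(sprintf("^# %s:", key), ln, value = TRUE)[1L])
  kind <- val("kind")
  m <- as.integer(val("m")); N <- as.integer(val("N"))
  dt <- as.numeric(val("dt"))
  n_pi <- as.integer(val("pi_rows"))
  pstart <- grep("^# pi:$", ln) + 1L
  pi <- do.call(rbind, lapply(ln[pstart:(pstart + n_pi - 1L)], function(r)
    as.numeric(strsplit(trimws(r), " +")[[1L]])))
  gstart <- grep("^# Gamma:$", ln) + 1L
  Gamma <- do.call(rbind, lapply(ln[gstart:(gstart + m - 1L)], function(r)
    as.numeric(strsplit(trimws(r), " +")[[1L]])))
  estart <- grep(if (kind == "mhmm") "^# E:$" else "^# Lambda:$", ln) + 1L
  nrow_e <- if (kind == "mhmm") m else N
  emis <- do.call(rbind, lapply(ln[estart:(estart + nrow_e - 1L)], function(r)
    as.numeric(strsplit(trimws(r), " +")[[1L]])))
  if (kind == "mhmm") mhmm_params(pi = pi, Gamma = Gamma, E = emis, dt = dt)
  else hmm_params(pi = pi, Gamma = Gamma, Lambda = emis, dt = dt)
}
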