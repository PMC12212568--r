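#' Rapid-state-switching demonstration
#'
#' Generates an MMPP dataset with long-dwell states, fits the vanilla
#' Poisson-HMM at a deliberately inflated number of states and the sticky
#' model at its BIC-selected number of states, and counts decoded state
#' segments shorter than `short_ms` milliseconds for each model. Converged
#' sticky fits cannot produce sub-threshold self-transitions, so their
#' decoded segments are long; the inflated vanilla fit typically converges
#' with at least one low self-transition probability and rapid switching.
#'
#' @param seed integer seed (the whole report is a deterministic function of
#'   it).
#' @param true_m,n_neurons,n_trials,trial_duration ground-truth dataset
#'   shape.
#' @param inflated_m number of states for the deliberately overfit vanilla
#'   model.
#' @param n_inits random initial guesses per model.
#' @param m_values candidates for the sticky BIC selection.
#' @param dt bin width in seconds.
#' @param short_ms segment-length cutoff in milliseconds.
#' @return list with per-model short-segment counts, minimum self-transition
#'   probabilities, and the underlying fits.
#' @export
run_switching_demo <- function(seed = 1L, true_m = 3L, n_neurons = 10L,
                               n_trials = 20L, trial_duration = 14,
                               inflated_m = 8L, n_inits = 10L,
                               m_values = 2:5, dt = 0.05, short_ms = 100) {
  spec <- random_mmpp_spec(true_m, n_neurons, n_trials, trial_duration,
                           diag_range = c(0.9, 0.98), seed = seed)
  sim <- generate_mmpp(spec, seed = seed + 1L)
  counts <- bin_spikes(sim$dataset, dt)

  seg_lengths <- function(states) {
    unlist(lapply(states, function(s) {
      s <- s[!is.na(s)]
      if (!length(s)) return(numeric(0))
      rle(s)$lengths * dt
    }))
  }
  count_short <- function(params) {
    dec <- posterior_decode(counts, params, threshold = 0)
    sum(seg_lengths(dec$states) < short_ms / 1000)
  }

  phmm_fits <- lapply(seq_len(n_inits), function(g)
    .fit_one(counts, inflated_m, "phmm", seed + 100L + g))
  phmm_conv <- Filter(function(f) f$converged, phmm_fits)
  phmm_best <- phmm_fits[[which.max(vapply(phmm_fits, `[[`, 1, "loglik"))]]

  sel <- select_best(counts, "sphmm", m_values, criterion = "bic",
                     n_inits = n_inits, seed = seed + 500L)

  list(seed = seed, true_m = true_m,
       phmm = list(m = inflated_m,
                   n_converged = length(phmm_conv),
                   min_self_transition = vapply(phmm_fits, `[[`, 1,
                                                "min_self_transition"),
                   n_short_segments = count_short(phmm_best$params)),
       sphmm = list(m_star = sel$m_star,
                    min_self_transition = sel$best_fit$min_self_transition,
                    n_short_segments = count_short(sel$best_fit$params),
                    table = sel$table),
       counts = counts)
}

#' Model-selection sweep on ground-truth datasets
#'
#' Generates random MMPP datasets over a grid of true state counts, runs the
#' sticky model with every selection criterion, and tabulates inferred vs.
#' true `m`. Optionally repeats the BIC selection on circular- and
#' swap-shuffled versions of each dataset as controls.
#'
#' @param true_m_values vector of ground-truth state counts.
#' @param n_datasets datasets per true `m`.
#' @param n_neurons,n_trials,trial_duration dataset shape.
#' @param n_inits random initial guesses per candidate `m`.
#' @param m_margin candidates range from 2 to `true_m + m_margin`.
#' @param dt bin width (s).
#' @param seed integer seed.
#' @param criteria selection criteria to tabulate.
#' @param shuffles run the shuffle controls (`"circular"`, `"swap"`).
#' @return data frame with one row per dataset x criterion (columns
#'   `true_m`, `dataset`, `criterion`, `m_star`, `data`), plus attribute
#'   `"swap_convergences"` when the swap control runs.
#' @export
run_selection_sweep <- function(true_m_values = 2:5, n_datasets = 2L,
                                n_neurons = 20L, n_trials = 15L,
                                trial_duration = 10, n_inits = 10L,
                                m_margin = 2L, dt = 0.05, seed = 1L,
                                criteria = c("bic", "aic", "cv_max",
                                             "cv_slope", "cv_1sd"),
                                shuffles = character(0)) {
  rows <- list()
  swap_conv <- 0L; swap_fits <- 0L
  for (tm in true_m_values) {
    for (d in seq_len(n_datasets)) {
      ds_seed <- seed + 1000L * tm + d
      spec <- random_mmpp_spec(tm, n_neurons, n_trials, trial_duration,
                               seed = ds_seed)
      sim <- generate_mmpp(spec, seed = ds_seed + 1L)
      counts <- bin_spikes(sim$dataset, dt)
      m_values <- 2:(tm + m_margin)
      cv_rep <- NULL
      for (cr in criteria) {
        m_star <- if (startsWith(cr, "cv")) {
          if (is.null(cv_rep))
            cv_rep <- cross_validate(counts, "sphmm", m_values,
                                     n_folds = 5L, n_inits = n_inits,
                                     seed = ds_seed)
          rule <- c(cv_max = "max", cv_slope = "slope",
                    cv_1sd = "one_sd")[cr]
          tryCatch(pick_cv(cv_rep, rule), error = function(e) NA_integer_)
        } else {
          sel <- tryCatch(
            select_best(counts, "sphmm", m_values, criterion = cr,
                        n_inits = n_inits, seed = ds_seed),
            error = function(e) NULL)
          if (is.null(sel)) NA_integer_ else sel$m_star
        }
        rows[[length(rows) + 1L]] <- data.frame(
          true_m = tm, dataset = d, criterion = cr, m_star = m_star,
          data = "original")
      }
      if ("circular" %in% shuffles) {
        cshuf <- bin_spikes(circular_shuffle(sim$dataset,
                                             seed = ds_seed + 2L), dt)
        sel <- tryCatch(
          select_best(cshuf, "sphmm", m_values, criterion = "bic",
                      n_inits = n_inits, seed = ds_seed),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          true_m = tm, dataset = d, criterion = "bic",
          m_star = if (is.null(sel)) NA_integer_ else sel$m_star,
          data = "circular")
      }
      if ("swap" %in% shuffles) {
        sshuf <- swap_shuffle(counts, seed = ds_seed + 3L)
        for (m in m_values) {
          for (g in seq_len(n_inits)) {
            fit <- .fit_one(sshuf, m, "sphmm", ds_seed + 7919L * m + g)
            swap_fits <- swap_fits + 1L
            if (fit$converged) swap_conv <- swap_conv + 1L
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if ("swap" %in% shuffles)
    attr(out, "swap_convergences") <- c(converged = swap_conv,
                                        fits = swap_fits)
  out
}

#' Robustness of the selected model to the initial-guess pool size
#'
#' Compares the BIC-selected number of states obtained from small pools of
#' random initial guesses against a large-pool reference on MMPP data,
#' reporting the mismatch `m* - M*` per replicate pool.
#'
#' @param pool_sizes initial-guess pool sizes to test.
#' @param reference_pool pool size of the reference selection.
#' @param n_replicates replicate pools per size.
#' @param true_m,n_neurons,n_trials,trial_duration,dt dataset shape.
#' @param seed integer seed.
#' @return data frame with columns `pool_size`, `replicate`, `m_star`,
#'   `reference_m`, `mismatch`.
#' @export
run_init_robustness <- function(pool_sizes = c(5L, 10L, 25L),
                                reference_pool = 50L, n_replicates = 3L,
                                true_m = 3L, n_neurons = 20L, n_trials = 15L,
                                trial_duration = 10, dt = 0.05, seed = 1L) {
  spec <- random_mmpp_spec(true_m, n_neurons, n_trials, trial_duration,
                           seed = seed)
  sim <- generate_mmpp(spec, seed = seed + 1L)
  counts <- bin_spikes(sim$dataset, dt)
  m_values <- 2:(true_m + 2L)
  ref <- select_best(counts, "sphmm", m_values, criterion = "bic",
                     n_inits = reference_pool, seed = seed + 2L)
  rows <- list()
  for (ps in pool_sizes) {
    for (r in seq_len(n_replicates)) {
      sel <- select_best(counts, "sphmm", m_values, criterion = "bic",
                         n_inits = ps, seed = seed + 100L * ps + r)
      rows[[length(rows) + 1L]] <- data.frame(
        pool_size = ps, replicate = r, m_star = sel$m_star,
        reference_m = ref$m_star, mismatch = sel$m_star - ref$m_star)
    }
  }
  do.call(rbind, rows)
}
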