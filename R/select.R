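# fit one Poisson-family model from one seeded random initial guess
.fit_one <- function(counts, m, model_kind, seed, theta = 0.8,
                     gamma_bar = 0.9, a_bar = 1.1, maxiter = 1000L,
                     tol = c(1e-6, 1e-6)) {
  init <- random_init(counts, m, "poisson", seed = seed,
                      theta = if (model_kind == "sphmm") theta else NULL)
  switch(model_kind,
         phmm = train_phmm(counts, init, maxiter = maxiter, tol = tol),
         sphmm = train_sphmm(counts, init,
                             sticky_config(theta = theta, maxiter = maxiter,
                                           tol = tol)),
         dphmm = train_dphmm(counts, init,
                             prior = if (m >= 2L)
                               dirichlet_prior(m, gamma_bar, a_bar)
                             else flat_prior(1L),
                             maxiter = maxiter, tol = tol),
         stop("unknown model kind: ", model_kind))
}

# validation log-likelihood of a fitted model on held-out trials, using the
# stationary initial distribution (held-out trials have no trained pi)
.validation_ll <- function(counts_val, params) {
  pi <- if (params$m == 1L) 1 else stationary_distribution(params$Gamma)
  .poisson_loglik(counts_val, params, pi = pi)
}

.subset_counts <- function(counts, idx) {
  out <- counts
  out$counts <- counts$counts[idx]
  out$n_bins <- counts$n_bins[idx]
  out
}

#' Cross-validated log-likelihood curves over the number of states
#'
#' Partitions trials into `n_folds` folds (seeded shuffle, then contiguous
#' blocks), trains on each fold's complement with `n_inits` random initial
#' guesses per candidate `m`, and scores each converged fit by its summed
#' log-likelihood over the fold's validation trials (`LLv`). For the
#' Dirichlet-prior model the validation log-posterior `LPv` (LLv plus the
#' transition log-prior) is also recorded. Means and standard deviations are
#' pooled across folds and initial guesses.
#'
#' @param counts a `binned_counts` object with at least `n_folds` trials.
#' @param model_kind `"phmm"`, `"sphmm"` or `"dphmm"`.
#' @param m_values candidate numbers of hidden states.
#' @param n_folds number of non-overlapping validation folds.
#' @param n_inits random initial guesses per fold and per `m`.
#' @param seed integer seed controlling folds and initializations.
#' @param theta sticky threshold (sPHMM only).
#' @param gamma_bar,a_bar Dirichlet prior settings (DPHMM only).
#' @param maxiter,tol passed to the trainers.
#' @return object of class `cv_report`: a data frame `table` with per-`m`
#'   mean/sd of `LLv` (and `LPv`) and convergence counts, a per-fit record
#'   `fits` (`m`, `fold`, `init`, `converged`, `llv`), plus `best_fit` (the
#'   highest-`LLv` converged fit per `m`) and the call settings.
#' @export
cross_validate <- function(counts, model_kind = c("sphmm", "phmm", "dphmm"),
                           m_values, n_folds = 5L, n_inits = 100L, seed = 1L,
                           theta = 0.8, gamma_bar = 0.9, a_bar = 1.1,
                           maxiter = 1000L, tol = c(1e-6, 1e-6)) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(counts, "binned_counts"))
  n_trials <- length(counts$counts)
  if (n_trials < n_folds) stop("need at least 'n_folds' trials")
  set.seed(seed)
  ord <- sample.int(n_trials)
  fold_of <- rep(seq_len(n_folds), length.out = n_trials)[order(ord)]
  llv <- lpv <- list(); best <- list()
  tab <- NULL
  fit_rows <- list()
  for (m in m_values) {
    key <- as.character(m)
    llv[[key]] <- numeric(0); lpv[[key]] <- numeric(0)
    n_conv <- 0L; n_above <- 0L; n_tot <- 0L
    best_fit <- NULL; best_ll <- -Inf
    for (fold in seq_len(n_folds)) {
      tr_idx <- which(fold_of != fold)
      va_idx <- which(fold_of == fold)
      ctr <- .subset_counts(counts, tr_idx)
      cva <- .subset_counts(counts, va_idx)
      for (g in seq_len(n_inits)) {
        fit_seed <- seed + 7919L * m + 613L * fold + g
        fit <- .fit_one(ctr, m, model_kind, fit_seed, theta = theta,
                        gamma_bar = gamma_bar, a_bar = a_bar,
                        maxiter = maxiter, tol = tol)
        n_tot <- n_tot + 1L
        ll <- if (fit$converged) .validation_ll(cva, fit$params) else NA_real_
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          m = m, fold = fold, init = g, converged = fit$converged,
          llv = ll, min_self_transition = fit$min_self_transition)
        if (!fit$converged) next
        n_conv <- n_conv + 1L
        if (fit$min_self_transition >= theta) n_above <- n_above + 1L
        llv[[key]] <- c(llv[[key]], ll)
        if (model_kind == "dphmm" && m >= 2L)
          lpv[[key]] <- c(lpv[[key]],
                          log_posterior(ll, fit$params$Gamma,
                                        dirichlet_prior(m, gamma_bar, a_bar)))
        if (ll > best_ll) { best_ll <- ll; best_fit <- fit }
      }
    }
    tab <- rbind(tab, data.frame(
      m = m,
      mean_llv = if (length(llv[[key]])) mean(llv[[key]]) else NA_real_,
      sd_llv = if (length(llv[[key]]) > 1L) stats::sd(llv[[key]]) else 0,
      mean_lpv = if (length(lpv[[key]])) mean(lpv[[key]]) else NA_real_,
      sd_lpv = if (length(lpv[[key]]) > 1L) stats::sd(lpv[[key]]) else 0,
      n_fits = n_tot, n_converged = n_conv,
      n_converged_above_threshold = n_above))
    best[[key]] <- best_fit
  }
  structure(list(table = tab, fits = do.call(rbind, fit_rows),
                 best_fit = best, model_kind = model_kind,
                 n_folds = n_folds, n_inits = n_inits, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%s, %d folds x %d inits):\n", x$model_kind,
              x$n_folds, x$n_inits))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pick the number of states from a cross-validation curve
#'
#' Three elbow rules for the mean validation log-likelihood curve:
#' `"max"` takes the maximum (prone to overestimation on monotone curves);
#' `"slope"` takes the point of largest decrease in discrete slope, i.e. the
#' `m` maximizing `[LLv(m) - LLv(m-1)] - [LLv(m+1) - LLv(m)]`; `"one_sd"`
#' takes the smallest `m` whose mean plus one SD exceeds the mean at the
#' maximizing `m` minus one SD there.
#'
#' @param report a [cross_validate()] result (or any data frame with columns
#'   `m`, `mean_llv`, `sd_llv`).
#' @param rule `"max"`, `"slope"` or `"one_sd"`.
#' @param use_lp rank by the validation log-posterior column instead (DPHMM).
#' @return the selected number of states.
#' @export
pick_cv <- function(report, rule = c("max", "slope", "one_sd"),
                    use_lp = FALSE) {
  rule <- match.arg(rule)
  tab <- if (inherits(report, "cv_report")) report$table else report
  tab <- tab[!is.na(tab$mean_llv), , drop = FALSE]
  tab <- tab[order(tab$m), , drop = FALSE]
  mu <- if (use_lp) tab$mean_lpv else tab$mean_llv
  sdv <- if (use_lp) tab$sd_lpv else tab$sd_llv
  if (rule == "max") return(tab$m[which.max(mu)])
  if (rule == "slope") {
    if (nrow(tab) < 3L) stop("the slope rule needs at least 3 candidate m")
    d <- diff(mu)                       # slope entering each m
    drop2 <- d[-length(d)] - d[-1L]     # slope decrease at interior m
    return(tab$m[1L + which.max(drop2)])
  }
  i_max <- which.max(mu)
  ok <- mu + sdv >= mu[i_max] - sdv[i_max]
  tab$m[which(ok)[1L]]
}

#' BIC and AIC for spike-train HMMs
#'
#' Information criteria with the parameter count `K = m (m - 1) + m N`
#' (transition rows plus state firing-rate vectors; initial distributions are
#' auxiliary and excluded) and `D` the total number of time bins across all
#' trials of the session: `BIC = -2 (LL + log_prior) + K log D` and
#' `AIC = -2 (LL + log_prior) + 2 K`. With `log_prior = 0` these are the
#' standard criteria; supplying the Dirichlet transition log-prior gives the
#' log-posterior-modified scores.
#'
#' @param loglik training-set log-likelihood of the fitted model.
#' @param m number of hidden states.
#' @param n_neurons ensemble size `N`.
#' @param n_bins_total total number of time bins `D` across trials.
#' @param mode `"bic"` or `"aic"`.
#' @param log_prior optional transition log-prior to add to the
#'   log-likelihood.
#' @return the score (smaller is better).
#' @export
information_criteria <- function(loglik, m, n_neurons, n_bins_total,
                                 mode = c("bic", "aic"), log_prior = 0) {
  mode <- match.arg(mode)
  K <- m * (m - 1) + m * n_neurons
  ll <- loglik + log_prior
  if (mode == "bic") -2 * ll + K * log(n_bins_total) else -2 * ll + 2 * K
}

#' Select the number of hidden states
#'
#' For `"bic"`/`"aic"` (optionally log-posterior-modified), models are
#' trained on the full dataset with `n_inits` random initial guesses per
#' candidate `m`; non-convergent fits are excluded, the chosen `m*` minimizes
#' the mean score over converged fits, and the returned model is the
#' lowest-score fit at `m*`. For the cross-validation criteria the trials are
#' split into folds via [cross_validate()] and `m*` follows the requested
#' elbow rule, returning the highest-`LLv` fit at `m*`.
#'
#' @param counts a `binned_counts` object.
#' @param model_kind `"phmm"`, `"sphmm"` or `"dphmm"`.
#' @param m_values candidate numbers of states.
#' @param criterion one of `"bic"`, `"aic"`, `"cv_max"`, `"cv_slope"`,
#'   `"cv_1sd"`.
#' @param n_inits random initial guesses per `m` (per fold for CV criteria).
#' @param seed integer seed.
#' @param modified use the log-posterior-modified BIC/AIC (DPHMM only).
#' @param n_folds folds for the CV criteria.
#' @param theta,gamma_bar,a_bar,maxiter,tol as in [cross_validate()].
#' @return object of class `selection_report`: `m_star`, `best_fit`, `table`
#'   (per-`m` score summaries and convergence counts), `criterion`.
#' @export
select_best <- function(counts, model_kind = c("sphmm", "phmm", "dphmm"),
                        m_values, criterion = c("bic", "aic", "cv_max",
                                                "cv_slope", "cv_1sd"),
                        n_inits = 25L, seed = 1L, modified = FALSE,
                        n_folds = 5L, theta = 0.8, gamma_bar = 0.9,
                        a_bar = 1.1, maxiter = 1000L, tol = c(1e-6, 1e-6)) {
  model_kind <- match.arg(model_kind)
  criterion <- match.arg(criterion)
  if (startsWith(criterion, "cv")) {
    rep <- cross_validate(counts, model_kind, m_values, n_folds = n_folds,
                          n_inits = n_inits, seed = seed, theta = theta,
                          gamma_bar = gamma_bar, a_bar = a_bar,
                          maxiter = maxiter, tol = tol)
    rule <- c(cv_max = "max", cv_slope = "slope", cv_1sd = "one_sd")[criterion]
    m_star <- pick_cv(rep, rule)
    return(structure(list(m_star = m_star,
                          best_fit = rep$best_fit[[as.character(m_star)]],
                          table = rep$table, criterion = criterion,
                          model_kind = model_kind),
                     class = "selection_report"))
  }
  D <- sum(counts$n_bins)
  tab <- NULL
  best_per_m <- list()
  for (m in m_values) {
    scores <- numeric(0)
    n_conv <- 0L; n_above <- 0L
    best_fit <- NULL; best_score <- Inf
    for (g in seq_len(n_inits)) {
      fit <- .fit_one(counts, m, model_kind, seed + 7919L * m + g,
                      theta = theta, gamma_bar = gamma_bar, a_bar = a_bar,
                      maxiter = maxiter, tol = tol)
      if (!fit$converged) next
      n_conv <- n_conv + 1L
      if (fit$min_self_transition >= theta) n_above <- n_above + 1L
      lp <- if (modified && model_kind == "dphmm" && m >= 2L)
        sum((dirichlet_prior(m, gamma_bar, a_bar)$A - 1) *
              log(fit$params$Gamma)) else 0
      sc <- information_criteria(fit$loglik, m, counts$n_neurons, D,
                                 mode = criterion, log_prior = lp)
      scores <- c(scores, sc)
      if (sc < best_score) { best_score <- sc; best_fit <- fit }
    }
    tab <- rbind(tab, data.frame(
      m = m,
      mean_score = if (length(scores)) mean(scores) else NA_real_,
      sd_score = if (length(scores) > 1L) stats::sd(scores) else 0,
      n_fits = n_inits, n_converged = n_conv,
      n_converged_above_threshold = n_above))
    best_per_m[[as.character(m)]] <- best_fit
  }
  if (all(is.na(tab$mean_score)))
    stop("no convergent fit at any candidate m")
  m_star <- tab$m[which.min(tab$mean_score)]
  structure(list(m_star = m_star,
                 best_fit = best_per_m[[as.character(m_star)]],
                 table = tab, criterion = criterion,
                 model_kind = model_kind),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("selection_report (%s, %s): m* = %d\n", x$model_kind,
              x$criterion, x$m_star))
  print(x$table, row.names = FALSE)
  invisible(x)
}
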