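---
title: "Segmenting spike trains with sticky Poisson hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting spike trains with sticky Poisson hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphmm)
```

## The model

Cortical ensemble activity often unfolds as a sequence of metastable states:
epochs of hundreds of milliseconds to seconds during which the firing rates
of simultaneously recorded neurons are approximately stationary, separated
by fast coordinated transitions. `sphmm` models an ensemble of `N` neurons
with a hidden Markov model whose `m` states are firing-rate vectors: state
`i` is the column `lambda[, i]` of an `N x m` rate matrix, time is
discretized into bins of width `dt` (50 ms by default), and the spike count
of neuron `n` in a bin spent in state `i` is Poisson with mean
`lambda[n, i] * dt`, with neurons conditionally independent given the state.
Cross-neuron correlations are carried by the shared state sequence, which
evolves by a row-stochastic transition matrix `Gamma`.

Training is multi-trial Baum-Welch (EM): a scaled forward-backward E-step
computes per-bin posteriors `q_i(t)`, pairwise posteriors `xi_ij(t)` and the
exact log-likelihood; the M-step re-estimates `Gamma` and `Lambda` with
numerators and denominators pooled over trials. A separate initial state
distribution is re-estimated per trial and treated as auxiliary (sessions
may mix conditions with different initial states); a fixed-initial mode is
available. Rates are floored at 0.001 spikes/s after every M-step so that
emission probabilities stay positive, and the `log(k!)` term is always
included in the reported log-likelihood so that information criteria are
comparable across models.

## Why sticky

Two failure modes plague HMM fits to spike data. First, the cross-validated
log-likelihood rarely decreases with `m`: extra states duplicate existing
ones, so likelihood-maximizing selection over-segments. Second, fitted
self-transition probabilities of intermediate-to-low value produce decoded
state switching far faster than spike data can support; a self-transition
probability `g` at bin width `dt` implies geometric dwells with mean
`dt / (1 - g)`, so `g = 0.5` at 50 ms bins means 100 ms states, at odds
with the typical 300-1000 ms persistence of cortical states.

The sticky trainer (`train_sphmm()`) runs ordinary EM while monitoring the
diagonal of `Gamma`. It keeps a rolling snapshot of `(Gamma, Lambda)` from
the most recent iteration (the initial guess qualifies) at which all
diagonals were at least a threshold `theta`. When some diagonal *converges*
below the threshold -- it changes by less than `epsilon = 5e-5` between
iterations while sitting below `theta` -- the snapshot is restored and the
snapshot's rate columns are randomly permuted across states, which acts as a
fresh initial guess that preserves the rates learned so far. Requiring
convergence before resetting means transient dips below `theta` during
normal EM progress do not interrupt training. The result is a hard
guarantee: a fit returned with `converged = TRUE` has every self-transition
probability at least `theta`; data incompatible with that constraint simply
never converges within the iteration budget (1000 iterations by default,
shared across resets). `theta_for_duration()` converts a target mean state
duration into the threshold via `theta = 1 - dt / duration`; the default
`theta = 0.8` at 50 ms bins corresponds to dwell times of at least 250 ms
(5 bins).

Design points that the algorithm sketch leaves open, resolved here: the
snapshot is a single rolling copy (O(1) memory); the rate-column permutation
at a reset is uniform over permutations and seeded; the per-trial initial
distributions are left untouched by a reset; and the pre-reset convergence
tolerance is identified with `epsilon`. Because the overall parameter
tolerance (1e-6) is smaller than `epsilon`, ordinary convergence cannot
sneak a sub-threshold diagonal past the reset trigger, so the guarantee
holds by construction (and is asserted over a randomized suite in the
tests).

The Dirichlet-prior variant (`train_dphmm()`) is the soft counterpart: an
independent Dirichlet prior on each transition row, parameterized by the
desired diagonal mode (`gamma_bar = 0.9`) and a common off-diagonal
concentration (`a_bar = 1.1`), from which the diagonal concentration follows
by inverting the Dirichlet mode formula (`a_ii = 1 + 0.9 (m - 1)` at the
defaults). The transition M-step becomes the maximum-a-posteriori update and
the monitored objective is the log-posterior (log-likelihood plus transition
log-prior, the prior's normalizing constant omitted since it is constant in
the parameters at fixed hyperparameters). The categorical benchmark
(`train_mhmm()`) encodes each short bin (5 ms default) as which single
neuron fired, or a no-spike symbol; it approximates the Poisson model only
when bins are short enough that multi-neuron collisions are rare --
`multi_spike_probability()` quantifies the breakdown (0.26 for 100 neurons
at 5 spikes/s in 2 ms bins).

## Convergence and numerics

The forward pass normalizes the forward variables per bin and accumulates
log scale factors, after also rescaling each bin's emission vector by its
maximum in log space; this is exact (it matches brute-force path enumeration
to 1e-10 on small instances, which is how the tests pin it down) and safe
for long low-rate trials. Convergence requires both the relative change of
the monitored objective (log-likelihood, or log-posterior for the MAP
variant) and the largest absolute parameter change to fall below 1e-6; the
categorical trainer additionally thresholds the emission-matrix change.
Degenerate cases surface explicitly: an all-impossible emission row raises a
numerical-degeneracy error, a state with zero expected occupancy triggers a
collapse warning and has its rates floored, and posterior-decoding argmax
ties resolve deterministically to the lowest state index (with a 1e-9
tolerance so floating-point near-ties behave identically).

## Decoding

`posterior_decode()` assigns each bin to the state with maximal posterior
probability and leaves bins *undecided* when no state reaches the 0.8
threshold -- many undecided bins are themselves a signature of
over-segmentation, since duplicated states split the posterior mass. The
decoding initial distribution defaults to the stationary distribution of the
fitted chain; the alternative of starting deterministically in state 1 is
provided with a configurable burn-in (default 0.4 s) that is marked
undecided, since only the post-burn-in decoding is trustworthy under that
convention. `viterbi_decode()` returns the single most probable path (no
undecided bins). Model comparison (`model_distance()`, `rho()`) decodes with
a threshold of zero, because its squared-error measure needs a rate in every
bin.

## Model selection

`cross_validate()` splits trials into 5 folds (seeded shuffle, contiguous
blocks), trains on each complement with seeded random initial guesses, and
pools the validation log-likelihood across folds and guesses;
non-convergent fits are excluded but counted, mirroring the convergence
bookkeeping that is itself diagnostic (a sticky model that rarely converges
at large `m` is telling you `m` is too large). Three elbow rules are
implemented for the typically monotone validation curve: the maximum (known
to overestimate), the largest decrease in discrete slope (formalized as the
maximal second difference, since no formula is standard), and the one-SD
rule (smallest `m` whose mean plus one SD exceeds the mean at the argmax
minus one SD). `select_best()` with BIC/AIC trains on the full session,
penalizing with `K = m(m-1) + mN` parameters (initial distributions are
auxiliary and excluded) and `D` the total bin count across trials; the
returned model is the lowest-score converged fit at the score-minimizing
`m`. The log-posterior-modified scores replace the log-likelihood with the
log-posterior at fixed prior. BIC is the recommended default: in the
ground-truth sweeps it recovers the generating `m` in the majority of
20-neuron datasets, while the maximum rule and AIC overestimate and the
slope rule underestimates.

SD pooling across folds and initial guesses is a single pooled SD (the
source analyses do not specify the decomposition); the per-fit records are
returned so any other aggregation can be computed.

## Ground-truth simulators

`generate_mmpp()` produces data for which the Poisson-HMM is the true model:
a continuous-time Markov chain simulated by the Gillespie algorithm -- the
per-bin transition matrix `Gamma` referenced to `dt_ref` is interpreted as a
generator with exit rate `(1 - gamma_ii) / dt_ref` and jump law
`gamma_ij / (1 - gamma_ii)`, which makes discrete-bin fitting at `dt_ref`
consistent with the generator -- emitting per-neuron Poisson spikes via
exponential inter-spike intervals restarted at each switch (exact by
memorylessness). The randomized variant draws diagonals uniform in
[0.8, 1], off-diagonal mass by normalized uniforms, and rates uniform in
[0, 30] spikes/s over 50 trials of 14 s -- the surrogate study conditions.
The initial state of each trial is drawn from the chain's stationary
distribution (the sources are silent; this makes trials exchangeable).
Dwell times are verified exponential with mean `dt_ref / (1 - gamma_ii)`
and within-state counts Poisson-dispersed in the tests. To emulate a
recorded session instead, wrap a fitted model's `(Gamma, Lambda)` in
`mmpp_spec()` with the session's trial layout.

Two shuffle controls break specific structure: the circular shuffle rotates
each neuron's spike train independently within its trial (single-neuron
statistics intact, cross-neuron state structure destroyed) and the swap
shuffle permutes bin order within each trial jointly across neurons (count
vectors intact, dwell structure destroyed). Both are implemented
within-trial (whether the sources wrap across the session is unstated).
Swap-shuffled data is the sticky trainer's designed failure case: with
dwell structure gone, no solution with all self-transitions above 0.8
exists, and training must not converge -- asserted in the tests.

`simulate_snn()` is the biologically grounded surrogate: 4000 excitatory
and 1000 inhibitory leaky integrate-and-fire neurons, 90% of the excitatory
population in 10 clusters with potentiated within-cluster weights
(`J+ = 2.2`) and depressed between-cluster weights, forward-Euler at
0.005 ms. The synaptic convention used here: each presynaptic spike injects
a total charge equal to its weight (a current jump `w / tau_syn` decaying
with `tau_syn`), which is the delta-drive reading of the synaptic equation.
Membrane and synaptic parameters follow the clustered-network literature
values carried in `snn_config()`. Desk-scale durations (seconds to tens of
seconds) already display metastable cluster switching; the thousands of
seconds used for full surrogate sessions are a cluster-scale job and not
run in the tests.

## Model comparison

`model_distance()` decodes every bin (no threshold) and sums squared
differences between observed counts and the decoded state's expected count;
`rho()` is the ratio of two models' distances on shared validation data.
Equivalent models give `rho` near 1; against a known generating model,
`rho(m)` decreases to about 1 at the true `m` and stays there for larger `m`
(over-segmented models duplicate states rather than invent wrong ones, which
is also why `match_states()` -- Hungarian assignment on Euclidean distances
between rate columns -- reports surplus states as near-duplicates).
`shuffled_rho_null()` gives the chance level: each draw permutes every
neuron's rates across states and shuffles each transition row's
off-diagonal entries in place. The per-neuron (rather than whole-column)
rate permutation is deliberate: relabeling intact rate vectors leaves the
decoded squared error essentially unchanged, because the decoder simply
follows the relabeled states, whereas breaking the vectors' composition
moves the null to about 1.2 -- the regime in which a genuinely matching
model's `rho` of about 1 is distinguishable chance at the percent level.

## A worked example

A small end-to-end run (sizes reduced so it executes in seconds):

```{r example, eval = FALSE}
spec <- random_mmpp_spec(m = 3, n_neurons = 10, n_trials = 15,
                         trial_duration = 10, seed = 2)
sim <- generate_mmpp(spec, seed = 3)
counts <- bin_spikes(sim$dataset, dt = 0.05)

sel <- select_best(counts, "sphmm", m_values = 2:5, criterion = "bic",
                   n_inits = 10, seed = 4)
sel$m_star                      # 3: the generating number of states
fit <- sel$best_fit
fit$min_self_transition         # >= 0.8 by the sticky guarantee

mt <- match_states(fit$params$Lambda, spec$Lambda)
mean(abs(fit$params$Lambda[, mt$pairs$state1] -
         spec$Lambda[, mt$pairs$state2]))   # < 1 spikes/s

dec <- posterior_decode(counts, fit$params)
```

## Scope and limitations

The surrogate generators emulate the statistical structure of cortical
sessions -- trial counts, durations, rate ranges, sticky dwell statistics --
but not everything about real recordings: no slow rate drift within states,
no non-Poisson interspike statistics (refractoriness, bursting), no
inhomogeneous task-locked modulation, and no spike-sorting noise. Passing
the ground-truth recovery tests therefore demonstrates correctness of the
algorithms under the model's own assumptions, not that any particular
recording is well described by an HMM; the shuffle controls are the
practical check for the latter. Semi-Markov durations, GLM-modulated
transitions, non-Poisson emissions and nonparametric (infinite-state)
alternatives are out of scope, as is clustering-based initialization, which
brought no measurable benefit over seeded random initial guesses in the
source analyses. Test and example problem sizes (tens of trials, tens of
initial guesses) are chosen so the whole suite runs in minutes on one core;
the same code scales to the 50-trial, 100-1000-guess setting by changing
arguments.
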