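---
title: "Dynamic brain-state analysis with brainstates: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain-state analysis with brainstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

`brainstates` decomposes multi-subject ROI fMRI time series into a small
set of recurring whole-brain activity states and asks how the temporal
deployment of those states differs between two groups.  This vignette is
the package's own account of the science: the model, the knobs that
matter, the numerical choices, and what the synthetic-data validation
does and does not demonstrate.

## The model

Observations are per-subject matrices with `T` timepoints and `R`
regions of interest (ROIs).  After per-channel standardization, subject
concatenation and PCA reduction to `P` components, the stacked data are
modeled by a hidden Markov chain with multivariate Gaussian emissions:
at each timepoint exactly one of `K` states is active, state `k` emitting
observations from `N(mu_k, Sigma_k)` in PC space.  The state sequence
follows a row-stochastic `K x K` transition matrix; each subject's chain
restarts from the initial distribution (no transition is counted across
a subject boundary), while all parameters are shared across subjects, so
states are defined at the group level and are directly comparable
between groups.

Inference is variational Bayes with conjugate priors:

* symmetric Dirichlet(`alpha0 = 1`) on the initial distribution and on
  each transition row;
* Normal–Wishart on each state's mean and precision, with weak settings
  `beta0 = 1e-3`, `nu0 = P + 2`, prior mean at the data grand mean, and
  prior scale matched to the per-component data variances.

The E-step runs scaled forward–backward per subject (in C++) using the
expected log-parameters; the M-step updates the conjugate posteriors
from the pooled responsibilities.  The reported *free energy* is the
negative evidence lower bound of the structured variational posterior;
VB-EM increases the bound at every sweep, so the trace is non-increasing
and the tests assert this on every restart.  Convergence is declared at
a relative free-energy change below `1e-6` (default `max_iter = 500`);
each fit runs several restarts from k-means initializations on a data
subsample, and the restart with the lowest final free energy wins.
Posterior-mean parameters are reported; covariances are regularized by
an escalating diagonal jitter only if a Cholesky factorization fails.

State labels are arbitrary; recovered states are matched to a reference
by exhaustive minimal-cost assignment over permutations for `K <= 8`
(greedy beyond), in `match_states()`.

## Preprocessing

Each ROI channel is demeaned and divided by its sample SD (denominator
`n - 1`), per subject.  Subjects are concatenated in manifest order and
one PCA basis is fit on the stacked matrix, so all state means live in a
single space; rows are weighted equally regardless of subject length.
The default retains the smallest `P` reaching 90% cumulative explained
variance; a fixed `n_components` overrides the target (and the achieved
variance is reported), matching a workflow in which roughly 90% of
variance corresponds to a fixed component count on full-size data.
Loading signs follow a deterministic convention (largest-magnitude entry
of each column positive) so maps are reproducible run-to-run.  State
activation maps are the posterior mean vectors back-projected to ROI
space; they are in standardized (z) ROI units and include the PCA
center, so the map of an "empty" state equals the grand mean pattern.

## Choosing the number of states

Fitting across a range of `K` shows the free energy decreasing
monotonically with `K`; it carries no selection information here and is
reported only.  Selection instead uses the fractional-occupancy elbow:
for each `K` the scan records the median over states of each state's
median FO across subjects.  Once `K` exceeds the number of states the
data support, surplus states go empty, their per-state medians are zero,
and the summary stops decreasing; `select_n_states()` returns the
smallest scanned `K` whose relative drop to the next `K` falls below
`epsilon = 0.05`.  A subtlety motivated this exact summary: the naive
median over all pooled (subject, state) FO values keeps decreasing by
roughly `1/K` even when every surplus state is exactly empty, because
the added zeros push the pooled median into the lower tail of the real
states' cross-subject spread — that summary has no elbow and cannot
drive the rule.  When no plateau exists the largest scanned `K` is
returned with a warning flag.

On planted 3-state cohorts (20 subjects, `T = 200`, 3-SD separation),
the elbow recovers `K* = 3` in 9 of 10 seeded scans of `K = 2..8`; the
failures occur when the cross-subject FO spread makes the `K = 3` to
`K = 4` relative drop straddle `epsilon`.  At a few hundred subjects
this noise term is negligible; at desk scale it is visible.

## Temporal statistics

All statistics are computed on hard (argmax, ties to the lowest index)
state paths, in units of timepoints: fractional occupancy (count / `T`),
lifetimes (maximal-run lengths), and interval times (gap between the end
of one visit and the start of the next).  Runs truncated by the sequence
boundaries are included by default — this preserves the exact identity
that lifetimes sum to `T` per subject — with a censoring flag available.
The multi-site source data have no single repetition time, so no seconds
conversion is applied by default; an optional TR setting adds converted
columns for reporting only.

## Group comparison

For each metric (FO, mean lifetime, mean interval) and state, nuisance
covariates are regressed out of the pooled sample by OLS — intercept
plus age (primary) or age, one-hot site and FIQ (robustness) — with
group deliberately excluded from the design, and the residuals compared
by a two-sided pooled-variance t-test (`t` signed case minus control;
Welch optional).  This residualize-then-test scheme is what "regressing
out" denotes; it is not ANCOVA, and the two differ slightly when
covariates correlate with group.  Significance is flagged by Bonferroni
with family size `K` (the states within one metric); because the
appropriate family is genuinely ambiguous in this literature, the
uncorrected flag is reported alongside rather than guessed away.  States
with undefined values (never visited) are dropped per test with counts
retained, and low-coverage tests are flagged rather than suppressed.

## Transition communities

The group-level transition matrix, diagonal removed, is thresholded to
the strongest 25% of off-diagonal entries
(`ceiling(0.25 * K * (K - 1))`, ties at the cutoff all retained and
reported).  On the resulting directed weighted graph, modularity

`Q = (1/w) * sum_ij [A_ij - s_out_i * s_in_j / w] * [c_i = c_j]`

is maximized by Newman spectral bisection — the eigen step uses the
symmetrized matrix `(B + B')/2`, recursion stops when the leading
eigenvalue is non-positive or a split does not increase `Q` — followed
by Kernighan–Lin-style single-node moves until no move helps.  The
procedure is deterministic.  On graphs of up to 8 nodes the partition
attains the exhaustive-enumeration maximum in at least 16 of 20 random
instances (and never exceeds it); planted two-block graphs with 3x
within-block weight are recovered essentially always.  Whether to
symmetrize the transition matrix before community detection is an open
choice in the source literature; the directed formulation is used here
because transitions are directed.

Modules are then labeled from the FO group tests: a module with more
significantly case-increased states than case-decreased ones is
`case-related`, the opposite `control-related`, ties or no significant
states `mixed`.  The plurality rule (rather than majority of module
size) is deliberate: with a single-state planted effect inside a
two-state module, a majority rule could never label any module.

## The synthetic cohort generator

The generator is first-class, tested code: it emulates exactly the
structure the model assumes — a hidden chain with state-specific
Gaussian emissions, a block-structured transition matrix, two groups
differing only in transition dynamics (never in state identity), and
per-subject nuisance covariates (age, FIQ, framewise displacement, site,
optional per-site mean offsets and age leakage into the dynamics).
Defaults, chosen once as a realistic desk-scale cohort: 30 subjects per
group, `T = 150` timepoints, `R = 20` regions, `K = 4` states in two
planted modules, self-transition probability 0.7, 75% of each row's
off-diagonal mass within-module, isotropic unit-variance noise, state
means separated by 3 noise-SDs (minimum pairwise Euclidean distance).
Full covariances are available behind an option.  A single global seed
fans out to per-subject streams by a fixed counter, so any subject can
be regenerated independently.

The group effect raises the case group's stationary occupancy of one
state by a target amount, funded only by the other module's states: the
generator finds the column-scaled transition matrix with the prescribed
stationary law (a damped multiplicative fixed point), leaving the effect
state's module-mate a genuine null state for specificity checks.  The
default effect size is 1 between-subject SD of that state's FO, with the
SD computed exactly from the chain's autocovariance series and pooled
over the two groups self-consistently — so "a 1-SD effect" is true by
construction rather than by estimate.  A consequence worth knowing: with
a true 1-SD effect and 30 subjects per group, the per-cohort probability
that the effect survives a two-sided Bonferroni test at `0.05/K` is only
about 0.88 — power, not implementation, limits how often desk-scale
cohorts flag the planted state.

What passing on synthetic data does not show: the generator has no
hemodynamic convolution, no autocorrelated noise within state, no
scanner drift, no motion artifacts and no long-range temporal
dependencies, all of which real resting-state fMRI has.  Recovery at
3-SD separation says the inference machinery is correct, not that real
cohorts carry that much signal.

## Problem sizes and runtime

The shipped validation uses cohorts of 20–60 subjects with `T` of
150–200 and `R` of 10–30, scans of `K = 2..8`, 10–20 seeded replicates
per experiment, and 10,000-replicate null calibrations — sizes chosen so
the full suite re-runs in minutes on one CPU while keeping every
recovery margin wide.  A 40-subject, 8,000-timepoint fit at `K = 5`
takes a few seconds thanks to the C++ forward–backward core.

## Known limitations

* Hard-path statistics ignore posterior uncertainty; near-degenerate
  states make lifetimes sensitive to the argmax rule.
* The Bonferroni family choice is a documented convention, not a fact of
  the method; both corrected and uncorrected flags are emitted.
* The elbow rule is noise-limited on small cohorts (see above).
* Exact replication of any specific real-data solution (state count,
  modularity value) is not claimed: priors, restarts and convergence
  settings all shift local optima, and the source analyses' settings are
  not fully knowable.
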