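# brainstates

Dynamic brain-state analysis for multi-subject ROI fMRI time series.

Resting-state fMRI is usually summarized by static functional
connectivity, which ignores that the brain moves through recurring
activity configurations on the scale of seconds.  `brainstates` models
those dynamics for a two-group cohort (e.g. patients vs controls): it
infers a set of whole-brain states shared by all subjects, quantifies
how each subject deploys them over time, tests group differences in
that deployment with covariate adjustment, and characterizes the
community structure of the transitions between states.  It is aimed at
researchers who already have per-subject ROI time series (one `T x R`
matrix per subject plus a cohort manifest) and want a reproducible,
seed-deterministic pipeline from those matrices to group-level results.

## The model in brief

After per-channel standardization, subject concatenation and PCA
reduction to `P` components, the stacked data `x_t` follow a `K`-state
hidden Markov model with Gaussian emissions,

    x_t | z_t = k  ~  N(mu_k, Sigma_k),        z_t  ~  Markov(A, pi),

with one shared parameter set across subjects (each subject's chain
restarts from `pi`).  Inference is variational Bayes with conjugate
priors (Dirichlet on `pi` and the rows of `A`, Normal–Wishart per
state); the negative evidence lower bound ("free energy") decreases
monotonically over sweeps and selects among random restarts.  From the
hard state paths the package computes per-subject fractional
occupancies, lifetimes and interval times; compares them between groups
by covariate-adjusted pooled t-tests with Bonferroni control; selects
the number of states by the median fractional-occupancy elbow across a
scan of `K`; and, after keeping the strongest 25% of off-diagonal
transitions, partitions the transition graph by Newman spectral
modularity maximization (directed formulation):

    Q = (1/w) * sum_ij [ A_ij - s_out_i s_in_j / w ] * 1{c_i = c_j}.

A fully tested synthetic-cohort generator plants known states, group
effects and transition communities, so every stage is validated against
ground truth without any data download.

## Worked example

Simulate a default cohort — 30 cases and 30 controls, `T = 150`
timepoints, `R = 20` ROIs, 4 planted states in two transition modules,
with the case group's occupancy of state 1 raised by one between-subject
SD — and run the full pipeline:

```r
library(brainstates)

cfg    <- cohort_config(seed = 42)
cohort <- simulate_cohort(make_ground_truth(cfg), cfg)

res <- run_pipeline(
  pipeline_config(out_dir = "demo_out",
                  hmm = list(K = 4, n_restarts = 3, seed = 1)),
  cohort = cohort)

print(res$fit)
subset(res$stats, metric == "FO" & covariate_set == "age")
print(res$partition)
score_recovery(res$fit, cohort, res$transform)
```

Output (abridged):

```
Variational Bayes Gaussian HMM: K = 4 states, P = 18 dims
  60 subjects, final free energy 224731.21 (8 iterations)

  state      t        p significant
1     1  0.842 0.403196       FALSE
2     2 -3.317 0.001573        TRUE
3     3  4.035 0.000162        TRUE
4     4 -1.935 0.057930       FALSE

Community partition: 2 modules, Q = 0.4376
  module 1: states 1, 3 (case-related)
  module 2: states 2, 4 (control-related)

state-mean correlation 0.997, path accuracy 0.947, FO MAE 0.0148
```

Reading this: the fit retained 18 principal components (90% variance).
Estimated state 3 is the planted effect state (state labels are
arbitrary; `score_recovery()` matches them) — its fractional occupancy
is significantly higher in cases after regressing out age and
Bonferroni correction over the 4 states (`t = 4.04`, `p = 1.6e-4`),
while state 2, in the donor module, is significantly lower.  The
thresholded transition graph splits into the two planted modules
(`Q = 0.438`), labeled case- and control-related from the occupancy
tests.  Recovery against the generator's ground truth: state-mean maps
correlate 0.997 with the planted patterns, 94.7% of timepoints are
decoded correctly, and per-subject occupancies are off by 0.015 on
average.

Real cohorts enter through `load_cohort("manifest.tsv")` (TSV manifest
with `subject_id, group, site, age, fiq, mean_fd, path` plus one
numeric TSV per subject) instead of `simulate_cohort()`; `scan_states()`
and `select_n_states()` choose `K` when it is not known.

## Layout

- `R/` — generator, preprocessing, VB-HMM core (+ `src/` C++
  forward–backward), temporal statistics, group comparison, transition
  communities, pipeline orchestration.
- `tests/testthat/` — unit, property and acceptance suites (oracle
  cross-checks include an independent run-length encoder, exhaustive
  modularity enumeration, and an external EM implementation).
- `vignettes/brainstates-methods.Rmd` — the methods vignette: model,
  parameter choices, numerical details, generator realism, limitations.
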