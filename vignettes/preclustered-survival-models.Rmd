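---
title: "Survival models with preclustered gene groups: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival models with preclustered gene groups: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-dimensional gene expression studies of censored survival outcomes face a
double bind: models sparse enough to interpret rarely use the biology we
already have, and models built on annotated gene sets (such as Gene Ontology
biological-process groups) inherit those sets' internal heterogeneity — one GO
group routinely contains subsets of genes with unrelated, or even
anti-correlated, expression profiles.  Summarizing such a group by a single
representative profile averages the informative subset away.

`preclustsurv` addresses this by *preclustering*: before a group becomes a
covariate, its genes are partitioned into correlated subclusters, and each
subcluster — not the whole group — is summarized and offered to the survival
model.  The package implements the full pipeline: covariate construction for
three genomic covariate types (single genes, whole groups, preclustered
subclusters), penalized Cox regression with mandatory clinical covariates,
cross-validated tuning, and honest repeated-split evaluation.

## Model

The hazard for a patient with genomic covariates $X$ and clinical covariates
$Z$ is

$$ h(t \mid X, Z) = h_0(t) \exp(\beta' X + \gamma' Z), $$

with an arbitrary baseline hazard $h_0$.  Coefficients maximize the Breslow-tie
log partial likelihood

$$ \ell(\beta, \gamma) = \sum_{i : \delta_i = 1} \Big[ \eta_i -
   \log \sum_{j : t_j \ge t_i} e^{\eta_j} \Big], \qquad
   \eta_i = \beta' x_i + \gamma' z_i, $$

penalized by $\lambda \sum_j |\beta_j|$ (lasso) or $\lambda \sum_j \beta_j^2$
(ridge).  Only the genomic block is penalized: the handful of clinical
covariates are mandatory and unpenalized.  $\beta'x_i + \gamma'z_i$ is the
*prognostic index* (risk score) of patient $i$.

## Preclustering

Within one group of $N$ genes, the dissimilarity between genes $i$ and $j$ is
$d(i,j) = 1 - \mathrm{Cor}(x_i, x_j)$ (Pearson, across samples): positively
correlated genes are close, anti-correlated genes are maximally distant.
Partitioning around medoids (PAM) finds $K$ representative genes minimizing
$\sum_i \min_j d(i, j)$.  The number of clusters is chosen by maximizing the
mean *intra-cluster correlation*

$$ \mathrm{ICC} = \frac{2}{n(n-1)} \sum_{\text{pairs}} C_i $$

(the mean of the lower triangle of the within-cluster correlation matrix of a
cluster of $n$ genes) over $K = 2, \dots, \min(N-1, k_{\max})$.

Design choices worth knowing about:

* **Exact PAM on small instances.** Classic PAM (greedy build followed by
  best-improving swaps) is a local search; on random dissimilarities it misses
  the global optimum in roughly 6% of small instances — and so does the
  reference implementation in the `cluster` package.  Because the medoid set
  determines the covariates downstream, `pam_cluster()` enumerates all medoid
  subsets when $\binom{N}{K} \le 2000$ (exact, deterministic,
  lexicographic tie-break) and only falls back to build + swap beyond that.
  Typical GO groups (a few dozen genes, small $K$) are solved exactly.
* **Degenerate cases.** Groups of 1–2 genes become a single cluster (the
  $K$ range $2..N-1$ is empty); the medoid is the min-total-dissimilarity
  gene, ties lexicographic.  Zero-variance genes have undefined correlation;
  they are treated as uncorrelated with everything ($\mathrm{Cor} = 0$,
  $d = 1$).  Singleton clusters get $\mathrm{ICC} = 0$, which penalizes
  fragmentation into singletons.
* **Ties in mean ICC** go to the smaller $K$ (parsimony).
* **$k_{\max} = 20$ by default.** The full sweep is $O(N)$ PAM runs per group
  and is disproportionate for groups with hundreds of genes; set
  `k_max = Inf` to match the full $2..N-1$ sweep.
* **Refinement of large homogeneous blocks.** The max-mean-ICC rule can
  *split* a large block of equally correlated genes into tighter sub-pairs
  (the mean pairwise correlation of the best split exceeds the block's by a
  sampling-noise margin).  Exact recovery of a planted partition is therefore
  reliable for small blocks (two blocks of three genes: >95% at
  $\rho = 0.9$, $n = 100$) while larger blocks may come back as several
  *pure* subclusters.  For the downstream model this is benign — each pure
  subcluster still tracks its latent factor — but interpreters should read
  "cluster" as "coherent subset", not "maximal subset".
* **Preclustering is retrained inside every training split** by default
  (honest evaluation; the alternative of clustering once on the full data is
  available via `precluster_on_full` for exploratory use).

## Covariate construction

A gene set (whole group or subcluster) is summarized by the first principal
component of its member genes, standardized to mean zero and unit variance
(correlation-scale PCA, consistent with correlation-based clustering).  The
sign of a principal component is arbitrary; scores are oriented to correlate
positively with the cluster medoid (or, for whole groups, the mean member
profile), which makes the reported effect directions (+1/−1) reproducible.
All constants — per-gene centering/scaling, loadings, covariate
standardization — are learned on training samples only and frozen;
`project_design()` transforms test samples without refitting.  Covariates are
standardized before penalized fitting because both penalties are
scale-sensitive.

## Fitting and tuning

* Unpenalized and ridge fits use exact Newton–Raphson with step halving
  (analytic gradient and Hessian of the Breslow partial likelihood; the ridge
  adds $2\lambda I$ on the penalized block).  Convergence is declared at a
  scaled gradient norm below $10^{-8}$, which reproduces `survival::coxph`
  coefficients to well below $10^{-5}$.
* Lasso fits use iteratively reweighted least squares with cyclic coordinate
  descent on the diagonal quadratic approximation of the partial likelihood —
  soft-thresholding yields exact zeros, step halving on the penalized
  objective guarantees monotone ascent, and the subgradient conditions are
  verified by the test suite.  Relative-objective tolerance $10^{-6}$,
  at most 200 outer iterations.
* $\lambda$ is chosen by maximizing the M-fold (default 10) cross-validated
  partial likelihood: fold $m$ contributes
  $\ell(\hat\theta_{-m}) - \ell_{-m}(\hat\theta_{-m})$, the all-patient log
  partial likelihood minus the leave-fold-out one, both at leave-fold-out
  estimates.  Folds are stratified by event status (every fold gets an event
  whenever possible) and shared across the whole grid; ties go to the larger
  $\lambda$.  The default lasso grid is 50 log-spaced values from just above
  $\lambda_{\max}$ (the smallest penalty that zeroes every genomic
  coefficient, computed from the score at $\beta = 0$) down to
  $0.01\,\lambda_{\max}$; the ridge grid spans $[10^{-2}, 10^{6}] \cdot n/p$.
  A saturation guard (`df_max`, default 90% of the fold's event count) stops
  each fold's path once the active set reaches the overfitting regime; those
  deep-path $\lambda$ values cannot win the CVPL argmax but dominate run time.
  One caution from our null simulations: CVPL-argmax selects the *exactly*
  empty model on pure-noise covariates in only about three quarters of
  replicates — the familiar behavior that motivates one-standard-error rules.

## Evaluation

Each of `n_splits` random 2:1 splits (train $\lfloor 2n/3 \rfloor$, test the
rest) is processed independently: precluster, build the design, tune
$\lambda$, fit on the full training set, project the test samples, then

* **logrank test** on two prognostic groups (high risk = prognostic index
  strictly above the test-set median; ties at the median go to low risk);
* **prognostic-index likelihood-ratio test**: the PI enters a univariate Cox
  model and $2[\ell(\hat\alpha) - \ell(0)]$ is referred to $\chi^2_1$;
* **integrated Brier score**: survival predictions
  $\hat S(t \mid x, z) = \exp(-\hat H_0(t) e^{\hat\eta})$ from the Breslow
  baseline, scored by the IPCW Brier estimator with the censoring
  distribution $\hat G$ estimated by reverse Kaplan–Meier *on the test set*,
  and averaged over $[0, t^*]$, $t^* = 10$ years, by the trapezoid rule on
  the union of the test-set event times and the endpoints.  The event-term
  weight uses the left limit $\hat G(t_i^-)$ (Graf's convention).  If
  $\hat G$ hits zero before $t^*$, $t^*$ is truncated with a warning.

Selection frequencies aggregate the lasso fits across splits.  Because
preclustering is retrained per split, subcluster covariates are identified
across splits by their (group, medoid) pair; the reported effect sign is the
majority sign over selecting splits and the cluster size the median.

## The synthetic world

The generator produces the structure the method assumes, not microarray
realism: per-cluster latent factors (standard normal per sample), member
genes $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ so the within-cluster
correlation is $\rho$, optional sign-flipped members, exponential event times
with rate $h_0 \exp(\beta' f + \gamma' Z)$ and independent exponential
censoring.  Clinical covariates are one binary and one standard-normal
variable with modest effects, exercising the unpenalized block.  Presets:

* `tiny` — 20 genes / 4 groups / 40 samples; unit-test scale.
* `null` — no survival association at all; calibration checks.
* `clustered_signal` — 3 signal groups hidden among 50 noise groups
  (12 genes, two latent clusters each, $\rho = 0.8$), $n = 200$, cluster
  effects $\beta = (1, -1, 1)$, censoring calibrated numerically to ~25%
  events (the naive rate-ratio formula ignores the spread of the linear
  predictor, which inflates the event fraction).
* `anticorrelated` — six groups, each a 5-gene survival-relevant cluster
  beside a 15-gene distractor cluster with half its genes sign-flipped,
  $\rho = 0.9$, $n = 300$.  The whole-group first principal component locks
  onto the larger distractor factor ($|\mathrm{Cor}|$ with the signal factor
  ~0.05) while the subcluster component tracks it (~0.99) — the motivating
  phenomenon, built to be visible.

What a green test does *not* establish: performance under probe-level noise,
batch effects, non-proportional hazards, informative censoring, or annotation
error; none of these are modeled.

## Numerical and degenerate-input conventions

* Ties in event times: Breslow everywhere (partial likelihood, baseline,
  LRT); no Efron correction.
* Zero events: refuse to fit (the partial likelihood is identically zero).
* Perfect separation at $\lambda = 0$: the unbounded linear predictor is
  detected and reported as divergence.
* All prognostic indices equal: every patient goes to the low-risk group with
  a warning, the logrank test is then undefined and recorded as missing.
* Failed splits in the batch protocol are recorded with an error marker and
  excluded from aggregation, with a count, rather than aborting the batch.
* Reproducibility: every stochastic step takes an explicit seed; batch runs
  derive per-split and per-fold sub-seeds from one master seed, so identical
  master seeds give bit-identical summaries.

## Known limitations

Whole-group mode inherits the instability of a first principal component under
near-tied eigenvalues.  The exact-PAM threshold trades a little bias for
determinism on large groups ($\binom{N}{K} > 2000$ falls back to a local
search).  The ICC rule over-refines large homogeneous blocks (see above).  The
CLI and report writer are conveniences, not stable interfaces.
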