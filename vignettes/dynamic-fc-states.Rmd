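---
title: "Dynamic functional connectivity states: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectivity states: models, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`dynfc` implements a sliding-window dynamic functional-connectivity (dFC)
analysis for ROI-level resting-state fMRI time series, of the kind used to
compare a patient group against matched controls. The pipeline has five
stages.

**Windowed FC.** For each participant, Pearson correlation matrices are
computed over rectangular sliding windows of the ROI time series. Defaults
are a window of 10 TRs moved in steps of 1 TR, so a 135-time-point series
(140 acquired volumes with the first 5 discarded upstream) yields 126
windows; at TR = 3 s a window spans 30 s. Each symmetric matrix is stored as
its strict upper triangle ("edge vector", length $p(p-1)/2$). No Fisher
z-transform and no window tapering are applied: the downstream clustering
and statistics operate on raw correlations.

**State detection.** Recurring whole-brain connectivity patterns ("FC
states") are found by k-means clustering of all windows under the L1
(cityblock) distance, in two stages:

1. *Exemplar subsampling.* For each participant, let $l_i$ be the L1-norm of
   window $i$'s edge vector and $m$ the L1-norm of the participant's
   across-window mean matrix. Windows with $|l_i - m| > 1.5\,s$, where $s$
   is the standard deviation of the $l_i$, are selected as exemplars. The
   deviation is two-sided and the SD is the participant's own.
2. *Cluster-number scan and final clustering.* On the exemplars, the
   clustering is repeated for $k = 2..9$ with 100 seeded restarts per $k$;
   the best-cost fit per $k$ is scored by the mean Silhouette width (L1
   metric) and the Calinski-Harabasz (CH) index. The chosen $k$ is the CH
   peak; the Silhouette elbow (the interior $k$ maximizing the discrete
   second difference of the curve) is computed alongside and any
   disagreement is recorded. All windows of all participants are then
   clustered once, initialized at the exemplar centroids.

"k-means with L1 distances" is implemented as k-medians: the element-wise
median is the L1-consistent centroid, matching common cityblock k-means
implementations. States are relabeled by ascending mean absolute centroid
connectivity, so state 1 is always the weakest ("baseline") state and state
names are stable across runs.

**State metrics.** Per participant and state: the element-wise median FC
matrix over the windows in that state (a state never visited is marked
absent and excluded); dwell time (window occupancy per state — not mean
contiguous run length; a run-length variant is available behind a flag);
the number of transitions; and the distribution of transition frequencies
over ordered (source, target) pairs.

**Nodal temporal variability.** For region $k$, its FC profile in window $i$
is row $k$ of the window-$i$ correlation matrix with the self-entry removed.
Temporal variability is one minus temporal stability,

$$V_k = 1 - \frac{\sum_{i \ne j} \rho(F_{i,k}, F_{j,k})}{n(n-1)},$$

with $n$ the window count. Values lie in $[0, 2]$; 0 means a perfectly
stable connectivity fingerprint. The sum is evaluated over unordered pairs
with the denominator handled analytically (Pearson correlation is
symmetric), and a closed-form standardized-profile computation replaces the
double loop; an explicit double-loop reference implementation
(`variability_oracle()`) ships in the package and the two are required to
agree to $10^{-10}$ in the tests.

**Group statistics.** A Lilliefors test (at $\alpha = 0.05$) gates
continuous variables into the normal-theory or rank-based test family.
Edgewise and regionwise group comparisons use a univariate linear model with
age and sex as covariates, with Benjamini-Hochberg FDR correction within
each analysis family (per state for edges; over regions for variability;
over the dwell/transition/frequency set for temporal properties). Temporal
properties are compared with a Mann-Whitney U test after pooled OLS
residualization on age and sex — the residualization is this package's
operationalization of "controlling" covariates for a rank test, recorded in
the output metadata rather than asserted as the only possible reading. ROC
analyses classify patients against controls by the median strength of the
significant edges of each state and direction; because edge selection and
classification reuse the same sample, these AUCs are descriptive
(an optional split replication is left to the user). Partial correlations
between dFC indicators and clinical scores (MMSE, NPI) control age and sex
by residualizing both variables and use $n - 2 - c$ degrees of freedom.

# The synthetic cohort generator

Real case-control fMRI data cannot ship with a package, so `dynfc` includes
a generator whose cohorts have known ground truth at every level the
pipeline estimates: the state sequence of every participant, the per-state
per-group correlation matrices, and the group assignment.

Each participant's signal is a zero-mean multivariate normal draw given the
current latent state, plus white observation noise (SD 0.1); states differ
by correlation structure only, because windowed Pearson correlation is
mean-invariant. Latent states follow a first-order Markov chain at
time-point resolution, so windows spanning a switch are genuinely mixed, as
in real recordings.

## Default study conditions

The defaults describe a 20+20 cohort, 60 regions, 135 time points, three
states. The state geometry and switching dynamics were designed once, from
the following considerations, and are not tuned per analysis:

* **Three module-structured states.** Each state is a three-module block
  correlation matrix (within-module correlations 0.6 / 0.7 / 0.8 for states
  1-3, between-module 0). The increasing strengths give the familiar
  ordering from a weak "baseline" state to a strong, rarer state, and make
  the strength-based state naming stable.
* **Partitions with chance-level overlap.** The three module partitions
  (contiguous thirds; region-index mod 3; a coprime-stride permutation of
  contiguous thirds) share within-module region pairs only at the ~1/3
  chance level. This matters: partitions with structured overlap bring two
  states closer in edge space than the others, and the variance-ratio (CH)
  criterion then prefers merging the close pair — the cluster-number scan
  would report two states even when window labels are perfectly
  recoverable. With near-equal pairwise separations and balanced state
  sizes, the CH peak at the true number of states is robust across seeds.
* **Moderate separation.** Within-module correlations near 0.7 place the
  between-state distances a factor ~2 above the within-state scatter that
  10-TR windowed correlation estimates carry. Much weaker states are not
  resolvable at this window length; much stronger states make the
  switch-spanning windows (about a third of all windows at the default
  dynamics) so far from every state centroid that they form their own
  cluster and the scan over-estimates $k$.
* **Group dynamics.** Transition matrices have the form
  $(1-r)\,I + r\,\mathbf{1}\pi^T$, so the stationary distribution is exactly
  $\pi$ and the switching rate is set by $r$. Controls use
  $\pi = (0.45, 0.25, 0.30)$, $r = 0.05$ (about 4 transitions per 135 time
  points); patients use $\pi = (0.20, 0.50, 0.30)$, $r = 0.085$ (about 7).
  This plants the clinical pattern of interest — patients dwell less in the
  baseline state, much longer in state 2, and switch more often — with
  margins large enough that a 20-per-group rank test detects the dwell
  difference reliably, while keeping per-participant state-2 occupancy high
  enough in both groups for stable participant-level median FC matrices.
* **Planted edge effects.** Group differences in specific edges of one
  state are added via `patient_edge_effects`;
  `default_edge_effects()` builds the canonical set: 12 strengthened
  between-module edges and 12 weakened within-module edges
  ($|\Delta r| = 0.4$) in state 2, all on distinct regions so the
  positive-semidefinite repair of the perturbed matrix (eigenvalue clipping
  at $10^{-8}$, then rescaling the diagonal to 1) shrinks every planted
  effect equally (to about 0.33-0.34 in practice).
* **Demographics.** Ages ~ N(75, 6.4), balanced sex, MMSE near 29 (controls)
  vs 21 (patients), NPI near 0.7 vs 4.6 — an elderly memory-clinic profile,
  so covariate adjustment and clinical correlations can be exercised
  realistically.

## What the generator does not emulate

Observations are temporally independent given the state: there is no
hemodynamic response, no autocorrelation, no scanner drift, no head-motion
artifact, and no physiological nuisance structure. Two consequences matter
for interpreting green tests. First, windowed estimates from real, band-pass
filtered BOLD have fewer effective degrees of freedom per window and
correlated errors across overlapping windows, so all recovery results here
are optimistic relative to real data. Second, the exemplar rule selects far
more windows here (nearly all) than it does on real recordings (typically
~10-15% per participant): with independent observations every window's
L1-norm exceeds the mean matrix's norm by a nearly constant sampling-noise
offset that dwarfs the across-window SD. The rule is implemented exactly as
specified and behaves conventionally on data with realistic temporal
smoothness; on the synthetic cohorts it simply passes most windows through,
which costs computation but no correctness. Passing tests therefore
demonstrate the pipeline's internal consistency and its statistical
calibration, not field performance on fMRI.

# Numerical choices

* **k-medians.** Assignment ties break toward the lowest centroid index;
  empty clusters are re-seeded at the vector farthest (L1) from the empty
  cluster's centroid and the event is logged. Iteration stops on label
  stability by default (`tol = 0`); a cost-decrease threshold is available.
  The C++ core uses Hamerly-style distance bounds (valid for any metric, via
  the triangle inequality) and recomputes a cluster's median only when its
  membership changed — both exact optimizations that leave the Lloyd
  trajectory untouched, verified against naive implementations in the tests.
* **Restart screening.** "100 restarts per k" is implemented as 100 seeded
  initial centroid sets scored by their exact initial assignment cost, of
  which the 5 most promising are run to convergence and the best-cost fit is
  scored. On separable data the converged best is insensitive to this
  screening (the scan's purpose is the best-of-restarts fit, not the
  distribution of restarts), and the scan runs in minutes rather than hours
  at the default problem size.
* **Degenerate inputs.** Zero-variance window segments yield 0-valued
  correlations plus a per-window flag (never NaN); regions whose FC profile
  is constant in any window are marked invalid in the variability output; a
  state with fewer than 2 participants per group is skipped by the edgewise
  comparison with a warning (the fate of rare states in small cohorts);
  constant inputs to the normality gate classify as non-normal with a
  warning.
* **Matrix norms.** L1-norms of FC matrices are taken over the unique
  off-diagonal edges. The constant unit diagonal would only shift both
  $l_i$ and $m$ by the same amount in the exemplar rule, so this choice is
  inert there, but it is stated here because other conventions exist.
* **Determinism.** Every random draw flows from a single master seed through
  derived sub-seeds; generated cohorts and pipeline outputs are
  byte-identical across runs with the same configuration, which the tests
  enforce via file hashes.

# Validation problem sizes

The shipped validation uses: the default 20+20 cohort for state recovery
(cluster-number scan over $k = 2..9$ with 100 restarts); 20 replicate
cohorts for effect recovery (planted edges, dwell difference, ROC);
20 null cohorts at 10 per group and 40 regions for the edgewise
false-positive check plus 500 null scalar draws for test calibration; 50
synthetic participants at 60 regions and 126 windows for the $V_k$ oracle
equivalence; and exhaustive enumeration up to 8 vectors and $k = 3$ for the
clustering optimality check. These sizes were chosen so the full suite
completes on a laptop-class single core while keeping every check at its
intended severity.

# Known limitations

* The sliding-window + k-means construction is one of several dFC
  methodologies; hidden Markov models, point-process approaches, and
  windowless phase-synchrony variants are out of scope.
* The ROC analyses reuse the sample that selected the significant edges and
  must not be read as out-of-sample classification performance.
* The rank-test covariate adjustment by residualization is a convention,
  not a canonical definition; with strongly non-normal covariate effects
  the residualization itself borrows a linear-model assumption.
* Group-level mean dwell time averages over all participants, counting a
  never-visited state as 0; the occurring-participants-only variant is
  reported alongside because both conventions appear in the literature.
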