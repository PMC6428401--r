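---
title: "Resistance-perturbation kernel tests for brain connectivity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance-perturbation kernel tests for brain connectivity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpdkernel)
```

# The problem

Resting-state functional MRI studies summarise each subject as a weighted
graph: nodes are atlas regions, edge weights are inter-regional correlations
of the BOLD signal.  The usual route to group comparison collapses each
graph to one or two scalar summaries (global efficiency, clustering, rich
club), discarding most of the topology.  `rpdkernel` instead compares whole
graphs through the **resistance perturbation distance** and tests the
association between that between-subject geometry and a binary phenotype
with a **kernel-machine score test**.  No assumption is made about the form
of the association; parametric covariates (age, sex, handedness) are
adjusted for in an ordinary logistic component.

# Effective resistance and the distance

For an undirected graph with non-negative symmetric weights $A$ and
Laplacian $L = D - A$, the effective resistance between vertices $i$ and
$j$ treats every edge as a resistor of conductance $A_{ij}$:

$$R = \operatorname{diag}(L^+)\mathbf 1^\top + \mathbf 1\operatorname{diag}(L^+)^\top - 2L^+,$$

with $L^+$ the Moore–Penrose pseudo-inverse.  $R_{ij}$ is small when many
strong parallel paths join $i$ and $j$, so it is sensitive to both local and
global reorganisation.  The resistance perturbation distance between two
graphs on the same vertex set is the element-wise $p$-norm of the difference
of their resistance matrices,

$$d_{rp(p)}(G^{(1)}, G^{(2)}) =
  \Big[\textstyle\sum_{i,j}|R^{(1)}_{ij}-R^{(2)}_{ij}|^p\Big]^{1/p},$$

summed over ordered pairs (each unordered pair counts twice; the factor is
uniform and cancels wherever scale-free quantities are formed).  With
$p = 2$ — the default — $d_{rp(2)}$ is the Euclidean distance between
vectorised resistance matrices, which is what guarantees a positive
semi-definite Gaussian kernel later; other $p \ge 1$ are supported, with a
spectral check on the kernel.

## Disconnected graphs

Effective resistance diverges as a bridge weight tends to zero, but the
bare pseudo-inverse of a *disconnected* Laplacian jumps to small formal
cross-component values — it rewards disconnection instead of penalising it,
and (in our experiments) inverts the qualitative orderings a graph distance
is supposed to respect.  When a disconnected graph must be evaluated
(`allow_disconnected = TRUE`), the non-trivial null directions of $L$ are
therefore assigned a small conductance $\varepsilon$ (`regularization`,
default $10^{-6}$): within-component resistances remain exact (null vectors
are constant on components), while cross-component resistances become
$O(1/\varepsilon)$, the continuous analogue of a vanishing bridge.  Setting
`regularization = 0` recovers the bare pseudo-inverse.  The default
$\varepsilon$ only sets the magnitude of the disconnection penalty; any
value several orders below the smallest genuine edge weight gives the same
qualitative behaviour.

Connectivity itself is decided spectrally: a graph is connected iff the
second-smallest Laplacian eigenvalue exceeds $10^{-9}$ times the largest —
a scale-free test that agrees with component counting on all non-degenerate
inputs.

# The kernel-machine score test

For subjects $i = 1,\dots,n$ with binary outcome $y_i$, covariates $x_i$,
and connectivity graph $G_i$, the semiparametric logistic model is

$$\operatorname{logit}\Pr(Y_i = 1) = x_i^\top\beta + h(G_i),$$

where $h$ lives in the reproducing-kernel Hilbert space of the Gaussian
distance kernel

$$K_{ij} = \exp\{-d_{rp(2)}(G_i, G_j)^2/\rho\}.$$

Treating $h$ as a random effect with covariance $\tau K(\rho)$, the null
hypothesis "connectivity carries no information about the phenotype" is
$H_0: \tau = 0$.  The variance-component score statistic at bandwidth
$\rho$ is

$$Q(\rho) = (y-\hat\mu_0)^\top K(\rho)\,(y-\hat\mu_0), \qquad
  S(\rho) = \frac{Q - \mu_Q}{\sigma_Q},$$

with $\hat\mu_0$ the fitted null logistic probabilities,
$\mu_Q = \operatorname{tr}(P_0K)$,
$\sigma_Q^2 = 2\operatorname{tr}(P_0KP_0K)$, and
$P_0 = D_0 - D_0X(X^\top D_0X)^{-1}X^\top D_0$,
$D_0 = \operatorname{diag}[\hat\mu_0(1-\hat\mu_0)]$.  No factor of $1/2$ is
carried on $Q$; since the same convention enters $\mu_Q$ and $\sigma_Q$,
the standardised process $S(\rho)$ is unaffected.

$\rho$ is inestimable under the null, so $S(\rho)$ is maximised over a grid
and the p-value is bounded from above in the manner of Davies' treatment of
nuisance parameters absent under the null:

$$p \le \Phi(-M) + W\,\frac{e^{-M^2/2}}{\sqrt{8\pi}},$$

with $M = \max_\rho S(\rho)$ and $W$ the total variation of $S$ over the
grid.  The search interval follows the common grid recommendation
$L = 0.1\min_{i\ne j} d_{ij}^2$, $U = 100\max_{i\ne j} d_{ij}^2$ (duplicated
subjects with $d_{ij}=0$ are excluded from the minimum so that $L>0$), with
50 log-spaced interior points by default.  Grid points whose score variance
degenerates (for instance $K \to \mathbf{1}\mathbf{1}^\top$ with an
intercept-only null, which $P_0$ annihilates) are dropped; at least two
must survive.  The bound can exceed 1 and is clipped for reporting (the raw
value is kept in the result).

`fit_semiparametric()` additionally estimates $(\beta, h)$ at a fixed
$\tau$ by the blockwise Newton–Raphson scheme on the working response; it
is provided for visualising the fitted network effect, not for inference.

# The synthetic cohort generator

No real data ship with the package.  `cohort_spec()` / `sample_cohort()`
emulate a cohort of correlation-derived networks with three ingredients:

1. **Population component** — a preferential-attachment (Barabási–Albert)
   topology whose attachment count is chosen so the realised edge density
   matches `1 - sparsity`; each edge receives a signed strength, magnitude
   `pop_strength` × Uniform(0.3, 1), sign ± with probability 1/2.  The
   mixed signs produce the mixed positive/negative correlations seen in
   functional connectivity.
2. **Subject effects** — `ceiling(REsize% × n_edges)` candidate positions
   among the population edges; each included independently with probability
   `REprob` and given a Normal(0, `REnoise`²) precision perturbation.  This
   models inter-subject variability *of the shared edges*; the alternative
   reading (effects at arbitrary vertex pairs) makes subject noise at the
   study's `REnoise = 3` overwhelm any population signal, leaving cohorts
   from different populations statistically indistinguishable, which
   contradicts the separability the validation studies require.
3. **Sampling** — each subject's precision matrix
   $\Theta^{pop} + \Theta^{(i)}$ passes through the positive-definite
   correction $PD(\cdot)$ (a diagonal shift of $|\lambda_{\min}| + 0.1$
   whenever $\lambda_{\min} \le 0.1$), is inverted, and `n_time` i.i.d.
   multivariate-normal observations are drawn; the empirical correlation
   matrix, symmetrised, zero-diagonal, with negatives resolved by
   `negative_mode` (default: zeroed, the neuroimaging convention), becomes
   the subject's graph.  `method = "direct"` bypasses sampling and uses the
   partial correlations implied by the precision matrix — a noise-free
   variant used by the distance-property experiments.

Subjects whose zeroed-negative graph is disconnected are redrawn (up to 10
times, logged in the `resamples` attribute); rare survivors are kept and
flagged so downstream code can use the regularised-resistance path.

## Default parameters and the one calibrated scale

| parameter | default | meaning |
|---|---|---|
| `p` | 90 | nodes (atlas regions) |
| `n_subjects` | 100 | cohort size |
| `sparsity` | 0.75 | absent-edge fraction of the population network |
| `REsize` | 10 | % of population edges eligible for subject effects |
| `REprob` | 0.65 | inclusion probability per eligible edge |
| `REnoise` | 3 | SD of a subject-effect precision entry |
| `n_time` | 150 | observations per subject (a typical ~5 min resting-state run at TR = 2 s) |
| `pop_strength` | 15 | population edge-strength scale (see below) |

`p`, `sparsity`, `REsize`, `REprob` and `REnoise` are the study settings
used throughout the validation experiments.  The magnitude of the
population edge strengths relative to the *absolute* subject-effect scale
`REnoise` is not determined by those settings, yet it controls everything
the validation studies measure: with unscaled Uniform(0.3, 1) strengths the
population share of the precision variance is a few percent and cohorts
from different populations are indistinguishable (between/within distance
ratio ≈ 1.00).  `pop_strength` is therefore an explicit parameter,
calibrated **once** against the regime the validation studies describe —
separable populations with visible subject-level variability — and not
revisited: rejection rates in the two-population design plateau for
`pop_strength` between roughly 14 and 25, and 15 is the smallest round
value on that plateau.  Larger values buy nothing: the $PD(\cdot)$ shift
pins the smallest precision eigenvalue at 0.1, so strongly scaled
populations become nearly rank-one, and their correlation matrices develop
weakly bridged sign-blocks whose enormous effective resistances dominate
the distance matrix.  That spectral artefact, not the test, is what limits
the attainable power of the emulated two-population design: the shipped
power study (`power_experiment()`, 200 replicates) measures rejection
rates in the mid-0.8s at the defaults, and no admissible `pop_strength`
raises the plateau.

## What the generator does and does not emulate

It reproduces: a shared scale-free population topology, subject-specific
perturbation of shared edges, correlation matrices estimated from finite
noisy data, mixed correlation signs and their conventional zeroing.  It
does **not** model temporal autocorrelation of the BOLD signal (rows are
i.i.d.), physiological or motion artefacts, site effects, or any spatial
embedding of the atlas.  Passing validation tests on these cohorts
therefore says the statistics behave as designed under a plausible
correlation-network model — not that effect sizes on real fMRI data will
match.

# The validation experiments

Four **distance-property experiments** (ten-node matrices, one condition
pair per iteration) check the qualitative behaviour expected of a graph
distance: disconnecting deletions hurt more than random ones
(edge importance), heavier removed edges hurt more (weight awareness),
deletions matter more in sparse graphs (submodularity), node-targeted
deletions hurt more than scattered ones (focus awareness).  They run on
`method = "direct"` network matrices at population `sparsity = 0.1`: the
sampled-correlation variant carries near-zero noise edges whose removal can
move huge resistances, drowning the weight-awareness comparison in
artefacts, and sparser graphs make *random* deletions disconnect almost as
often as targeted ones, blurring edge importance.  The weight-awareness
experiment additionally resamples iterations where either single deletion
would disconnect the graph: that comparison is about connectivity-
preserving deletions of different strengths; disconnecting changes are
precisely what the edge-importance experiment measures.  The
submodularity conditions use absent-edge fractions 0.55 (sparse) and 0.05
(dense), i.e. edge densities 0.45 and 0.95 — the densities of the original
study's sparse and dense conditions expressed in this package's
parameterisation.

The **power study** draws, per replicate, three independent population
networks: 10 "control", 10 "patient" and 80 "noise" subjects, the noise
split 45/35 so the labelled groups are 55 vs 45, and rejects at the Davies
bound < 0.05.  The **Type-I study** draws all 100 subjects from one
process with an arbitrary 55/45 labelling.  The **noise-allocation sweep**
varies the noise split from 5% to 95% (Type II error peaks near even
splits, where the labelled groups look alike).  The **label-split sweep**
relabels one fixed cohort with control-group sizes 5..95; since all
subjects are exchangeable, the pooled fraction of p < 0.05 estimates the
size of the test.  Distances and kernels are computed once per cohort and
shared across relabelings.

Problem sizes in the shipped test-suite runs: 200 replicates for power,
500 for Type-I, 5 seeds × 91 splits for the sweep, 200 iterations per
property experiment — large enough that the binomial confidence intervals
asserted in the tests are meaningful, small enough to keep the suite
practical on one core.

# Numerical choices

* Laplacian pseudo-inversion via symmetric eigendecomposition; eigenvalues
  below $10^{-9}\lambda_{\max}$ count as null.
* Pairwise $p=2$ distances through a Gram-matrix identity (BLAS), other
  $p$ through Minkowski distances on vectorised resistance matrices.
* The null logistic fit uses iteratively reweighted least squares
  (`glm.fit`) with tolerance $10^{-12}$ and at most 100 iterations;
  quasi-separation (fitted probabilities within $10^{-10}$ of 0/1) and
  score norms above $10^{-8}$ are errors, not warnings.
* Kernel PSD handling: for $p = 2$ the Gaussian kernel is PSD analytically
  and no spectral work is done; for other $p$ eigenvalues in
  $[-10^{-8}, 0)$ are clipped and anything lower is an error.
* Degenerate grid points ($\sigma_Q^2 \le 10^{-14}$) are skipped; at least
  two surviving points are required.
* `make_positive_definite()` shifts by $|\lambda_{\min}| + 0.1$ whenever
  $\lambda_{\min} \le 0.1$; the identity passes through untouched.

# Known limitations

* The Davies expression is an upper bound; the test is conservative by
  construction, and no exact characteristic-function inversion is offered.
* The distance is sensitive to near-disconnection: a single subject with a
  weakly bridged graph can dominate the distance matrix.  The generator's
  resampling keeps this rare at the defaults, but heavy-tailed distance
  rows are worth inspecting in any real application (`pairwise_rpd` output
  row sums are a quick diagnostic).
* Signed (negative-weight) graphs are handled formally: the Laplacian is
  built from signed row sums and positive semi-definiteness is not
  guaranteed; global efficiency and the rich club are undefined there.
* Binary outcomes only; no repeated measures.
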