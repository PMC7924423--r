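---
title: "Blind compressive normalization: model, design and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blind compressive normalization: model, design and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcnorm)
```

## The problem and the model

High-throughput matrices assembled from many experiments carry systematic
distortions from confounding factors: instrument settings, preparation
protocols, batch composition. When the confounders are unknown and
unannotated, neither supervised batch correction nor designed replication is
available, and distribution-forcing methods (quantile normalization) assume
the biological signal is exchangeable across samples — often false.

`bcnorm` models the observed matrix as $O = X + S$ with a biological signal
$S$ and an additive bias $X$ of low rank $r$: a limited number of
confounding factors, each contributing a rank-one pattern. Low rank is a
flexible approximation — any smooth bias surface is captured by a few
factors — and it is what makes *blind* recovery possible at all: a rank-$r$
$n \times m$ matrix has $r(n + m - r)$ degrees of freedom, far fewer than
$nm$, so comparatively few linear constraints pin it down.

The constraints come from redundancy. If two features (or two samples) are
strongly correlated in the signal, their centered observations should lie on
the line through the origin with slope $\sigma_2/\sigma_1$ in the pair's
plane. The orthogonal offset of each observed point from that line is
attributable to bias, and is a 2-sparse linear measurement of $X$:
coefficients $w$ (the line's unit normal) at the two positions, target
$y_i = w^\top o$. The recovery problem
$\min_X \|y - \mathcal{A}(X)\|_2^2$ s.t. $\operatorname{rank}(X) \le r$
is then standard compressed-sensing matrix recovery, and the corrected
matrix is $O - \hat X$.

Three assumptions matter:

1. **Sparsity of confounding** — the bias is (approximately) low rank.
2. **Detectable redundancy** — enough correlated pairs survive the
   confounding to be found; detection need only be specific, not sensitive,
   because measurements are abundant when the database is large.
3. **Incoherence** — the bias must not align with the redundancy structure;
   a bias that itself looks like the correlated pairs cannot be separated
   from signal.

## What each module contributes

* `estimateCorrelations()` finds pairs by Pearson correlation on
  pairwise-complete entries, keeping $|\hat\rho| \ge \tau$ with at least
  `minOverlap` shared observations (default 10). Pearson was chosen over
  rank correlations because the constraint geometry is itself linear.
  Negative correlations are kept and handled with a signed line direction.
  `oracleRedundancies()` substitutes the simulator's ground truth —
  the forced-accurate regime used by the benchmarks.
* `blindMeasurements()` emits one measurement per (pair, observation):
  coefficients are scaled to unit norm per measurement (option
  `coeffScale = "sigma"` keeps the raw $(\sigma_1, \sigma_2)$ scale) so
  every pair weighs equally in the least-squares objective. Duplicate
  (space, a, b) pairs are rejected at the container level; columns with a
  missing entry are skipped; pairs with non-positive standard deviation are
  skipped with a message.
* `recoverBias()` runs Riemannian conjugate gradient on the embedded
  fixed-rank manifold with truncated-SVD retraction. Gradients are
  assembled analytically from the sparse measurement entries — the dense
  automatic-differentiation route is the known memory bottleneck of generic
  manifold toolboxes on this problem, and avoiding it is what keeps the
  solver linear in the number of measurement nonzeros per iteration.
* `subtractBias()` subtracts the densified estimate; missing entries stay
  missing.

## Centering

The perfect-correlation line passes through the origin only for centered
data. `doubleCenter()` (row means of observed entries, then column means) is
the pre-processing step for real data, and the recovered matrix is then the
correspondingly centered bias. The simulated evaluations in this package
deliberately run with `center = FALSE`: the generator's signal is built
zero-mean and exactly proportional within correlated blocks (including the
group-design mean, see below), so the raw constraints are exact at the true
bias. This is what makes the zero-residual contract testable at $10^{-10}$
and recovery errors measurable against the uncentered ground truth, rather
than against a centered surrogate. Centering real data costs a little
constraint accuracy (column means are computed over all rows, mixing the
pair structure); this is a second-order effect when pairs are numerous.

## The simulator

`assembleDatabase()` emulates the structure the method relies on:

* **Signal** $S = M + A N B$, a matrix-variate normal draw. $A$ and $B$ are
  symmetric square roots of $D C D$ covariances, with $C$ block-structured:
  1 on the diagonal, $\rho$ within blocks, 0 elsewhere. Blocks occupy
  leading consecutive indices; the rest is uncorrelated background.
  Factors are built block-diagonal sparse, so correlation-fidelity checks
  with $10^5$ samples stay cheap. Eigenvalues of a block covariance that
  are numerically zero relative to the largest are clipped to exactly zero,
  so $\rho = 1$ blocks produce exactly proportional rows — the property the
  zero-residual contract rests on.
* **Standard deviations** are half-normal (scale `stdScale`, default 1) with
  a floor of 0.05 — a sub-gaussian spread, with the floor avoiding
  degenerate pairs; `"uniform"` is available.
* **Bias** $X = U \Sigma V^\top$ with $U, V$ uniform on the Stiefel manifold
  (QR of a Gaussian matrix, sign-fixed to a positive R diagonal so draws are
  backend-reproducible) and singular values from Uniform(0, 1), then
  rescaled so $\|X\|_F / \|S\|_F$ equals the configured ratio exactly —
  this keeps difficulty comparable across ranks.
* **Missingness**: MAR masks entries independently at the target rate; MNAR
  masks with probability $\propto$ logistic$(-k(v - \mathrm{median}))$
  rescaled to the target rate (low values more likely missing — the
  intensity-dependent dropout typical of proteomics), reducing to MAR as
  $k \to 0$. The logistic form is this package's choice; only the MAR/MNAR
  distinction itself is inherited from the problem setting.
* Every stage draws from its own seed substream, so a configuration is a
  complete, bit-reproducible description of a dataset.

What it does **not** emulate: count distributions and mean–variance
coupling, platform artefacts (GC content, probe affinities), nonlinear or
multiplicative bias, dependence between missingness and the bias itself.
Passing tests therefore demonstrate correct recovery of additive low-rank
confounding under Gaussian redundant signals — not performance on any real
platform.

## The benchmark design

The differential-expression benchmark (`runTable1()`) uses 40 genes × 30
samples: two 5-replicate groups (samples 1–5, 6–10) and 10 background
sample blocks of 2, all at $\rho = 1$; all 40 genes in 20 feature blocks
of 2 with `stdScale = 0.1`. Three design choices deserve explanation:

* **Replicates are exact copies** (sample standard deviations fixed at 1,
  perfect within-block correlation). The benchmark's published premise is
  that without corruption the group contrast is detected with essentially
  zero within-group variance — average p-values dozens of orders of
  magnitude below any significance level. Only exact replication reproduces
  that regime; any plausible nonzero replicate noise leaves the
  no-correction average p around $10^{-7}$, a qualitatively different
  (and weaker) baseline. With exact replicates, degenerate per-gene t-tests
  (zero pooled variance) score 0 when the group means differ, 1 otherwise.
* **Group shifts are proportional to each gene's standard deviation**
  ($\Delta_g = \sigma_g$, `effectSize = 1`). Proportionality keeps
  correlated genes exactly proportional *including* the shift, so the
  differential signal is part of the redundant structure rather than a
  violation of it. The magnitude is calibrated so that i.i.d. N(0, 1)
  corruption destroys detection (per-gene effects of a fraction of the
  noise standard deviation), mirroring the partially suppressed random-row
  averages the benchmark is expected to produce, while no-noise detection
  remains certain.
* **Groups are separate sample blocks**, so oracle sample pairs are
  within-group only. Pairing samples across groups would place the
  biological contrast itself into the bias constraints and make the method
  remove it — the incoherence assumption in miniature.
* **Systematic noise** is a rank-2 bias scaled to $\|X\|_F = \sqrt{nm}$, the
  expected Frobenius norm of the i.i.d. N(0, 1) matrix used in the random
  condition, so the two corruption rows are amplitude-matched.

## Solver numerics

* Iterates live on the embedded fixed-rank manifold as $U, \sigma, V$;
  the retraction is a truncated SVD of the ambient step, with singular
  values floored at $10^{-14} \sigma_1$ to step off the manifold boundary.
* Conjugate directions: Polak–Ribière with projection transport, reset to
  steepest descent whenever descent is lost; Armijo backtracking from the
  exact minimizer of the linearized objective.
* Stopping: Riemannian gradient norm below
  `gradientTolerance` × max(1, ‖y‖) (default $10^{-7}$), an iteration cap
  (default 500), or a failed line search at machine precision.
  Non-convergence is flagged in the diagnostics and raised as a warning,
  never silent.
* Initialization: random small-norm rank-$r$ point (Frobenius norm
  $10^{-2} \cdot$ median $|y|$) by default — small enough to sit in the
  basin of the zero matrix when the targets carry no signal; `"spectral"`
  initialization (truncated SVD of $\mathcal{A}^*(y)$, rescaled) is
  available. Default 3 restarts, best final objective wins.
* Heavily overdetermined measurement sets can destabilize conjugate
  gradient; `maxMeasurements` optionally subsamples to a cap.
* `selectRank()` splits measurements (default 25% held out), fits each
  candidate, scores held-out squared residual, and breaks exact ties toward
  the smaller rank (candidates are scanned in ascending order).

## Problem sizes used in the tests

The test and benchmark suites run at the evaluation scales of the method's
original validation: 50 × 50 matrices with 25 + 25 correlated pairs (2,500
available measurements), ranks 1–4, and the 40 × 30 benchmark with 5–10
simulation replicates per condition. The blind-vs-2-sparse equivalence
comparison is made at matched measurement counts with a small matched
relative target corruption (1% of rms $y$) on both operators: in the exactly
consistent noiseless setting both solvers converge to the numerical floor of
the optimizer, where error ratios reflect stopping thresholds rather than
operator quality; the matched corruption places both at a stable,
noise-determined error level where the comparison is meaningful.

## Known limitations

* **Estimated redundancies at small scale.** With correlations and standard
  deviations estimated from a confounded 50 × 50 matrix at bias amplitudes
  near the signal's, recovery is unstable: estimation errors in
  $\hat\sigma$ tilt the constraint lines, and false pairs inject wrong
  constraints. This matches the method's stated operating regime — large
  databases, high-specificity detection — and is why the benchmark forces
  accurate estimation. The estimated path is fully functional
  (`estimateCorrelations()` → `blindMeasurements(center = TRUE)`) and
  behaves well when the bias is weak relative to the signal and pairs are
  strong and abundant.
* **Scale.** Dense $n \times m$ iterates inside the solver limit practical
  use to hundreds × hundreds — adequate for the simulations; database-scale
  operation would need a factored-tangent implementation.
* **Identifiability up to centering.** Blind constraints are differences
  along pair structures; components of the bias constant along those
  structures (e.g. global row/column means) are not constrained and are
  resolved by the centering convention.
* The rank must be supplied or selected; nuclear-norm formulations and
  rank-pursuit warm starts are out of scope (naive grid search via
  `selectRank()` stands in).
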