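# bcnorm — blind compressive normalization

`bcnorm` removes unknown, low-rank confounding bias from feature × sample
high-throughput data matrices (gene expression, proteomics, metabolomics)
**blindly**: without quantitative standards, annotated batches, or prior
knowledge of the contrast of interest. It is aimed at researchers integrating
heterogeneous public data, where supervised batch correction (known
confounders, designed replicates) and distribution-forcing methods like
quantile normalization are either unavailable or rest on assumptions the data
do not satisfy.

## The model

The observed matrix is

    O = X + S,          rank(X) ≤ r ≪ min(n, m)

where `S` is the biological signal and `X` an additive bias produced by a
limited number of confounding factors, modeled as a low-rank matrix. Complex
systems are redundant: some feature pairs and sample pairs are strongly
correlated, and those correlations survive confounding well enough to be
*detected* even when their exact values are distorted. Each detected pair
yields constraints on `X`. In the plane of a correlated feature pair
(s₁, s₂), the signal lies on the perfect-correlation line through the origin
with slope σ₂/σ₁ (the ratio of the two standard deviations). For every
sample x where both entries are observed, the orthogonal offset of the
observed point (O[s₁,x], O[s₂,x]) from that line is attributable to the
bias. With w the unit normal of the line, this is one sparse linear
measurement

    ⟨A_i, X⟩ = w₁ O[s₁,x] + w₂ O[s₂,x] = y_i ,

and sample pairs contribute identically on the transpose. Collecting p such
measurements gives a compressed-sensing matrix recovery problem

    min_X ‖y − 𝒜(X)‖₂²   subject to   rank(X) ≤ r,   p ≪ nm,

solved here by Riemannian conjugate gradient on the fixed-rank manifold
(truncated-SVD retraction, analytic sparse gradients). The recovered bias is
subtracted to give the normalized matrix. Spike-in controls, when available,
enter the same problem as 1-sparse entry measurements.

The package also ships the full evaluation apparatus: a matrix-normal
simulator with block-structured redundancies and known ground truth,
k-sparse Gaussian sensing (the non-blind reference), measurement corruption
(noisy targets, shuffled pairs), hold-out rank selection, recovery sweeps,
and a differential-expression benchmark against quantile normalization.

## Worked example

Simulate the worst-case 50 × 50 evaluation database (all features and all
samples in perfectly correlated pairs, rank-2 bias as strong as the signal),
build blind measurements from the pair structure, recover, and subtract:

```r
library(bcnorm)

db    <- assembleDatabase(evaluationConfig(biasRank = 2, seed = 1))
pairs <- oracleRedundancies(db)           # 25 feature + 25 sample pairs
mset  <- blindMeasurements(observedMatrix(db), pairs, center = FALSE)
measurementCount(mset)
#> [1] 2500

mset60 <- sampleMeasurements(mset, 1500, seed = 1)   # use 60% of them
fit <- recoverBias(mset60, rank = 2, solverSettings(seed = 1))
fit
#> LowRankEstimate: 50 x 50, rank 2
#>   singular values: 53.66, 7.994
#>   solver: objective 2.104e-11, grad norm 3.5e-06, 150 iterations, converged

relativeError(fit, biasMatrix(db))
#> [1] 3.09e-07
corrected <- subtractBias(observedMatrix(db), fit)
max(abs(corrected - signalMatrix(db)))
#> [1] 2.61e-06
```

The bias — as large as the signal in Frobenius norm — is recovered to a
relative error of 3 × 10⁻⁷ from 60% of the available pair constraints, and
subtracting it restores the signal to within 3 × 10⁻⁶ per entry. When the
rank is not known, hold-out selection recovers it:

```r
selectRank(mset60, 1:4, settings = solverSettings(restarts = 2, seed = 1))$rank
#> [1] 2
```

The differential-expression benchmark (40 genes, 30 samples, two 5-replicate
groups; blind recovery with oracle redundancies vs quantile normalization vs
no correction, under random / systematic rank-2 / no corruption):

```r
runTable1(seed = 101, nReps = 10)$summary
#>     condition method    medianAvgP call
#> 1        none    BCN  4.887254e-76    +
#> 2      random    BCN  4.475447e-01    -
#> 3  systematic    BCN  5.021265e-42    +
#> 4        none     NC 2.156675e-119    +
#> 5      random     NC  5.134226e-01    -
#> 6  systematic     NC  5.491604e-01    -
#> 7        none     QN  1.250000e-02    +
#> 8      random     QN  5.144656e-01    -
#> 9  systematic     QN  4.883397e-01    -
```

Read: the cell value is the median (over 10 simulated replications) of the
average per-gene two-sided t-test p-value between the replicate groups; `+`
marks detection at the 0.05 level. Systematic low-rank corruption hides the
group differences from quantile normalization and from no correction, while
blind compressive normalization removes it and restores decisive detection —
i.i.d. random noise, having no low-rank structure, defeats all three, as it
must.

A command-line surface over the same functions is installed at
`system.file("cli/bcn.R", package = "bcnorm")` with subcommands `simulate`,
`estimate`, `recover`, `normalize`, `benchmark` and `sweep` (TSV in/out, JSON
config echoes, `--seed` everywhere).

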