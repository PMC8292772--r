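# glvident

Structural and practical identifiability of the generalized
Lotka–Volterra (gLV) model when only **relative abundances** are
observed — the situation of essentially every amplicon-sequencing
time-series study, where read counts estimate composition but the
absolute size of the community is lost.

The gLV model for an *n*-taxon community is

```
(1/N_i) dN_i/dt = r_i + Σ_j β_{i,j} N_j ,      i = 1, …, n
```

with per-capita growth rates `r_i` and interaction rates `β_{i,j}`
(the effect of taxon *j* on the per-capita growth of taxon *i*;
`K_i = −r_i/β_{i,i}` is the carrying capacity). The package
establishes, and lets you re-derive and stress-test, the two headline
facts about fitting this model to compositional time series:

* **Structural** — by exact symbolic elimination of the unobserved
  total (a differential-algebra input–output relation for the
  two-species system, built on an exact sparse-polynomial engine
  shipped in the package): the growth rates `r_i` are uniquely
  identifiable, while the interaction rates are identifiable **only up
  to one common scale factor** (gauge `β_{2,2}`). Numeric
  scale-invariance and distinguishability checks extend the statement
  to communities of 3–5 taxa.
* **Practical** — a bootstrap particle filter (C++) with multinomial
  read-count weights plus an adaptive particle marginal
  Metropolis–Hastings sampler shows that with multiplicative
  environmental noise (σ = 0.1) and sequencing depth V = 500 the
  parameters of a three-species community are recovered to within
  ≈ 20% relative error, and that the population **fold change**
  `N(t)/N(0)` is recoverable from composition alone even though the
  absolute scale is not.

It also ships the synthetic-data generator used by all experiments:
Euler–Maruyama integration of the stochastic gLV system
(`dN_i = N_i(r_i + Σ_j β_{i,j}N_j)dt + σ_i N_i dW_i`) with Dirichlet
or multinomial sequencing noise at fixed read depth.

Intended users: microbiome/ecology researchers deciding whether their
compositional time series can support gLV-style interaction inference,
and methods developers who need a clean, fully tested reference
implementation of the identifiability argument and the particle-MCMC
experiment.

## Worked example

```r
library(glvident)

## the reference three-species community (value set 1)
p1 <- referenceParameters(1)
p1
#> GLVParameters: 3 species
#>   r: 6, 4, 2
#>   B:
#>       sp1      sp2      sp3
#> sp1 -0.05  0.15000 -0.20000
#> sp2 -0.01 -0.02667  0.05000
#> sp3  0.10 -0.10000 -0.01481
carryingCapacities(p1)
#> sp1 sp2 sp3
#> 120 150 135

## the scale gauge: (r, 100B) from X0/100 gives the same composition
numericScaleInvarianceCheck(p1, 100, c(10, 14, 4), defaultTimes())
#> [1] 1.260426e-08
```

The deviation between the two relative-abundance trajectories is at
integrator tolerance — the two systems are observationally identical
in composition even though their absolute abundances differ 100-fold.

```r
## symbolic structural verdict for the two-species system
rel <- makeMonic(deriveIORelation(),
                 at = c(r1 = 6, r2 = 4, b11 = -0.05, b12 = 0.15,
                        b21 = -0.01, b22 = -2/75))
solveAlternativeParameters(rel)
#> Structural identifiability verdict (relative-abundance data):
#>   identifiable:       r1, r2
#>   up to common scale: b11, b12, b21, b22
#>   gauge parameter:    b22
#>   solution family dimension: 1
#>      r1 = a1
#>      r2 = a2
#>      b11 = (a3/a6) * b22
#>      b12 = (a4/a6) * b22
#>      b21 = (a5/a6) * b22
#>      b22 = free scale (gauge)
```

The verdict is certified three ways at once: exact homogeneity of
every input–output coefficient in the interaction rates, Jacobian rank
5/6 with the null direction along the pure interaction-scale
direction, and a numeric re-solve for alternative parameters at
different gauge values.

```r
## a noisy synthetic dataset (sigma = 0.1, V = 500, dt = 0.001)
d <- makeSyntheticDataset(valueSet = 2, seed = 1)
d$counts
#> ObservedCounts: 51 samples x 3 taxa, depth V = 500
head(readCountMatrix(d$counts), 3)
#>      sp1 sp2 sp3
#> [1,] 170 264  66
#> [2,] 202 251  47
#> [3,] 270 194  36

## practical recovery with the reduced particle-MCMC budget (~2 min)
res <- runExperiment(experimentConfig("practical", valueSet = 2,
                                      budget = "reduced", seed = 1))
res$result$fractionWithin20pct
#> [1] 0.75
```

Three quarters of the 12 gLV parameters land within ±20% of their true
values from composition-only data; every retained draw is inside the
±40% prior box by construction. See the vignette
(`vignettes/glv-identifiability.Rmd`) for the model, the elimination,
the noise models, the sampler protocol and the package's design
choices.

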