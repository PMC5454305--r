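# lossyRD

Rate–distortion analysis of lossy perceptual coding in random environments.

## The problem

Perception is costly: the more faithfully an organism tracks its
environment, the more resources its sensory machinery consumes. Rate–
distortion theory makes the trade-off precise. The environment has `N`
states (uniform, so complexity is `log2 N` bits); a stochastic codebook
`p(x̂|x)` maps states to percepts; the **rate** `R = I(X; X̂)` (bits)
measures the perceptual resource cost; the **distortion**
`D = Σ p(x) p(x̂|x) d(x, x̂)` measures the average cost of confusions,
priced by a distortion matrix `d` with zero diagonal. The rate–distortion
function `R(D)` — the least rate achieving distortion `D` — is computed by
the Blahut–Arimoto fixed point

    p(x̂|x) ∝ r(x̂) · exp(−β · d(x, x̂)),   r(x̂) = Σ_x p(x) p(x̂|x),

which minimizes `I(X; X̂) + β·D` at each gain `β`; sweeping `β` traces the
curve.

Environments are modelled as random matrices whose off-diagonal entries are
i.i.d. shifted exponential or lognormal (plus a pairwise-correlated
variant). Every such environment has a **minimal confound**
`d_min = min_{x≠x̂} d(x, x̂)`, and it divides the trade-off in two:

* `D > d_min` (low fidelity): `R(D)` asymptotes to a constant as `N`
  grows — bounded by `log2(1 / P(d < D))`, independent of `N` (about 6.6
  bits at `D` = 1% of the mean confusion cost, 10 bits at 0.1%, for the
  unit exponential);
* `D < d_min` (high fidelity): `R(D)` grows linearly in `log2 N`, between
  `(1 − D/d_min)·log2 N` and `(1 − D/⟨d⟩)·log2 N`.

The package is for theorists and modellers in sensory ecology and
theoretical neuroscience who want these curves, bounds and scaling
experiments as tested, reproducible building blocks.

## Worked example

```r
library(lossyRD)

spec <- environmentSpec("exponential", shift = 1, nStates = 50, seed = 7)
dm <- drawMatrix(spec)
dm
#> DistortionMatrix: 50 states
#>   minimal confound d_min = 1 | <d> = 2.004 | d_max_useful = 1.64
#>   drawn from exponential ensemble (shift 1, seed 7)

curvePoints(sweepCurve(dm, nPoints = 6))[, 1:4]
#>      beta rate_bits distortion iterations
#> 1 16.0000    5.6438     0.0000          2
#> 2  3.4238    3.5781     0.3279         16
#> 3  2.6187    2.1634     0.6558         60
#> 4  2.0005    1.0705     0.9837       1000
#> 5  1.1533    0.3138     1.3115       1000
#> 6  0.0000    0.0000     1.9644          2
```

Reading the curve: lossless coding of 50 states would cost
`log2 50 ≈ 5.64` bits (the first point, distortion ~0); tolerating average
distortion 0.98 — just below the minimal confound 1 — costs only 1.07
bits; at 1.96 (the cost of random guessing) perception is free. Bounds and
regime at a target distortion:

```r
boundsReport(dm, 0.5)[c("regime", "uniform_env_lb", "uniform_alloc_ub", "synonym_ub")]
#> $regime          "high-fidelity"
#> $uniform_env_lb  1.84     # Hamming-type lower bound, bits
#> $uniform_alloc_ub 3.43    # explicit sub-optimal codebook, bits
#> $synonym_ub      5.64     # synonym-count bound (no synonyms below d_min)

requiredGainEmpirical(dm, 0.5)   # minimal gain to hold D <= 0.5
#> [1] 2.957031
```

The two scaling regimes, with bootstrap intervals and the slope against
`log2 N`:

```r
ens <- runEnsemble(family = "exponential", shift = 1,
                   Nlist = c(20L, 50L, 100L), Dtargets = c(0.5, 1.5),
                   nSamples = 10L, seed = 1L)
cells(ens)
#>     N D_target mean_rate_bits   ci_low ci_high mean_beta n_samples
#> 1  20      0.5        1.99164 1.979079 2.00292    2.2998        10
#> 2  50      0.5        2.78255 2.778814 2.78604    2.9676        10
#> 3 100      0.5        3.37730 3.375775 3.37859    3.4923        10
#> 4  20      1.5        0.01283 0.006618 0.01910    0.1716        10
#> 5  50      1.5        0.07691 0.071363 0.08278    0.5352        10
#> 6 100      1.5        0.12816 0.121887 0.13442    0.6687        10

regimeSlope(ens, 0.5)
#>       slope      stderr
#> 0.596850094 0.001001642   # inside [1 - D/d_min, 1 - D/<d>] = [0.5, 0.75]
```

Below the confound (`D = 0.5`) the mean rate climbs steadily with `N` and
the fitted slope sits inside the analytic bracket; above it (`D = 1.5`)
successive doublings of `N` add less and less rate — the low-fidelity
asymptote. The `mean_beta` column shows the same split for the gain an
organism needs.

A thin command-line wrapper over the same functions lives at
`inst/cli/lossyrd.R` (subcommands `generate-env`, `rd-curve`, `bounds`,
`ensemble`, `required-beta`; global `--seed`, `--config`, `--out-dir`,
`--log-level`).

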