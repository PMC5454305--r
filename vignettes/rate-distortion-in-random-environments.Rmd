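---
title: "Rate-distortion analysis of perception in random environments"
author: "lossyRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-distortion analysis of perception in random environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lossyRD)
```

## The model

An organism lives in an environment with $N$ states, drawn uniformly
($p(x) = 1/N$, so the environmental complexity is $H[X] = \log_2 N$ bits).
Its perceptual system is a stochastic *codebook* $p(\hat x \mid x)$ mapping
each true state to a percept. Two costs compete:

* the **rate** $R = I(X;\hat X)$ in bits — the information the perceptual
  channel must carry, a proxy for the size and energy budget of the sensory
  apparatus; and
* the **distortion** $D = \sum_{x,\hat x} p(x)\,p(\hat x|x)\,d(x,\hat x)$ —
  the average fitness cost of acting on a mistaken percept, where the
  distortion matrix $d(x,\hat x) \ge 0$, with $d(x,x)=0$, prices every
  possible confusion.

The rate-distortion function $R(D)$ is the smallest rate achieving average
distortion $D$. We compute it by minimizing the Lagrangian
$\mathcal{L} = I(X;\hat X) + \beta D$ at a sweep of gains $\beta$, using the
Blahut-Arimoto fixed-point iteration

$$p_{t+1}(\hat x \mid x) \;\propto\; r_t(\hat x)\, e^{-\beta d(x, \hat x)},
\qquad r_t(\hat x) = \sum_x p(x)\, p_t(\hat x \mid x).$$

Each full update can only decrease $\mathcal{L}$ (alternating minimization
of a convex problem), which is the convergence monitor the solver uses.
Internally the objective is tracked in nats ($I_{\mathrm{nats}} + \beta D$),
the form with guaranteed monotone descent under the $e^{-\beta d}$
reweighting; all reported rates are in bits.

## Random environments and the two regimes

Environments are modelled as random distortion matrices: the $N(N-1)$
off-diagonal entries are i.i.d. from a shifted exponential or lognormal
distribution with support $[d_{\min}, \infty)$. The shift is the ensemble's
**minimal confound** $d_{\min}$ — the cheapest possible confusion — and it
splits the trade-off into two regimes:

* **low fidelity** ($D > d_{\min}$): harmless near-synonyms accumulate as
  $N$ grows, and the rate needed for distortion $D$ asymptotes to a
  constant, bounded by the quantile bound
  $R(D) \le \log_2\!\big(1/P(d < D)\big)$, independent of $N$. For the
  unit-mean exponential this ceiling is $\approx 6.6$ bits at $D$ equal to
  1% of the mean confusion cost and $\approx 10$ bits at 0.1%;
* **high fidelity** ($D < d_{\min}$): the rate grows linearly in
  $\log_2 N$, bracketed between $(1 - D/d_{\min})\log_2 N$ (from the
  uniform-penalty environment whose exact Hamming-type $R(D)$ lower-bounds
  the true one) and $(1 - D/\langle d \rangle)\log_2 N$ (from the explicit
  uniform-allocation codebook), where $\langle d \rangle$ is the mean
  off-diagonal distortion.

The gain $\beta$ needed to hold distortion at a target behaves the same
way: linear growth in $\log_2 N$ below the confound, saturation above it.
A continuous Gaussian environment under squared error
($R(D) = \tfrac12\log_2(\sigma^2/D)$ for $D<\sigma^2$) has no low-fidelity
regime; it takes discrete structure for one to appear.

```{r quick-example}
dm <- drawMatrix(environmentSpec("exponential", shift = 1, nStates = 50,
                                 seed = 1))
dm
solveRDPoint(dm, beta = 3)
```

## What the generator emulates — and what it does not

`drawMatrix()` reproduces the study conditions exactly: zero diagonal,
i.i.d. shifted-exponential or lognormal off-diagonal entries (shift 0, 1 or
20 in the canonical settings, unit exponential mean above the shift), and a
pairwise-correlated variant in which each entry is replaced by the average
of itself and one uniformly chosen other entry (`correlateMatrix()`, which
preserves the support floor and the ensemble mean, and records its pairings
for testability). The lognormal comparison ensemble is pinned to the
exponential one by a single quantile constraint via
`calibrateLognormal()`: the probability of a confusion cheaper than a small
threshold is matched. That constraint under-determines the two lognormal
parameters, so the log-sd is exposed as a free parameter (default 1) and
only the log-mean is solved for.

These are deliberately *unstructured* environments: entries are
exchangeable (or weakly pairwise-correlated), there is no block or
hierarchical structure, no non-uniform source, and no temporal dynamics.
Tests passing on these ensembles say nothing about environments whose
synonym counts fail to scale proportionally with $N$ — hierarchically
organized distortions are exactly the case the theory flags as different.

## Numerical choices

* **Rates and logs.** Bits ($\log_2$) everywhere in reported quantities;
  $0 \log 0 = 0$.
* **Stability.** The exported single step `baStep()` works in the log
  domain (per-row max subtracted before exponentiation). The iteration
  loop inside `solveRDPoint()` exploits that $e^{-\beta d}$ is
  loop-invariant: it is computed once per $\beta$, and because the diagonal
  contributes an exact $e^0 = 1$ to every row, plain-domain updates are
  safe; a guard falls back to the log-domain step if a row's partition
  function ever underflows.
* **Convergence.** Default `maxIter = 1000`, `tol = 1e-10` on the change of
  the alternating-minimization objective $-\sum_x p(x)\log Z_x$ (the
  Lagrangian evaluated through the per-row partition function, free to
  compute). `tol = 0` recovers the fixed-iteration-count mode.
* **Initialization.** The uniform codebook at every $\beta$ — the problem
  is convex, so warm starts buy speed but are not needed for correctness,
  and cold starts keep every solve independent.
* **Distortion targeting.** $D_\beta$ is monotone non-increasing in
  $\beta$, so `solveAtDistortion()` brackets by doubling $\beta$ from
  $[0, 1]$ and bisects until $|D_\beta - D^\ast| < 10^{-4} \cdot
  D_{\max}$ or the bracket is narrower than $10^{-8}$ ($\beta$ capped at
  $2^{20}$). Targets at or above the $\beta = 0$ distortion return the
  zero-rate solution.
* **Curve sweeps.** `sweepCurve()` places targets evenly on
  $[0, D_{\max}]$, where $D_{\max}$ (`dMaxUseful`) is the distortion of the
  best single-percept codebook — the exact point where $R(D)$ reaches 0,
  which makes the endpoint attainable. The curve is closed with the exact
  $\beta = 0$ point (rate 0 at the uniform-codebook distortion). An
  all-zero matrix yields the single point $(R, D) = (0, 0)$.
* **Degenerate inputs.** Matrices are stored rows = true state, columns =
  percept; the synonym count uses the strict inequality $d < D$ and counts
  the state itself (its self-distortion 0 is always $< D$), matching the
  $P(d < D)$ convention of the quantile bound.

## Ensemble experiments

`runEnsemble()` draws `nSamples` matrices per environment size, measures
the optimal rate (and the gain required) at each distortion target, and
aggregates each $(N, D)$ cell with a percentile bootstrap of the mean
(1000 resamples, 68% interval by default — the bootstrap variant is not
pinned down by the analysis, so the simplest percentile method is used).
Two measurement modes exist: the default `"target"` mode bisects $\beta$
directly at each requested distortion, which is exact at the target and
cheaper; `"curve"` mode sweeps a full curve per draw and interpolates with
`rateAtDistortion()`, as one would when tracing whole rate-distortion
functions. The two agree to the bisection tolerance (this is tested).

All randomness flows from one root seed through `deriveSeed(root, task,
index)`, so execution order cannot change results; manifests record the
config, every derived seed and a content hash per matrix, and a rerun from
the same config and seed reproduces the result CSVs byte for byte.

Default experiment sizes — $N \in \{20, 50, 100\}$, 10 samples per size,
distortion targets $\{0.5, 1.5\}$ straddling the shifted-exponential
confound $d_{\min} = 1$ — are desk-scale choices that already separate the
two regimes cleanly; the full-figure settings ($N$ up to 200, 25-50
samples) are a config change (`N_list`, `n_samples`), not a code change.
`regimeSlope()` fits the mean rate against $\log_2 N$ by unweighted least
squares (bootstrap-variance weighting is available via `weighted = TRUE`);
in the high-fidelity regime the fitted slope should sit inside
$[1 - D/d_{\min},\, 1 - D/\langle d \rangle]$, and it does at these sizes.

## Known limitations

* Only stochastic codebooks: deterministic (hard-clustering) coding, which
  adds memory constraints, is out of scope.
* Single-letter coding only — no blocked/multi-letter schemes.
* The uniform source is assumed by the ensemble and bounds machinery;
  `rateOf`/`distortionOf`/`solveRDPoint` accept general sources.
* No fitness dynamics: the evolutionary interpretation (organisms poised
  at $D \approx d_{\min}$) is read off the computed curves and gain
  requirements, not simulated.
* Bisection assumes the strict monotonicity of $D_\beta$ in $\beta$, which
  holds for these ensembles but can plateau for matrices with large exact
  ties; the solver then returns the closest achieved point and says so via
  the `converged` flag and iteration count.
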