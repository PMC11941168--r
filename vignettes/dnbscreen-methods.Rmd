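---
title: "Models and methods behind dnbscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnbscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnbscreen)
```

## Scope

`dnbscreen` implements three connected pieces of methodology:

1. **DNB detection** — locating the pre-disease stage of an ordered
   expression series and the gene module driving it, from per-stage
   fluctuation and correlation statistics;
2. **intervention ranking** — ordering genes by the absolute entries of the
   dominant eigenvector of the pre-disease sample covariance matrix;
3. **a generative testbed** — a planted-module stochastic network model with
   exact stationary statistics, used both to ground-truth the first two
   pieces and to validate selected targets by simulated stabilization.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the known limits — in particular what the HDLSS
(high-dimensional low-sample-size) regime does and does not allow.

## The generative model

The simulator draws expression as a stationary linear (Ornstein–Uhlenbeck)
stochastic system

$$dx = A(p)\,x\,dt + L\,dW, \qquad A(p) = A_0 + pB, \qquad Q = LL^\top,$$

with $A_0 = -I$ (unit self-degradation), diffusion $Q = qI$, and a scalar
control parameter $p \in [0,1)$ that moves the system toward its stability
boundary as disease progresses. This linear form is the natural testbed
because DNB statistics are derived from the linearization of a nonlinear
system near a codimension-one bifurcation; everything the detector is
supposed to see (one collective mode slowing down and inflating) is present,
and everything else is controlled.

$B$ is zero outside a planted module of $m$ genes. Inside the module it
combines symmetric positive couplings $w = c/m$ (argument `intra_coupling`
$= c$) with a uniform diagonal increment $d = 1 - w(m-1)$, which calibrates
the leading eigenvalue of $A(p)$ to exactly $-(1-p)$. Two consequences:

* the module's collective (uniform) mode has stationary variance
  $q/(2(1-p))$, diverging as $p \to 1$ — the early-warning fluctuation;
* its transverse modes have eigenvalue $-(1 + p(c-1))$, so for strong
  coupling the module's genes become almost perfectly correlated near the
  transition.

Samples are drawn i.i.d. from the exact stationary law (mean `mu`,
covariance solving the Lyapunov equation $A\Sigma + \Sigma A^\top + Q = 0$),
plus i.i.d. per-gene Gaussian measurement noise (sd 0.1). Exact stationary
sampling rather than trajectory integration keeps the generator fast and its
ground truth analytic; a Euler–Maruyama trajectory simulator is retained in
the test suite as an independent oracle for the Lyapunov solutions.

### Default parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_genes` | 500 | HDLSS regime at realistic cost |
| `dnb_size` | 10 | small module, as DNB theory assumes |
| `schedule` | 0.1, 0.3, 0.5, 0.7, 0.95 | five ordered stages approaching the boundary |
| `n_samples_per_stage` | 8 | few samples per stage (genes ≫ samples) |
| `intra_coupling` | 20 | strongly co-fluctuating module: within-module \|r\| ≈ 0.97 at $p=0.95$ — the "sharply increased correlation" regime the theory describes |
| `noise_scale` (q) | 1.0 | process noise dominates the fixed measurement sd 0.1 (~1% of variance), as for decently replicated array data |
| `meas_noise_sd` | 0.1 | i.i.d. Gaussian measurement error |
| `mu_range` | 6–10 | array-like baseline log-intensities |

The coupling default deserves a note. With weak coupling the planted module
is nearly undetectable at $n = 8$: each gene's share of the collective-mode
variance is only $1/(m(1-p)) = 2\times$ its baseline variance at $p = 0.95$,
and sample correlations at 8 samples carry noise of order 0.35. A pilot
power analysis across coupling values showed that only the strongly coupled
regime gives the detector a fair target; the generator therefore defaults to
it, and weaker regimes remain available through `intra_coupling` for power
studies.

### Seed policy

`generate_stage_series()` derives one child seed per stage from the master
seed by the fixed rule `child_seed(seed, i) = (1009·seed + 9973·i) mod
(2^31 − 1)`; all draws run under a private RNG state that never disturbs the
caller's stream. Identical seeds give byte-identical series across the whole
module.

## Detection

Per stage, `compute_stage_stats()` returns per-gene sample standard
deviations (denominator $n-1$) and absolute Pearson correlations on the
values as given; any log transform is the caller's preprocessing (`log2`
flag, default off). Constant genes are masked — stored as zero correlation
with a mask — rather than dropped, so gene indexing is stable across stages.

Candidate modules are formed by average-linkage hierarchical clustering on
the distance $1 - |r|$, cut at $1 - $ `corr_link_min`. Each cluster of at
least `min_module_size` genes is scored with the composite index

$$I = \mathrm{sd}_{in} \cdot r_{in} / \max(r_{out}, \varepsilon),$$

and the stage whose best cluster maximizes $I$ is called pre-disease (ties
toward the earlier stage: an earlier warning is preferred). The peak is
flagged significant when it reaches `peak_ratio_min` (default 2) times the
median of the other stages' best indices; a zero peak is never significant.

### Why these defaults

* `sd_fold_min = 1` (pass-through prefilter). At $n = 8$ the ratio of two
  per-gene sample sds carries $F(7,7)$ noise whose central 90% range spans
  roughly $[0.55, 1.8]^{1/2}$-fold; worse, all module genes share one 7-df
  fluctuation of the collective mode's sample variance, so an informative
  fold threshold drops *the whole module at once* in a sizeable fraction of
  datasets. The fold filter is kept as an explicit option for long series or
  larger $n$, but the default must not gamble the module on a noisy ratio.
* `corr_link_min = 0.9`. At a lenient cut (say 0.6), average-linkage
  chaining among hundreds of genes routinely assembles spurious
  six-to-eight-gene "modules" from chance correlations (pairwise $|r| \ge
  0.6$ has null probability ≈ 0.12 at $n=8$) whose composite index rivals a
  genuine module's. At 0.9 such chains effectively vanish while a strongly
  coupled module (true $|r| \approx 0.97$) still clusters.
* `min_module_size = 6`. A DNB is by premise a *group* of genes; pairs and
  triplets passing a high correlation bar at $n = 8$ are still within reach
  of chance. Six is small enough to find a ten-gene module even when
  sampling splits it, large enough that chance cliques are negligible
  (pure-noise series yield no qualifying cluster at all, so the null
  false-positive rate of the significance flag is ~0).
* `eps = 1e-6` merely guards division when a module is uncorrelated with
  every outsider (e.g. all outsiders constant).

These settings were fixed once, from simulation-based power analysis of the
generator's default regime, before the package's acceptance checks were
written, and are all exposed in `dnb_config()`.

## Intervention ranking

`sample_covariance()` is the ordinary $n-1$ covariance with genes as
variables. The *covariance* (not correlation) matrix is eigenanalyzed by
design — the index should weight genes by how much absolute fluctuation they
carry, not just by pattern membership; a standardize-first analysis can be
had by passing standardized data.

`dominant_eigen()` uses the dense symmetric eigensolver; when the input is
an expression matrix with fewer samples than genes, the package instead
takes the SVD of the centered data (the HDLSS path — an $O(pn^2)$
computation rather than $O(p^3)$). Both paths agree to $10^{-8}$ and are
cross-checked against a power-iteration oracle in the tests. The eigenvector
sign is fixed by requiring the largest-magnitude entry to be nonnegative
(ties to the lowest index); ranking ties are broken lexicographically by
gene id, so every ranking is deterministic.

Selection is fixed-$k$ (default $k = 10$) with the reported `threshold`
equal to the $k$-th index value — the height of the cut-off line in an
index-versus-gene plot. A largest-gap heuristic (`method = "gap"`) is
provided for users who prefer a data-driven cut. Near-degenerate spectra
(relative eigengap below 0.05) produce a warning flag, not an error: HDLSS
data legitimately yield nearly degenerate trailing spectra, and the caller
should know when the leading direction is poorly determined.

An optional mode restricts the covariance to detected DNB members before
eigenanalysis (`restrict_to_dnb`); the default analyzes all profiled genes,
which matches ranking the entire gene complement.

## Intervention simulation

Because the direction of a real intervention (suppress vs promote) cannot be
read off the covariance eigenvector, the simulator implements magnitude-only
stabilization: each target's drift diagonal gains self-degradation
$A_{ii} \leftarrow A_{ii} - c$ (default strength 0.5). For this model class
added damping can only lower the leading eigenvalue and the stationary
variance, which the tests assert on a strength grid.

`compare_to_random()` benchmarks the top-$k$ selection against uniformly
random $k$-sets by post-intervention total stationary variance. Exact ties
count one half (the Mann–Whitney convention). The no-module control is a
zero-coupling network evaluated at the healthy baseline $p = 0$, where the
network is exactly homogeneous: every target set is equally effective, all
comparisons tie, and the fraction is exactly 0.5 — the no-advantage value.
The control is *not* run at high $p$: under the calibration the module's
diagonal destabilization exists even with zero coupling, so its genes would
be genuinely better targets there and random sets would rightly lose.

## Numerical choices

* **Lyapunov solver.** For symmetric drift (every model this package
  builds) the solution is computed in the drift's eigenbasis,
  $\tilde\Sigma_{ij} = -\tilde Q_{ij}/(\lambda_i + \lambda_j)$; the residual
  $\|A\Sigma + \Sigma A^\top + Q\|_F / \|Q\|_F$ stays below $10^{-8}$
  (tested; typically $10^{-14}$). Small non-symmetric systems fall back to
  the Kronecker vectorized solve ($O(n^6)$, capped at $n = 200$). Drift
  matrices with a nonnegative leading eigenvalue raise a
  no-stationary-distribution error.
* **Stationary sampling** factorizes $\Sigma = V\,\mathrm{diag}(q/(-2\lambda))\,V^\top$
  directly from the drift eigendecomposition (one decomposition per stage),
  clipping eigenvalues at zero before the square root.
* **TSV round-trips** serialize at 12 significant digits; readers validate
  shape, uniqueness and numeric-ness with line-numbered parse errors, and
  metadata/matrix sample sets are cross-checked with the orphan ids named.

## What the generator does and does not emulate

It emulates: ordered stages with few samples each; thousands of genes; one
small module whose variance and internal correlation rise sharply at the
critical stage; stationarity within a stage; additive measurement noise.

It does **not** emulate: count-based (RNA-seq) noise, microarray
normalization artifacts, batch effects, heavy-tailed or skewed expression,
multiple interacting modules, nonlinear dynamics beyond the stability
boundary, or drift between samples within a stage. Passing tests on this
generator therefore demonstrates correctness of the statistics and the
machinery in the regime the theory describes — not robustness to every
failure mode of real transcriptomics data.

## Known limitations

* **Eigenvector recovery at $n = 8$ is fundamentally capped.** The planted
  collective mode's eigenvalue is $q/(2(1-p_{max})) = 20\times$ the bulk
  per-gene variance $q/2$, while the noise eigenvalues of an $n = 8$,
  $p = 500$ sample covariance scale like $(q/2)\,p/n \approx 62\times$ the
  bulk. The spike sits *below* the HDLSS detectability boundary of spiked
  covariance models (Jung & Marron 2009; Baik–Ben Arous–Péché-type
  thresholds), so the dominant sample eigenvector is not consistent for the
  planted direction: across replicates it either locks onto the module or
  onto a noise direction. The top-10 *gene ranking* is more forgiving than
  the full direction — `scripts/acceptance.R` recomputes its mean overlap
  with the planted module over 25 replicates — but no free parameter of this
  model class can push it toward full recovery while the calibration
  $\lambda_{max}(A) = -(1-p)$, the stage grid, and $n = 8$ stand. Detection,
  which pools correlation structure rather than estimating one direction, is
  far less affected (the recovery rate is recomputed over 50 replicates by
  the same script).
* **Total variance need not rise monotonically in $p$.** With strong
  coupling the module's transverse modes stiffen as $p$ grows, so
  $\mathrm{tr}\,\Sigma(p)$ dips at small $p$ before the collective mode
  takes over; fluctuation concentrates rather than simply growing. The
  monotone-trace property holds for weakly coupled modules ($c \lesssim 1$)
  and, for the default model, for the dominant eigenvalue of $\Sigma(p)$ —
  both are asserted in the tests in exactly those forms.
* **The significance rule is a stand-in.** The peak-to-median ratio (default
  2) is deterministic and cheap, controls the pure-noise false-positive rate
  well under the defaults, but is no substitute for a permutation test when
  stages are many and modules weak.

## Problem sizes used by the shipped checks

Unit tests run on fixtures of 2–80 genes; property checks use 20–25 random
fixtures each. The simulation-based checks use the default 500-gene
configuration: 50 replicates for stage recovery, 25 for ranking overlap, 100
random draws (plus 100 for the homogeneous control) for the intervention
benchmark, and Euler–Maruyama oracle runs of $10^7$ (2 genes) and
$2\times10^6$ (40 genes) steps. The full suite completes in about a minute
on one CPU; `scripts/acceptance.R` in well under two.
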