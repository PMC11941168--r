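# dnbscreen

Detection of the **pre-disease state** in stage-wise gene-expression data via
dynamical network biomarker (DNB) statistics, and **intervention-target
ranking** by the dominant eigenvector of the pre-disease sample covariance
matrix — with a ground-truthed stochastic network simulator and an in-silico
intervention validator.

## The problem

Complex diseases often pass through an unstable transitional regime — a
*pre-disease state* — just before the critical transition from a healthy to a
disease state. DNB theory predicts that as a biological network approaches
such a tipping point, a small group of genes (the DNB module) starts to
fluctuate strongly and coherently: per-gene standard deviations and
within-group absolute Pearson correlations rise sharply while the group's
correlation to the rest of the network does not. `dnbscreen` is for
computational biologists who want to (i) locate that stage and module in
ordered, high-dimensional low-sample-size (HDLSS) expression series, and
(ii) prioritize genes for intervention once the pre-disease state is found.

## Methods in brief

**Detection.** For each stage the package computes per-gene sample standard
deviations and absolute Pearson correlations, clusters candidate genes by
average linkage on the distance `1 − |r|`, and scores each module by the
composite early-warning index

```
I = sd_in · r_in / max(r_out, ε)
```

(`sd_in`: members' mean standard deviation, `r_in`: mean within-module |r|,
`r_out`: mean module-to-outside |r|). The pre-disease stage is the stage
whose best module maximizes `I`; a peak-to-median ratio rule flags
significance.

**Intervention ranking.** With the sample covariance matrix `Σ̂` of the
pre-disease stage (genes × genes, `n − 1` denominator), the *intervention
index* of gene *i* is `|v1_i|`, the absolute entry of the dominant
eigenvector `v1` of `Σ̂` — the direction along which the network's
fluctuations diverge as stability is lost. Top-ranked genes (default
`k = 10`) are selected and can be filtered by biotype annotation (default:
drop lncRNAs).

**Validation.** A linear stochastic network model `dx = A(p)x dt + L dW`
with a planted DNB module supplies ground truth: the drift `A(p) = A0 + pB`
is calibrated so its leading eigenvalue is exactly `−(1 − p)`, and the
stationary covariance solves the Lyapunov equation `AΣ + ΣAᵀ + Q = 0`.
Stabilizing interventions add self-degradation (`A_ii ← A_ii − c`) to the
selected targets; success means reduced stationary variance, and the
selection is benchmarked against random target sets.

## Worked example

```r
library(dnbscreen)

model  <- build_network(500, 10, seed = 42)      # 10-gene planted module
series <- generate_stage_series(model, 8, seed = 42)  # 5 stages x 8 samples

result <- detect_predisease(series)
result
#> dnb_result: pre-disease stage 'stage05' (significant)
#>   11 members; composite index by stage: 1.95, 0, 0, 0, 3.67

ranking <- select_top(intervention_index(series$stages[[5]]), 10)
ranking
#> intervention_ranking: 500 genes, lambda1 = 50.42
#>   top: g0228 (0.172), g0146 (0.164), g0359 (0.161), g0500 (0.159), g0153 (0.158)
#>   selected (k = 10, threshold 0.1506): g0228, g0146, g0359, g0500, g0153, ...

out <- simulate_intervention(model, 0.95, ranking$selected, strength = 0.5)
out
#> intervention_outcome: 10 targets, strength 0.5
#>   leading eigenvalue: -0.05 -> -0.4988
#>   total variance: 255.2 -> 246.1 (DNB: 10.24 -> 1.233)
```

The detected stage (`stage05`, where the control parameter peaks at 0.95) is
the planted critical stage; the 11-gene member set covers all 10 planted
module genes. After stabilizing the 10 top-ranked genes the leading drift
eigenvalue moves from −0.05 (near-critical) to −0.50 (stable) and the
planted module's stationary variance drops by ~88% — the fluctuation
reduction that validates the selection.

For the published worked example of the biotype filter:

```r
ann <- read_annotation_tsv(system.file("extdata",
        "tsod_top10_annotation.tsv", package = "dnbscreen"))
filter_by_biotype(ann$gene_id, ann)   # 10 candidates -> 8 (2 lncRNAs removed)
```

A thin command-line front end over the same functions ships at
`inst/cli/dnbctl.R` (`simulate | detect | rank | intervene | run`), with the
demo configuration in `inst/extdata/demo_config.yaml`.

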