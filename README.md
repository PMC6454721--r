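# ddibalance

Community detection and cold-start interaction prediction for **signed
drug–drug interaction (DDI) networks** — graphs whose edges record whether
one drug *enhances* (+1) or *diminishes* (−1) another's pharmacological
effect. The package is aimed at computational pharmacologists and network
scientists who want to (a) partition a comprehensive DDI network into
communities that respect weak structural balance, and (b) predict signed
interactions for newly approved drugs that have no recorded DDIs, from
binary drug features such as drug-binding-protein profiles.

## What it computes

**Balance diagnostics.** Every triangle of the signed adjacency
`A ∈ {−1,0,+1}^{m×m}` is classified by its sign multiset — PPP, NNP (= PNN),
NNN, PPN — where only PPN is frustrated under weak balance. For a hard
partition `{C₁,…,C_k}` the community balance index

```
CBI = Σ_c n_c (1 − #PPN_c / #triads_c) / Σ_c n_c ∈ [0, 1]
```

is the size-weighted fraction of balanced triads inside communities, and
within/between log-ratio metrics (Δ_w, Δ_b, SR^w, DR^w) locate enhancive and
degressive density. A sign-shuffle null model — permute the sign multiset on
the fixed support, in closed hypergeometric form or by Monte-Carlo —
quantifies how far the observed triad mix is from sign-blind wiring.

**BRSNMF.** Balance-regularized semi-nonnegative matrix factorization
finds `A ≈ W Hᵀ` with real centroids `W` and nonnegative indicators `H` by
minimizing

```
‖A − WHᵀ‖²_F + α·tr(H 1 Hᵀ) − β·tr(Hᵀ(σI − η(A⁻ + L⁺))H),   H ≥ 0,
```

alternating an exact least-squares `W` update with a multiplicative `H`
update (defaults α = β = η = σ = 1). The α term evens community sizes; the
β term penalizes degressive edges inside and enhancive edges between
communities. With α = β = 0 the iteration is exactly Semi-NMF, included as
the baseline. Hard communities come from the row argmax of `H`.

**Cold-start pipeline.** Training couples BRSNMF with an (uncentered,
strictly linear) partial least squares regression `H = F B` from binary
features; a new drug's scores against the m training drugs are
`A_x = (F_x B) Wᵀ`. Evaluation is purely rank-based: top-n/bottom-n
accuracy at the two ends of the score list, AUROC/AUPR for interaction
detection with |score|, and mean percentile ranking (MPR), under drug-level
(never pair-level) cross-validation.

**Synthetic generators** plant weakly balanced partition structure and
community-linked binary features with controllable noise, so the whole
pipeline is testable without any proprietary database extract.

## Worked example

```r
library(ddibalance)

sim <- planted_signed_network(seed = 42)   # 3 planted communities of 40
net <- sim$network
net
#> <signed_network> 120 drugs, 3090 interactions (2074 enhancive, 1016 degressive)

fit <- brsnmf(net, k = 3, seed = 42)
part <- assign_communities(fit)
balance_report(net, part)
#> <balance_report> CBI = 0.8533 (85.33%), 3 communities
#> # A tibble: 3 × 13
#>   community     n triads   ppn balance no_triads pairs enhancive degressive
#> 1         1    40   6875   978   0.858 FALSE       780       654         37
#> 2         2    40   6743   952   0.859 FALSE       780       651         36
#> 3         3    40   7377  1155   0.843 FALSE       780       666         42
```

Each recovered community holds its 40 planted drugs; ~85% of the triads
inside communities are balanced (the 5% sign-flip noise plants PPN triads at
rate 3·0.05·0.95² ≈ 0.135, so ≈ 0.865 is the generative ceiling), and the
positive `delta_w` / negative `delta_b` columns (not shown) confirm
enhancive-dense communities separated by degressive edges.

The sign-shuffle null for a network with 125,298 enhancive and 55,278
degressive edges — counts typical of a curated DDI extract — gives:

```r
triad_shuffle_expectation(125298, 55278)
#> # A tibble: 4 × 3
#>   triad n_negative expected_fraction
#> 1 PPP            0            0.334
#> 2 NNP            2            0.195
#> 3 NNN            3            0.0287
#> 4 PPN            1            0.442
```

i.e. sign-blind wiring would make ~44% of triads unbalanced — far from the
balanced compositions real DDI networks show.

Cold-start cross-validation on the packaged 120-drug benchmark:

```r
bench <- coldstart_benchmark(seed = 1)
cv <- coldstart_cv(bench$network, bench$features, k = 3,
                   n_folds = 10, seed = 1, n_list = c(5, 10))
glance(cv)
#> # A tibble: 1 × 8
#>   n_folds auroc  aupr   mpr top_5 top_10 bottom_5 bottom_10
#> 1      10 0.850 0.820 0.289  0.84   0.81     0.82      0.87
```

Held-out drugs' interactions are detected with AUROC 0.85, and 81% of the
10 highest-scored pairs per fold are truly enhancive (87% of the 10 lowest
truly degressive) — the two ends of one ranked list carrying the polarity.

A command-line front-end (`inst/exec/ddinet`) exposes the same pipeline as
`simulate` / `cluster` / `metrics` / `train` / `predict` / `crossval`
subcommands, each writing a `manifest.json` with input hashes, options and
seed for reproducibility.

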