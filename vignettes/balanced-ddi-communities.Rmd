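---
title: "Weak balance, BRSNMF, and cold-start prediction on signed DDI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak balance, BRSNMF, and cold-start prediction on signed DDI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddibalance)
```

## The problem

A comprehensive drug–drug interaction (DDI) network records, for every pair
of drugs known to interact, whether the interaction is *enhancive* (one drug
increases the other's pharmacological effect, coded $+1$) or *degressive*
(it decreases it, coded $-1$). The result is a signed, undirected graph on
$m$ drugs with adjacency $A \in \{-1, 0, +1\}^{m \times m}$.

Two analysis tasks sit on top of this object:

1. **Community partition.** Signed social networks tend to organize into
   groups obeying *weak structural balance*: edges within groups are mostly
   positive (or, for a *weakly balanced* group, mostly negative), and edges
   between groups are mostly negative. DDI networks empirically show the
   same tendency, and a partition that respects it groups drugs with
   coherent pharmacological co-behavior.
2. **Cold-start prediction.** A newly approved drug has no recorded DDIs.
   Given binary features that are informative about its community (for
   example a drug-binding-protein profile), predict the sign and presence of
   its interactions with the established drugs.

## Balance diagnostics

Every 3-cycle (triad) of the network is classified by its multiset of edge
signs: `PPP`, `NNP` (two negative, one positive; the same multiset as PNN),
`NNN`, and `PPN`. Under weak balance the first three are consistent and
only `PPN` is frustrated: two mutually enhancive drugs that disagree about
a third. `triad_census()` counts these by enumerating the triangles of the
unsigned support (via igraph) and reading the three signs of each.

For a hard partition into communities $C_1,\dots,C_k$ the package reports:

* **CBI** (community balance index): the community-size-weighted mean of
  $1 - \#PPN_c / \#\mathrm{triads}_c$ over communities, where triads are
  counted in the induced subgraph of each community. A community with no
  internal triangles contributes 1 — it violates no balance constraint —
  and is flagged in the report so that degenerate partitions remain
  visible. CBI lives in $[0,1]$ and is printed as a percentage.
* **$\Delta_w$, $\Delta_b$**: log-ratios of enhancive to degressive
  interaction density within a community and between a community pair.
  Counts are pseudo-counted ($R = (\text{count} + 0.5)/\text{pairs}$)
  before the logarithm so a community with zero edges of one polarity still
  yields a finite, strongly signed value. A strongly balanced community has
  $\Delta_w > 0$; a weakly balanced one $\Delta_w < 0$; a well-separated
  pair has $\Delta_b < 0$.
* **$SR^w = R_e^w + R_d^w$** (how dense a community is) and
  **$DR^w = R_e^w - R_d^w$** (which polarity dominates), computed on raw
  (un-pseudo-counted) ratios so that $SR^w \in [0,1]$ and
  $|DR^w| \le SR^w$. Communities with fewer than two members have no
  internal pairs; their ratio metrics are reported as `NA` and flagged
  rather than invented.

### The sign-shuffle null

To ask whether an observed triad mix could arise with sign-blind wiring,
`shuffle_signs()` permutes the sign multiset over the fixed support, and
`triad_shuffle_expectation()` gives the closed form: with $E^+$ positive
and $E^-$ negative signs among $E$ edges, the three edges of any triangle
are three draws without replacement, so
$P(j \text{ negative}) = \binom{E^-}{j}\binom{E^+}{3-j}/\binom{E}{3}$.
The expectation is exact for each triangle regardless of how triangles
share edges, hence exact for the mean fraction. `triad_sign_null()`
enumerates the triangles once and re-tallies a permuted sign vector per
shuffle, so large supports (hundreds of thousands of edges) are cheap.

```{r toy}
toy <- fig1_toy()
triad_census(toy)
cbi(toy, attr(toy, "partition"))
```

## BRSNMF

Semi-NMF factorizes a real symmetric $A \approx W H^T$ with free centroids
$W \in \mathbb{R}^{m\times k}$ and nonnegative indicators
$H \in \mathbb{R}_{\ge 0}^{m\times k}$; row $i$ of $H$ scores drug $i$'s
affinity for each community. BRSNMF adds two regularizers:

$$\min_{W,\,H \ge 0}\; \|A - WH^T\|_F^2
  \;+\; \alpha\, \mathrm{tr}(H \mathbf{1}_{k\times k} H^T)
  \;-\; \beta\, \mathrm{tr}\!\big(H^T(\sigma I - \eta(A^- + L^+))H\big),$$

where $A^\pm = (|A| \pm A)/2$ and $L^+ = D^+ - A^+$ is the Laplacian of the
positive part. The $\alpha$ term penalizes rows spread over several
communities (squared row sums of $H$), which in practice evens out
community sizes; the $\beta$ term charges for degressive edges kept inside
a community (through $A^-$) and for enhancive edges cut between communities
(through $L^+$), while $\sigma$ rewards overall indicator mass. The trace
is taken with $H$ un-normalized, exactly as the update rules require; the
normalized Rayleigh-quotient motivation is not implemented separately, and
the general kernel form of the balance term is fixed at its identity-weight
specialization.

### Updates and numerical choices

The solver alternates

* $W \leftarrow A H (H^T H)^{-1}$ — the exact least-squares centroid
  update. A ridge $\lambda I$ with $\lambda = 10^{-8}\,\mathrm{tr}(H^TH)/k$
  is added before inversion because multiplicative updates drive entries of
  $H$ to exact zeros, which can make $H^TH$ singular in practice.
* a multiplicative indicator update
  $H \leftarrow H \odot \sqrt{N / (D + \varepsilon)}$ with
  $$N = (A^TW)_+ + H\,(W^TW)_- + \beta\eta\,(L^+)_-H + \beta\sigma H,
  \qquad
  D = (A^TW)_- + H\,(W^TW)_+ + \alpha H\mathbf{1} + \beta\eta A^-H
      + \beta\eta\,(L^+)_+H.$$
  The mixed-sign factors are split at the *matrix* level, the form the
  Semi-NMF and graph-regularized-NMF majorization arguments require; note
  that elementwise $(L^+)_+ = D^+$ and $(L^+)_- = A^+$, so the balance
  terms reduce to the classical degree/adjacency split. Splitting the
  *products* elementwise instead is not a descent step — it empirically
  increases the objective — which is why the package uses the matrix
  split. With $\alpha = \beta = 0$ the added terms are exact zero matrices
  and the iteration is bit-for-bit plain Semi-NMF (`semi_nmf()`).

Remaining choices, each exposed in the API:

* **Initialization** (`init`): k-means on the rows of $A$, converted to a
  membership indicator plus a 0.2 offset — the standard Semi-NMF recipe —
  or uniform-random nonnegative. Both are driven by `seed`; k-means falls
  back to random if it cannot produce $k$ centers.
* **Stopping**: relative objective change below `tol` (default $10^{-6}$)
  or `max_iter` (default 500).
* **Denominator floor**: $\varepsilon = 10^{-12}$ guards against
  division by zero; entries of $H$ that reach exact zero stay zero, which
  is inherent to multiplicative updates.
* **Hard assignment**: row argmax of $H$, ties to the lowest column index,
  empty communities compacted with a warning, all-zero rows an error.
* **Defaults**: $\alpha=\beta=\eta=\sigma=1$, the setting the method is
  robust around; for prediction, $k$ defaults to the numerical rank of $A$
  (singular values above $10^{-8}$ of the largest) divided by 10.

**Boundedness caveat.** Because the $\sigma$ term rewards indicator mass,
the objective is bounded below only while
$\alpha\,\mathrm{tr}(H\mathbf{1}H^T) \ge \beta\sigma\|H\|_F^2$, which holds
at the defaults ($\mathrm{tr}(H\mathbf{1}H^T) \ge \|H\|_F^2$). With
$\beta\sigma$ much larger than $\alpha$ the problem is genuinely unbounded
and the iteration can diverge; the solver detects non-finite iterates and
raises a numerical error rather than silently continuing.

**A property worth knowing.** The balance term charges for *any*
within-community degressive edge, so it mildly disfavors weakly balanced
(all-negative) communities: on planted networks containing such a block,
the optimum at $\alpha=\beta=1$ relocates one or two boundary nodes
relative to the planted partition even when the optimizer is started at the
planted solution. The block itself is still recovered as one community and
its $\Delta_w$ is negative; the effect is confined to ambiguous boundary
nodes.

### Comparing BRSNMF with Semi-NMF

With an informative k-means initialization on cleanly planted data, both
methods start near the planted optimum and differences vanish. The
package's comparison protocol therefore runs both methods from matched
uniform-random initializations over 20 seeds and compares mean CBI and the
standard deviation of community sizes. Under that protocol BRSNMF yields
markedly less dispersed community sizes and no worse balance — the
regularizers doing exactly their advertised work — whereas Semi-NMF
occasionally fragments or collapses communities.

## Cold-start prediction

Training fits BRSNMF on the known-drug network and then regresses the
indicator matrix on the binary features, $H = F B$, by partial least
squares. Prediction maps query features into the latent space and scores
all pairs against the training drugs:
$$A_x = H_x W^T = (F_x B) W^T.$$

Two design points matter:

* **The map is strictly linear.** An all-zero feature row scores zero,
  scaling features scales scores, and superposition holds. For that reason
  the PLS regression is computed *without centering* (an intercept would
  break linearity): a NIPALS PLS2 on the raw matrices, with the component
  count capped at $\min(k, p, m-1)$. At full rank it coincides with the
  no-intercept least-squares solution; with fewer components it applies
  the usual PLS shrinkage.
* **Evaluation is rank-based; no score cutoffs exist anywhere.** Score
  magnitudes scale with $k$, so fixed thresholds would be arbitrary.
  `evaluate_ranking()` reads one sorted list from both ends: top-$n$
  accuracy for enhancive ($+1$) labels among the highest scores, bottom-$n$
  for degressive ($-1$) among the lowest, with ties broken
  deterministically by (query, target) labels. Interaction *detection*
  ($|{\rm label}|=1$ vs 0) is scored by $|{\rm score}|$ with AUROC (exact
  Mann–Whitney statistic) and AUPR (average precision), and MPR is the mean
  percentile rank (0 = top) of true interactions in each query's
  $|{\rm score}|$-sorted candidate list — 0.5 is chance, smaller is better.

`coldstart_cv()` cross-validates at the *drug* level only: a fold's drugs
and every interaction touching them are removed before training, and the
removed rows are predicted from features alone. Pair-level CV would leak
the held-out drugs' latent positions and is deliberately not offered.

## The synthetic generator

`planted_signed_network()` realizes the generalized weak-balance model:
within-community pairs carry an edge with probability `within_edge_prob`
signed by the community's polarity (`within_sign = -1` plants a weakly
balanced block); between-community pairs carry an edge with probability
`between_edge_prob`, degressive except a `between_positive_rate` fraction;
finally `flip_rate` of all signs flip. The defaults — three communities of
40, within 0.9, between 0.2, 5% stray positives, 5% flips — give roughly
69% enhancive edges, matching the sign imbalance typical of curated DDI
extracts. `community_linked_features()` emulates binding profiles: each
community owns a block of $\lfloor p/k \rfloor$ marker features set with
probability `signal`, all others with probability `noise`; with
`signal == noise` the features are community-blind, which is the ablation
control. `coldstart_benchmark()` freezes the package's reference study
condition: 120 drugs, two strongly and one weakly balanced community,
within 0.9 / between 0.15, and 60 features at signal 0.9 / noise 0.1.

What the generator does *not* emulate: the heavy-tailed degree and
community-size distributions of real DDI networks, overlapping community
membership, correlated (protein-sharing) features, and the much lower edge
density of curated extracts. Passing tests on this generator therefore
demonstrate correctness of the machinery and the qualitative behavior of
the regularizers, not real-data effect sizes.

## Problem sizes used by the test suite

The suite runs planted networks of 40–120 nodes, 10–20 seeds per claim,
100 random instances for the descent property, and a 3,000-node /
180,576-edge support (the published DDI edge counts) with several hundred
sign shuffles for the null-model checks — sizes chosen so the full suite
completes in about a minute while keeping Monte-Carlo standard errors an
order of magnitude below the tolerances being asserted.

## Limitations

* Hard partitions only; $H$ is exported but overlapping community output
  is out of scope, as is any automatic choice of $k$.
* Triads only: $l$-cycle balance for $l > 3$ is not implemented.
* Unweighted, undirected signs; weighted or directed DDI polarity is not
  modeled.
* The package ships no database extract. Community memberships obtained on
  a particular DrugBank snapshot depend on that snapshot and on the chosen
  initialization, so absolute memberships are not comparable across
  extracts; the balance diagnostics and the cross-validation protocol are.
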