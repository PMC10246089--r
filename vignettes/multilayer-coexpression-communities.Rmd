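---
title: "Multilayer community detection in co-expression correlation matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer community detection in co-expression correlation matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcoex)
```

## The problem

Tissue-specific expression surveys measure the same genes in many donors
across several tissues. Two genes are *co-expressed* in a tissue when their
expression levels rise and fall together across donors; groups of mutually
co-expressed genes (gene modules) often share regulation or function. When
several tissues are profiled, the natural object is a *multiplex network*:
one co-expression layer per tissue over a common gene set, with each gene
connected to its own replica in every other layer. Communities in that
object separate into *generalist* modules (genes co-expressed the same way
in several tissues) and *specialist* modules (genes co-expressed in only
one tissue).

`mlcoex` detects such communities directly on the Pearson correlation
matrices, without thresholding them into sparse graphs. Thresholding
discards sub-threshold and negative correlations and injects an arbitrary
cutoff; working on the correlation matrix keeps all of the signal but
requires a null model appropriate for correlation matrices — the ordinary
configuration model of network science is not, in general, a correlation
matrix.

## The model

Each tissue layer $\alpha$ carries the correlation matrix
$\rho_{ij\alpha}$ of $\log(\mathrm{TPM}+1)$ expression across that tissue's
samples (the log damps the heavy right tail of TPM; zero TPM maps to zero).
Interlayer couplings $\omega_{i\alpha\beta}$ are the empirical correlations
of gene $i$'s log expression across donors common to tissues $\alpha$ and
$\beta$, clamped at zero from below because the modularity machinery
assumes non-negative interlayer weights.

The multilayer modularity of a partition $g$ of the $(i,\alpha)$ nodes is

$$Q = \frac{1}{C_{\mathrm{norm}}}\sum_{ij\alpha\beta}
  \left[(\rho_{ij\alpha} - \gamma_\alpha \langle \rho_{ij\alpha}\rangle)
  \delta_{\alpha\beta} + \omega_{i\alpha\beta}\,\delta_{ij}\right]
  \delta(g_{i\alpha}, g_{j\beta}),$$

with $C_{\mathrm{norm}} = \sum_{i\alpha}(\sum_j \rho_{ij\alpha} +
\sum_\beta \omega_{i\alpha\beta})$, both orders of every pair counted, and
the diagonal $(1-\gamma_\alpha)$ terms retained as written (they contribute
identically to every partition, so the argmax is unaffected — this is
asserted by a test). The resolution $\gamma$ scales the null term: larger
values produce smaller communities.

### The null model

$\langle\rho\rangle$ is the *configuration model for correlation matrices*:
the correlation matrix of maximal Gaussian differential entropy
(equivalently, maximal log-determinant) with unit diagonal and every node's
strength (row sum) matched to the input. Stationarity forces the inverse of
the null to have off-diagonal entries $(a_i + a_j)/2$ plus a node-specific
diagonal, so the fit reduces to $2N$ Lagrange multipliers.
`fit_configuration_model()` finds them by a damped Newton iteration on the
strictly convex dual, whose gradient is exactly the constraint violation
and whose Hessian has a closed form; typical fits converge below a residual
of $10^{-10}$ in under ten iterations (default tolerance $10^{-8}$,
`max_iter` 200). Inputs of size $N \le 2$ are fully pinned by the
constraints and returned unchanged; near-singular inputs are ridge-lifted
on the diagonal by $10^{-8}$ and renormalized, with a warning. The test
suite cross-checks the fit against an independent primal maximizer that
parametrizes the constraint null space and runs a generic quasi-Newton
optimizer — a different formulation sharing no code with the dual solver.

### Maximization, consensus, and the diagonal convention

`genlouvain()` maximizes $Q$ on the supra-modularity matrix by
single-node moves plus community aggregation. Two move rules are provided.
The default, `"best"`, takes the maximal-gain move, stays on ties, and
otherwise prefers the lowest community label; it is reproducible and
nearly deterministic — so nearly that 100 differently seeded runs on a
small system routinely return one identical partition. That determinism
starves consensus clustering, which exists precisely because stochastic
maximizers return different local optima. The `"prob"` rule therefore
draws the move target among all strictly improving communities with
probability proportional to the gain (the randomized move selection of the
multilayer Louvain toolboxes); it is the rule used whenever many seeded
runs feed a consensus, as in the pipeline's detection stage.

`iterated_genlouvain()` feeds each output back as the next initial
partition until a fixed point; $Q$ is non-decreasing across iterations.
`consensus_partition()` combines runs through the co-assignment
(agreement) matrix, subtracts the expected agreement under size-preserving
label permutations — which has a closed form, because permuting labels
never changes community sizes — and reclusters the residual matrix
(negative entries kept, acting as repulsion) until all runs agree.

A caveat worth stating plainly: consensus optimizes *agreement*, not
modularity. On small frustrated systems whose runs split between two
basins, the consensus partition can have strictly lower $Q$ than the best
run, and a further local-move refinement cannot escape it, because the
compromise is itself single-move stable. The test suite measures this
against exhaustive enumeration on 8-node instances.

### Resolution selection

For a fixed partition, $Q(\gamma)$ is affine in a shared $\gamma$, so each
candidate partition is a line in the $(\gamma, Q)$ plane
(`partition_line()`). `champ_1d()` computes the upper envelope of those
lines over a sweep range (default 15 evenly spaced values on $[1, 4]$):
the tiling of the range into intervals on which one partition dominates.
Wide intervals mark robust resolutions; `select_gamma()` returns the
midpoints of the two widest intervals (ties prefer smaller $\gamma$), with
an option to pin explicit values inside them. Envelope intervals are only
reported within the sweep range, and intervals truncated by its ends are
flagged, since the envelope is not extrapolated.

### Community significance

For a community $S$, the quality measure is the total intralayer weight
$W = \sum_\alpha \sum_{(i,\alpha),(j,\alpha)\in S,\ i>j} C_{ij\alpha}$
(diagonal excluded; interlayer couplings never counted). Under the null,
per-layer sample covariances of $L_\alpha$ Gaussian observations drawn
from the fitted null have mean equal to the null matrix, so $\mu$ is the
within-community null sum, and the variance follows from the Isserlis
fourth-moment identity:
$\sigma^2 = \sum_\alpha L_\alpha^{-1} \sum_{i>j}\sum_{k>r}
(C_{ik\alpha}C_{jr\alpha} + C_{ir\alpha}C_{jk\alpha})$. The printed form
of that expression uses a single $1/L$; since communities can span layers
with different sample sizes, the implementation applies $1/L_\alpha$
inside the layer sum, which reduces to the printed form when all counts
agree. $Z = (W-\mu)/\sigma$; communities without intralayer pairs have
$\sigma = 0$ and an undefined (NA, flagged) score rather than an error.
`mc_weight_moments()` is a Monte-Carlo oracle for both moments; its sample
covariance uses denominator $L-1$ (unbiased), so closed-form agreement is
exact for the mean and $O(1/L)$ for the variance.

### Specialist classification and genomic localization

The *specialist fraction* of a community counts, per tissue, the genes
present in exactly one layer within the community; the tissue with the
most such genes is the specialist tissue and the fraction is its count
divided by the community's node count. Communities are specialist iff the
fraction strictly exceeds 0.5. For genomic analyses, specialist
communities contribute all their genes; generalist communities only genes
present in at least 3 of the 4 layers, so the retained genes plausibly
carry the cross-tissue function.

Three permutation tests ask whether a community's genes cluster on the
genome (`localization_tests()`, 100 randomizations by default): the
same-chromosome pair fraction against shuffled chromosome labels
(one-sided upper), the mean same-chromosome gap against per-chromosome
uniform redraws preserving the group's per-chromosome counts (one-sided
lower), and the per-chromosome mean gap for chromosomes carrying at least
3 group genes, Bonferroni-corrected within the community. Gaps are
measured end-to-start in bp with overlapping genes at distance 0 (never
negative); BED input is converted to 1-based inclusive coordinates on
read. Because 100 replicates bound the empirical p at 0.01, both the
empirical permutation p and a one-sided normal-approximation p from the Z
score are reported, and the Bonferroni flag uses the normal approximation;
strand is ignored throughout.

Finally, `shared_eqtl_pairs()` lists gene pairs with co-expression above
0.5 whose eQTL variant sets intersect — candidate pairs under shared
genetic regulation.

## What the synthetic generator emulates

`planted_multilayer_expression()` draws Gaussian log-expression
($\mu_g = 5$, $\sigma_g = 1$, so $\exp(\cdot)-1$ is almost surely positive
and $\log(\mathrm{TPM}+1)$ recovers the planted correlations; clipping at
zero is negligible at these defaults) with block-structured target
correlations: by default 60 genes in 4 layers, three 12-gene generalist
blocks present in every layer, one 10-gene specialist block in the first
layer only, within-block correlation 0.7, all remaining pairs at 0.05,
500 samples per layer, and donors drawn from a pool sized so two layers
share half their donors on expectation. Generalist blocks reuse a
per-donor latent factor across layers, so interlayer couplings come out
near $\rho_{in}-\rho_{out}$ for generalist genes and near zero elsewhere;
the specialist block and the background factor are layer-private. Gene
coordinates and toy eQTL tables with planted clusters and shared variants
complete the inputs, so every pipeline stage is testable without
downloads.

The generator does *not* emulate library-size artifacts, batch effects, or
negative-binomial counting noise; a pass on synthetic data shows the
machinery recovers planted correlation structure, not that real-data
confounders are handled.

Truth labels mark planted block nodes; background genes (and specialist
genes outside their home layer) carry a reserved background label because
nothing is planted for them, and recovery is scored by the adjusted Rand
index over planted nodes (`recovery_ari()`), the usual planted-partition
convention — scoring exchangeable unplanted nodes would measure a
labelling convention rather than recovery. The manifest also reports the
all-node ARI.

Two behaviors of the method on this scenario deserve emphasis, because
they are genuine properties rather than bugs, and both are visible in the
test suite. First, a diffuse equicorrelated background ($\rho_{out} =
0.05$ among 14 genes) is *itself structure* under the strength-preserving
null: with blocks present, the null assigns background pairs an expected
correlation near 0.003, well below 0.05, so the background coalesces into
a weak community. For the fully equicorrelated matrix the null equals the
input and nothing is detected — the two situations differ. Second, that
background community attaches to the specialist block's community at
$\gamma = 1$ at near-zero modularity cost, glued by the positive-mean
clamped coupling noise of the specialist genes' replicas; the merged
partition has strictly higher $Q$ than the separated one. Detection
therefore recovers the planted blocks exactly (planted-node ARI 1.0, the
specialist block's weight $Z \approx 24$) while the specialist community's
*fraction* is diluted to zero by the absorbed background. With real
tissue panels this dilution requires a large pool of genes that are
mutually weakly correlated yet unstructured, which gene selection by
variance works against.

## Numerical choices and defaults

- 75 top-variance genes per tissue by default (variance of raw TPM;
  log-scale variance available), ties broken by gene id; the per-tissue
  selections are unioned.
- Correlations need at least 3 samples; zero-variance genes error in
  library calls and are dropped with a warning in the pipeline.
- Interlayer couplings need at least 3 common donors per layer pair; one
  sample per donor per tissue (first by sample id).
- Consensus uses 200 partitions in the pipeline's detection stage; the
  resolution sweep runs one iterated maximization per grid point.
- All stochastic stages consume named seeds derived from the master seed;
  reruns are byte-identical.
- Problem sizes in the shipped tests: 20-node configuration-model fits,
  8-node exhaustive-enumeration comparisons, the 60-gene default synthetic
  scenario with 200-run consensus, 10,000-replicate moment Monte-Carlo,
  and 200-group localization calibration — sizes at which every check runs
  in seconds to a few minutes on one core.

## Known limitations

- Louvain-type single-node dynamics cannot cross two-node barriers; on
  frustrated instances the global optimum may be unreachable from any
  visiting order, and agreement-based consensus can return a compromise
  with lower modularity than its best input run.
- The closed-form significance variance assumes Gaussian data, as does the
  entropy-maximizing null.
- With many layers, specialist structure becomes progressively harder to
  detect (couplings accumulate), and the specialist fraction is diluted by
  replicas — the behavior quantified on the synthetic scenario above.
- p-values from 100-replicate permutation tests rely on the normal
  approximation below 0.01.
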