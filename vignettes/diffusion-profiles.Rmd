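---
title: "Prioritizing disease genes by diffusion-profile similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes by diffusion-profile similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffusionRank)
```

## The model

A protein–protein interaction network is an undirected simple graph over
gene identifiers. With `M` the column-normalized adjacency matrix, a
random walk with restart iterates

$$P_{t+1} = (1-\gamma)\,M P_t + \gamma P_0,$$

and the stationary limit $P_\infty$ — the *diffusion profile* of the
start distribution $P_0$ — spreads each unit of start mass over the
whole network in proportion to topological proximity. A gene's profile
starts from its indicator vector; a disease's profile starts from equal
mass on its known causal genes. Phenotype information enters through the
weighted disease start vector

$$\tilde D_0 = D_0 + \lambda \sum_i \delta(d, d_i)\,\mathrm{Sim}(d, d_i)\,D_0^i,$$

where the sum runs over all other diseases, $D_0^i$ is the equal-mass
start vector of disease $d_i$, and $\delta$ keeps only pairs whose
similarity reaches the informativeness cutoff (0.3 by convention for
text-mining-derived phenotype similarity, below which scores carry no
functional signal).

Candidates are ranked by a *global* comparison of stationary
distributions — Pearson correlation (DP_LCC) or cosine (DP_COS) between
the disease profile and each candidate gene's profile — rather than by
the candidate's single component of the disease vector. The intuition:
a true disease gene does not merely receive much mass from the known
genes; its own view of the network resembles the disease's view.

Two baselines are provided for comparison. The classical RWR score is
the candidate's component of the unweighted ($\lambda = 0$) disease
stationary vector. The PRINCE-style baseline replaces the equal-mass
start vector with a logistic prior
$L(x) = 1/(1 + e^{cx + d})$, $c = -15$, $d = \log 9999$, applied to each
gene's best phenotype similarity to the query disease (own genes count
as similarity 1, unrelated genes sit on the floor $L(0) = 10^{-4}$); it
is "PRINCE-style" because only the prior construction and component
scoring are reproduced, not the original's edge-weight normalization or
iterative refinement.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.25 | restart probability; near 1 = local walk, near 0 = global |
| `lambda` | 0.5 | weight of similar diseases' start vectors |
| `threshold` | 0.3 | minimum informative phenotype similarity |
| `tol` | 1e-6 | L1 convergence threshold of the iteration |
| `max_iter` | 10000 | safety bound; profiles are flagged if not converged |
| `n_controls` | 99 | control genes per cross-validation case |
| `step` | 0.01 | rank-ratio threshold grid for the ROC sweep |

The `gamma`/`lambda` defaults are the settings at which the
prioritization performs best in our experience with this family of
methods; both are exposed everywhere and `parameter_sweep()` evaluates a
grid in one call.

## Numerical choices

**Node order.** Nodes are fixed in lexicographic order at load time, so
every vector and matrix index is reproducible across runs and cached
profile matrices can be validated against the network they came from.

**Isolated nodes and renormalization.** A degree-0 node produces an
all-zero column in `M`, which leaks mass from every iterate. We keep
such nodes (dropping genes that appear in association files would be
worse) and renormalize each iterate to sum 1; on networks without
isolated nodes this is exactly a no-op. Convergence is measured as the
L1 difference of successive renormalized iterates. The closed-form
oracle `rwr_closed_form()` solves
$P_\infty = \gamma (I - (1-\gamma)M)^{-1} P_0$ densely; it coincides
with the iteration exactly when no column is zero (with zero columns the
renormalized map is nonlinear and has a different fixed point), so the
oracle-equivalence tests generate graphs with minimum degree 1.

**Renormalizing the weighted start vector.** $\tilde D_0$ as written is
not a probability vector. We renormalize it to sum 1, which preserves
the probabilistic reading of the disease walk and provably cannot change
a DP_LCC/DP_COS ranking, because both measures are invariant to positive
rescaling of either argument (this invariance is asserted as a property
test). The self-term $d_i = d$ is excluded from the sum: including it
would only rescale $D_0$, and the input similarity matrix does not carry
a diagonal.

**Ties and undefined scores.** Tied candidates all receive the *worst*
rank of their tie group, so evaluation never credits a tie — a
conservative choice that can only lower PRE/AUC, visible in the
structure-free null where pooled ties push the AUC slightly below 0.5.
A candidate whose profile is constant (LCC) or zero (cosine) has no
defined score and ranks last: a non-informative profile should not be
rewarded.

**Rank ratio.** rank / (n_controls + 1), so it lies in (0, 1]. The ROC
sweeps thresholds 0, 0.01, …, 1; sensitivity is the fraction of held-out
genes at or below the threshold, specificity the fraction of control
genes above it, and the AUC is the trapezoid rule over the resulting
curve, whose endpoints (0,0) and (1,1) arise at the grid ends.

**Cross-validation protocol.** Each association (d, g) is removed in
turn — the *link* only; the gene remains a network node — and g is
ranked against its controls. Genes co-associated with the same disease
are excluded from the control pool (they cannot be both test and
control); on tiny fixtures where that would leave fewer than
`n_controls` eligible genes the exclusion relaxes to the test gene only.
By default, similar diseases' start vectors keep all their currently
known genes, mirroring the literal training-set construction; the
`strict` flag also removes the held-out gene from every similar
disease's vector for leakage analysis. Control sampling derives one
sub-seed per case from the caller's seed, making entire
cross-validation runs bit-reproducible.

## The synthetic generator

`generate_bundle()` emulates the statistical premise the method
exploits — genes of the same or phenotypically similar diseases cluster
in the interactome — with fully controllable strength:

* a scale-free (preferential attachment, `m = 2`) or Erdős–Rényi graph;
  the default is scale-free, matching the degree heterogeneity of real
  interactomes;
* phenotype clusters, each claiming a breadth-first territory of the
  network; each disease grows its 2–4 causal genes by a breadth-first
  walk inside its cluster's territory, and missing within-disease edges
  are added with probability `module_cohesion` (default 0.8);
* same-cluster disease pairs get similarities drawn from 0.5–0.9
  (informative), cross-cluster pairs from 0–0.2 (below the 0.3 cutoff);
* evenly spaced gene positions on synthetic chromosomes with jitter, for
  artificial-linkage-interval controls.

With `module_cohesion = 0` the generator instead draws disease genes
uniformly at random and leaves the network untouched — a structure-free
null in which no method should (and none does) beat chance.

The default scale — 300 genes, 20 diseases, 4 clusters — keeps a full
leave-one-out run with gene-profile precomputation in the order of
seconds, which is what the test suite and the acceptance script use
(the acceptance benchmark aggregates 10 generator seeds, ~600 cases).

What the generator does *not* emulate: literature-biased
ascertainment of associations, the heavy-tailed disease-size
distribution of real catalogs (most real disorders have one known gene
and are excluded from cross-validation anyway), correlated noise in
text-mining similarities, and false-positive interactions. Passing the
planted-signal benchmark therefore shows the pipeline extracts exactly
the kind of modular signal it assumes — not that it will achieve the
same figures on a curated interactome.

## Design choices that were genuinely open

* **Weighted-sum coefficient.** Descriptions of the weighting are
  ambiguous between scaling by the query disease's own start vector and
  by the contributing disease's; we implement the formula as stated
  above ($D_0^i$, the contributing disease's vector), which is also the
  only reading under which similar diseases add information.
* **All components kept.** The network is not restricted to its largest
  connected component by default (`largest_component()` is available);
  profiles of genes in side components are still well defined thanks to
  the renormalized iteration.
* **Full-length profiles.** The LCC/COS comparison uses the entire
  profile vectors over all network nodes, not a restriction to the
  candidate set.
* **PRE is reported both ways** — as a count of top-1 cases and as a
  proportion — since both readings are in common use.

## Limitations

* The dense closed-form solve is guarded to 2000 nodes; it is a test
  oracle and small-run convenience, not the production path.
* Batched profile computation materializes an n × n dense matrix;
  at interactome scale (~10⁴ genes) that is ~1 GB and still feasible,
  but chunked computation via the `genes` argument is the intended use.
* PRINCE is reproduced only at the fidelity described above.
* No statistical comparison of AUCs between methods (e.g. DeLong) is
  included.
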