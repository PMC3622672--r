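# diffusionRank

Disease gene prioritization by diffusion-profile similarity on
protein–protein interaction (PPI) networks.

## The problem

Given a disease with a handful of known causal genes, which of the
thousands of other genes in the interactome are the most plausible
additional candidates? Genes underlying the same or phenotypically
similar disorders tend to encode interacting or network-proximal
proteins, so network propagation is a natural prioritization engine.
`diffusionRank` implements a *global* propagation comparison: instead of
reading off a candidate's local score under a random walk seeded at the
known disease genes, it compares the *entire* stationary distribution of
the disease walk with the entire stationary distribution of each
candidate gene's walk.

## The method

Let `M` be the column-normalized adjacency matrix of the PPI graph. The
random walk with restart (RWR) iterates

    P(t+1) = (1 − γ) · M · P(t) + γ · P(0)

until the L1 change of successive iterates falls below `1e-6`; the limit
`P(∞)` is the **diffusion profile** of the start distribution `P(0)`.
`γ ∈ (0, 1]` is the restart probability (default 0.25): large values keep
the walk near its start nodes, small values give a global view.

* A **gene** starts from its indicator vector.
* A **disease** starts from equal mass on its known causal genes,
  optionally augmented by phenotype similarity: every disorder whose
  phenotype similarity `Sim(d, dᵢ) ≥ 0.3` contributes its own start
  vector scaled by `λ · Sim(d, dᵢ)` (default `λ = 0.5`), and the result is
  renormalized.

Candidates are ranked by the Pearson correlation (**DP_LCC**) or cosine
(**DP_COS**) between the disease profile and each gene profile — both
invariant to positive rescaling, so the renormalization cannot change a
ranking. Two classical baselines are included: **RWR** (the candidate's
component of the unweighted disease stationary vector) and a
**PRINCE-style** prior (logistic transform `1/(1 + exp(−15·x + log 9999))`
of the best phenotype similarity per gene, propagated and read off
component-wise).

The evaluation harness performs leave-one-out cross-validation: each
disease–gene link is removed, the held-out gene is ranked against 99
random or genomically nearest ("artificial linkage interval") control
genes, and performance is summarized as PRE (fraction of cases ranked
top 1), a rank-ratio ROC/AUC on a 0.01 threshold grid, and
precision–recall curves. A planted-module synthetic generator makes the
whole pipeline testable without any external downloads.

## Worked example

```r
library(diffusionRank)

cfg    <- synthetic_config(n_genes = 300, n_diseases = 20, seed = 7)
bundle <- generate_bundle(cfg)
tm     <- build_transition_matrix(bundle$network)

# hold one causal gene of disease D001 out of the training associations
train    <- bundle$map
held_out <- train$D001[1]              # "g0003"
train$D001 <- setdiff(train$D001, held_out)

rank_genome_wide("D001", "dp_lcc", map = train, sims = bundle$sims,
                 transition = tm, top_k = 5)
#> Candidate ranking for disease 'D001' (method: DP_LCC, 5 candidates)
#>    gene     score rank
#> 1 g0003 0.5601881    1
#> 2 g0135 0.5107534    2
#> 3 g0011 0.4382210    3
#> 4 g0091 0.3968159    4
#> 5 g0043 0.3414818    5

run_loocv(bundle$map, bundle$sims, tm, method = "dp_lcc", seed = 7)
#> Leave-one-out cross-validation (DP_LCC, random controls)
#> Cases: 63
#> PRE: 49/63 (0.7778)   AUC: 0.9936
```

The held-out gene `g0003` is recovered at rank 1 out of 297 candidates:
its diffusion profile correlates more strongly with the disease profile
than any other gene's. Over all 63 leave-one-out cases of this bundle,
49 held-out genes rank first among 100 candidates (PRE 0.778) and the
rank-ratio ROC has AUC 0.994.

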