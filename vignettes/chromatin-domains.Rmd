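---
title: "Hierarchical chromatin-state and domain annotation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical chromatin-state and domain annotation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`dihmm` fits a two-level hierarchical hidden Markov model to binarized
chromatin-mark tracks. Each 200 bp bin `i` carries an observation vector
`x_i` of 0/1 presence calls for `M` marks and a hidden pair state
`π_i = (j, μ)`: a nucleosome-level state `j ∈ 1..K_n` and a domain-level
state `μ ∈ 1..K_d`. The assumptions are:

1. **Markov property** of the pair chain, and **independence of
   observations** given the states, as in any HMM.
2. **Emissions depend only on the nucleosome level.** Given `j`, the marks
   are independent Bernoulli draws with success probabilities
   `e_{j·}` (the ChromHMM emission convention). A multinomial over all
   `2^M` mark patterns would be strictly more expressive but needs
   exponentially more parameters; we do not implement it.
3. **Nucleosome transitions are domain-dependent**: the chain `j → k` uses
   the matrix `t^{(ν)}` of the *destination* domain `ν`. This convention
   (rather than the source domain) also fixes how transition mass is
   credited during training: each expected transition count is attributed
   to the destination domain, which only matters at block boundaries since
   elsewhere source and destination coincide.
4. **Domain transitions are block-restricted.** The domain state is
   constant within blocks of `D_S` consecutive bins and may change only
   when a step crosses a block boundary, with matrix `T`. The composite
   transition is therefore `δ_{μν} t^{(ν)}_{jk}` inside blocks and
   `T_{μν} t^{(ν)}_{jk}` at boundaries. A structural consequence — and a
   useful invariant for testing — is that every domain segment is a
   multiple of `D_S` bins (4 kb at the defaults), except a possibly shorter
   chromosome-terminal segment, and the posterior domain marginal is
   exactly constant within each block.

**Boundary indexing.** With 0-based bins, the step entering bin `i` permits
a domain change iff `i mod D_S == 0` and `i > 0`; blocks are
`[b·D_S, (b+1)·D_S)`. A trailing partial block is treated as a block (the
domain is constant on it, emissions are unchanged) and is annotated rather
than dropped, flagged only by its shorter length.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `bin_size` | 200 bp | one nucleosome per bin; the resolution of the binarized tracks |
| `block_size` (`D_S`) | 20 bins | domain resolution of 4 kb; small enough to trace sub-TAD structure, large enough that domain states describe a grammar rather than single bins |
| `n_nuc`, `n_dom` | 30, 30 | reference configuration for human chromatin with 9 marks; for simulation fixtures much smaller models are used |
| `p_threshold` | 1e-4 | Poisson upper-tail threshold for binarization |
| `shift` | 100 bp | 5′-end shift toward the fragment centre before binning; 0 disables |
| `pseudocount` | 1e-6 | additive smoothing in every counted update; prevents absorption of parameters at exactly 0, at the cost of an O(pseudocount) violation of exact EM monotonicity |
| `tol` | 1e-4 | Baum–Welch stop: absolute log-likelihood gain per iteration |
| `max_iter` | 500 | EM iteration cap |

**Binarization.** The background rate of each mark is its mean count per
bin over the chromosome being binarized; a bin is called present iff its
count `c ≥ 1` and `P(X ≥ c | λ) ≤ 1e-4`. Whether the background should be
per chromosome or genome-wide is a judgement call — per chromosome is the
simplest reading and is what `poisson_binarize()` does on its one-
chromosome input; callers can pool counts first if they prefer a global
rate. No input-track subtraction is performed. The `c ≥ 1` guard makes
explicit that a zero count is never "enriched", however small λ is.

**Convergence metric.** We stop when the *absolute* gain in total
log-likelihood falls below `tol`, not the gain relative to `|log L|`. On
genome-scale data `|log L|` is of order 1e5–1e6, so a relative rule halts
while parameter estimates are still moving at the second decimal; an
absolute threshold of 1e-4 is reached only once successive iterates agree
far below the statistical precision of the data. `tol = -Inf` forces an
exact iteration count, which the test suite uses for trace comparisons.

## Initialization

Baum–Welch only finds a local optimum, so the starting point matters. We
initialize by clustering at both scales:

1. **Nucleosome level.** The observed 0/1 mark patterns are clustered into
   `n_nuc` centres by greedy farthest-point k-centre under Hamming
   distance, *weighted by pattern frequency*: the next centre maximizes
   (count × distance to nearest centre). With unit weights this is the
   classic greedy 2-approximation; the weighting matters because plain
   max–min k-centre is defined by its outliers and will happily pick a
   rare, fully-flipped noise pattern as a centre, which merges true states
   downstream. The first centre is the most frequent pattern; ties break
   lexicographically, making the procedure deterministic.
2. **Domain level.** Each block is summarized by its composition vector
   (fraction of each nucleosome state), and compositions are clustered by
   the same weighted greedy rule under Euclidean distance.
3. **Parameter estimates.** All four families are counted from the hard
   assignment with the additive pseudocount and row-normalized. The
   emission rows are then **shrunk toward 0.5** with weight 0.25. Hard
   assignment saturates emissions at the extremes of the data (a bin
   assigned to a centre contributes its marks wholesale), and a saturated
   emission row is a self-consistent fixed point of EM: a state whose
   probability for a mark is ~0 receives ~0 posterior mass at bins where
   the mark is on, so the estimate never moves. Starting in the interior
   restores EM's ability to reassign bins. The weight 0.25 is not tuned to
   any particular noise level; any moderate interior shift serves.

## The generative simulator

`simulate_tracks()` / `sample_path()` / `sample_observations()` sample from
the model exactly as inference assumes it: initial pair from `P0`; at block
boundaries the new domain first (from `T`), then the nucleosome step under
the new domain's matrix — the same destination-domain convention, so
simulation and inference are adjoint. `sample_counts()` adds a Poisson
read-count layer (background vs enriched rates) to exercise binarization
end to end. Sub-seeds are derived deterministically from the bundle seed
(path `i`: `seed + 2i − 1`; observations: `seed + 2i`), so bundles
regenerate bit-identically and single sequences can be re-drawn alone.

`make_fixture_model()` builds the recovery fixture: emission rows are
`0.5 ± separation` arranged as the binary code of the state index, so all
rows are distinguishable; each domain biases nucleosome transitions toward
its own preferred subset of nucleosome states (round-robin partition,
diagonal 0.9 for preferred states). The domain-specific preference is what
makes the *domain* parameters identifiable — if all domains shared one
transition matrix, `T` could not be recovered from data.

What the simulator emulates: the model's own dependence structure, mark
noise through Bernoulli emissions, domain-scale persistence. What it does
not: read-level artefacts (fragment-length variation, GC and mappability
bias, duplicated reads), correlated marks beyond what states induce,
copy-number effects, and real chromatin's unknown deviation from the Markov
assumptions. Passing recovery tests therefore demonstrates correctness of
the algorithms under the model, not that real chromatin satisfies the
model.

## Numerical choices

* All recursions are scaled: the per-position normalizer makes the rescaled
  forward row sum to 1, the likelihood is the product of the scales, and
  the backward pass reuses the same scales so `α̂·β̂` is directly the
  posterior.
* If the total probability mass at a position falls to ≤ 1e-300 the
  forward pass aborts with the offending position rather than silently
  renormalizing — this only happens for structurally inconsistent inputs
  (e.g. all-zero emission rows against observed marks).
* Viterbi runs in log space; ties break toward the lowest
  (nucleosome, domain) pair in lexicographic order. Posterior decoding
  picks each block's domain as the argmax of the block-constant domain
  marginal, then each bin's nucleosome state conditional on that domain,
  ties to the lowest index; block constancy holds by construction.
* Training never materializes the `(K_n·K_d)²` composite transition
  matrix; the dense form exists only in `pair_marginals()` (for inspection
  and tests) and in the enumeration oracle of the test suite.
* Model files are JSON at full floating-point precision with a format
  version tag; round trips are exact.

## The similarity score

To compare two segmentations `X` and `Y`, each state is represented by its
frequency vector over 4 kb windows (bp coverage fraction; at 200 bp bins
and 4 kb windows, bin counting and bp fraction coincide). For each state
`k` that is dominant in at least one window of `X`, we take the best
Pearson correlation between `X_k` and any `Y_j`, weighted by the
specificity of the mapping: the Gini index (relative mean absolute
difference, normalized by `(K−1)/K` to reach 1 at a point mass) of the
distribution of `Y`'s dominant states over the windows where `X`'s
dominant state is `k`. The direction score averages these products over
dominant states, and the reported score is the mean of both directions.
Identical segmentations score exactly 1 under any relabelling; independent
segmentations score near 0 (the correlations vanish). Degenerate constant
frequency vectors contribute 0 and unannotated windows are ignored. The
*combination* of these two ingredients — best-match correlation and
conditional Gini specificity — follows the published description of the
score's components; the exact published functional form is not available,
so this reconstruction is the package's own and is pinned down by its
invariants (identity = 1, label-permutation invariance, symmetry, null
→ 0), which the test suite asserts.

Similarly, the Gini convention used is the relative mean absolute
difference `Σ_{a,b}|p_a − p_b| / (2K² p̄)`, which is 0 for a uniform vector
and `(K−1)/K` for a point mass — the only convention consistent with both
stated anchor values.

## Problem sizes used in verification

The test suite and `scripts/acceptance.R` use sizes chosen to make each
property measurable while keeping the whole verification run in minutes on
one CPU: exhaustive-enumeration checks on toys with `(K_n·K_d)^L ≤ 5×10^4`
paths; flat-HMM equivalence over 20 EM iterations at `L = 5000`; EM
monotonicity over 10 random problems × 50 iterations; full-pipeline
parameter recovery at `L = 200{,}000` bins with the
`K_n = 4, K_d = 2, M = 5, D_S = 10, separation = 0.35` fixture (emission
max-abs error ≲ 0.003 at convergence); the structural 4 kb minimum domain
size over 100 decoded sequences of 2,000 bins; and the similarity-score
null at 50,000 windows.

## Known limitations

* Full-batch EM only; one training sweep is `O(L·K_d·K_n²)` and the reference-
  scale configuration (30×30 states, one chromosome of a mammalian genome)
  is compute-heavy, which is why training is usually done on one
  chromosome and the fitted model then applied genome-wide.
* No model selection for `K_n`/`K_d`; choosing state counts is the user's
  judgement, aided by `similarity_score()` across settings.
* Two levels only. The recursion generalizes to more levels (emissions at
  the lowest level, neighbour-level coupling, higher-level transitions at
  coarser block boundaries), but this package does not implement it.
* Binarization offers no control-track normalization, duplicate filtering
  or mappability correction; inputs are expected to be pre-filtered.
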