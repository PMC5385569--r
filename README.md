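# dihmm — hierarchical chromatin-state and domain annotation

Chromatin-state segmentation methods label the genome at nucleosome
resolution (~200 bp) from combinatorial histone-mark patterns, but
regulatory organization also operates at much larger scales: broad promoter
and super-enhancer domains, polycomb blocks, heterochromatin. `dihmm`
implements a two-level hierarchical hidden Markov model that annotates both
scales **simultaneously**: nucleosome-level states emit the binarized
multi-mark ChIP-seq signal of each 200 bp bin, while domain-level states
govern the *transition grammar* of the nucleosome states across blocks of
consecutive bins. It is aimed at computational epigenomics users who work
with ChromHMM-style binarized tracks and want domain-scale structure
without a second, ad hoc segmentation pass.

## The model

For bins `i = 1..L` with binarized mark vector `x_i`, the hidden state is a
pair `π_i = (j, μ)` of a nucleosome-level state `j ∈ 1..K_n` and a
domain-level state `μ ∈ 1..K_d`, with:

* **Emissions** — independent Bernoulli per mark, depending only on the
  nucleosome-level state: `P(x_i | j) = Π_m e_{jm}^{x_im} (1−e_{jm})^{1−x_im}`.
* **Domain-dependent nucleosome transitions** — `t^(ν)_{jk}`, the
  probability of `j → k` given the *destination* domain `ν`.
* **Block-restricted domain transitions** — the domain state is constant
  within blocks of `D_S` bins (default 20) and may change, with matrix
  `T_{μν}`, only at block boundaries. At 200 bp bins this makes the minimum
  domain size `D_S × 200 bp = 4 kb`.
* A joint initial distribution `P0(j, μ)`.

The composite transition is `δ_{μν} t^(ν)_{jk}` inside blocks and
`T_{μν} t^(ν)_{jk}` at boundaries. Inference uses scaled forward–backward
recursions (`O(L·K_d·K_n²)` per sweep, compiled core); training is
hierarchical Baum–Welch over any number of (cell type, chromosome)
sequences sharing one parameter set, initialized by frequency-weighted
k-centre clustering at both scales. Upstream, read counts are binarized per
mark with a Poisson background model at P ≤ 1e−4; downstream, the package
computes fold enrichments `(m/n)/(M/N)` with Fisher exact tests,
strand-aware TSS profiles, expression-by-state z-score summaries, and a
segmentation similarity score combining best-match Pearson correlation with
a conditional Gini specificity index.

## Worked example

Everything below is synthetic and self-contained — the package ships a
generative simulator, so no external data are needed.

```r
library(dihmm)

truth <- make_fixture_model(n_nuc = 4, n_dom = 2, n_marks = 5,
                            block_size = 10, separation = 0.35)
sim <- simulate_tracks(truth, length_bins = 20000, seed = 1)
fit <- dihmm(sim$tracks, n_nuc = 4, n_dom = 2, block_size = 10)
fit
#> Hierarchical chromatin-state model fit
#>   states: 4 nucleosome x 2 domain; block size 10 bins
#>   sequences: 1 (sim1:chrS)
#>   log-likelihood: -46758.241 after 500 EM iteration(s)

matched <- match_states(fit$model, truth)
max(abs(matched$emissions - truth$emissions))
#> 0.0157

seg <- predict(fit, sim$tracks[[1]], type = "segments")
head(subset(seg, level == "domain"), 3)
#>  chromosome start   end  level state cell_type
#>        chrS     0 26000 domain     1      sim1
#>        chrS 26000 50000 domain     2      sim1
#>        chrS 50000 54000 domain     1      sim1
min(subset(seg, level == "domain", end - start))
#> 2000
```

The fitted emissions recover the generating model to within 0.016 after
relabelling, and every decoded domain segment is a multiple of
`block_size × bin_size` (2 kb here; 4 kb at the genome defaults) — the
structural guarantee of the block constraint. `write_bed()` exports either
level as BED9 for genome browsers, and `fold_enrichment()`,
`tss_enrichment_profile()`, `expression_by_state()` and
`similarity_score()` provide the downstream statistics.

A thin command-line wrapper covering the same pipeline
(`simulate`, `binarize`, `init`, `train`, `annotate`, `evaluate`) is
installed at `exec/dihmm.R`:

```sh
Rscript exec/dihmm.R simulate --length 20000 --seed 0 -o sim_out
Rscript exec/dihmm.R train --binarized sim_out --n-nuc 4 --n-dom 2 -o model.json
Rscript exec/dihmm.R annotate --model model.json --binarized sim_out -o annotation
```

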