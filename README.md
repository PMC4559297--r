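# dmi — Differential Multi-Information modulator screening

`dmi` infers **post-translational modulators of a transcription factor**
(kinases, phosphatases) from a compendium of gene expression profiles. It is
aimed at systems biologists who know a TF's target genes and want a ranked
list of candidate regulators of the TF's *activity* — interactions that
high-throughput transcriptomics cannot see directly, because
phosphorylation leaves the TF's own mRNA unchanged.

The working hypothesis: when a modulator M activates a TF, the TF's target
genes G¹…Gᵈ become co-regulated; when M is absent, that co-regulation is
lost. For each candidate M the samples are sorted by M's expression and
split into equal bins, and the screen computes

> ΔI = I(G¹…Gᵈ | M high) − I(G¹…Gᵈ | M low),

where I is the **Rényi Multi-Information** (order α = 0.99) — the
divergence between the joint distribution of the targets and the product of
their marginals, zero exactly under independence. I is estimated by the
empirical copula transformation (per-gene ranks, so the statistic is
invariant to any monotone per-gene normalization) followed by a generalized
nearest-neighbor-graph entropy estimator,

> Ĥ = 1/(1−α) · log( L_p / (γ·n^(1−p/d)) ), p = d(1−α), Î = −Ĥ(copula),

with γ calibrated so Ĥ = 0 on uniform unit-cube samples. Positive ΔI means
M activates the TF, negative ΔI means M inhibits it. Significance comes
from a permutation null (random gene sets of the same size, same bins) with
Benjamini–Hochberg correction; candidates whose expression barely changes
between bins can be removed by a fold-change prefilter.

The package also ships the in-silico benchmark generators (D1, D2 and the
four noisy-bin variants, with recorded ground truth), estimator-convergence
generators with closed-form true values, and evaluation tools
(PPV-sensitivity and ROC curves, 11-point interpolated average precision,
vertical ROC averaging, pre-ranked gene-set enrichment).

## Worked example

Generate the D1 benchmark (100 profiles; 10 known targets, 10 hidden
targets, 50 candidate modulators of which 20 truly effective) and screen
all candidates:

```r
library(dmi)

d1  <- generate_dataset(synthetic_spec("d1", seed = 42))
cfg <- dmi_config(n_bins = 3, n_permutations = 500,
                  fc_threshold = -Inf,   # prefilter off: raw-scale simulation
                  seed = 42)
res <- run_dmi(d1$expr, d1$truth$target_ids, d1$truth$modulator_ids, cfg)
res
#> DMI screen: 50 candidates, 50 passed the fold-change filter
#>   bins = 3, fc > -Inf (log2), L = 500, alpha = 0.99
#>    modulator_id   i_low i_high delta_i delta_i_norm fold_change p_value
#> 1         M0017 -0.4969  3.622   4.119       1.3180       1.436       0
#> 2         M0013 -0.2242  3.741   3.966       1.1275       1.443       0
#> 3         M0010 -0.3448  3.429   3.773       1.2237       1.275       0
#> ...
```

Every row is one candidate: `i_high`/`i_low` are the multi-information of
the 10 target genes (in nats) inside the high- and low-expression bins of
that candidate, `delta_i` their difference (positive: the targets
co-regulate when the candidate is abundant, i.e. an activating modulator),
`p_value` the fraction of 500 random 10-gene sets with a larger ΔI, and
`rank` the final ordering (descending ΔI, ties by p-value). Scoring the
ranking against the recorded ground truth:

```r
eff    <- d1$truth$effective_modulator_ids
ranked <- res$modulator_id[order(res$rank, na.last = NA)]
sum(head(ranked, 20) %in% eff)
#> [1] 20
```

All 20 effective modulators occupy the top 20 ranks — a perfect
PPV-sensitivity curve (interpolated precision 1 at every sensitivity
level). The top-ranked decoys follow at ΔI roughly a third of the weakest
effective modulator's.

A thin command-line front end covering the same pipeline
(`simulate`, `run`, `evaluate`, `enrich`, `calibrate-gamma`) is installed
at `system.file("cli", "dmi.R", package = "dmi")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","dmi.R",package="dmi"))') \
    simulate --preset d1 --seed 1 --out sim/
```

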