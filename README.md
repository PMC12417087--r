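# dynetrank

Disease-gene prioritization on a background–temporal multilayer network.

Staged diseases — the motivating case is leukemia progressing through
clinically defined phases — reorganize their molecular interaction networks
as they advance, but most network-based gene prioritization runs on a single
static protein–protein interaction (PPI) network. `dynetrank` is for
computational biologists who have (i) a gene × sample expression matrix with
samples annotated by disease stage, (ii) a weighted PPI network
(STRING-style edge list), and optionally (iii) a known disease-gene list to
benchmark against. It ranks every gene in the network for disease
association while using the stage structure, and ships a synthetic benchmark
generator for method evaluation.

## Method

1. **k-sigma dynamic networks.** For each gene, activity thresholds
   `Th_k = mean + k·σ·(1 − 1/(1+σ²))`, k = 1,2,3, computed over all samples
   (σ unbiased). Each sample value maps to an active probability
   0.99 / 0.95 / 0.68 / 0 by band; each sample's network reweights the static
   adjacency `A'[i,j] = AP(i)·A[i,j]·AP(j)`; the stage network `A[s]` is the
   entrywise mean over the stage's samples.
2. **Multilayer coupling.** The S stage layers form a block-tridiagonal
   transition matrix `TS` (diagonal blocks `(1−μ)A[s]`, identity couplings
   `μI` between adjacent stages only). The static background `B` couples to
   every stage counterpart:
   `TL = [[(1−δ)B, δJᵀ], [δJ, TS]]` with `J = (1/S)·e⊗I`. `TL` is column
   normalized; dangling columns teleport to the restart vector.
3. **Seeded random walk with restart.** Per-stage one-vs-rest absolute
   t-statistics seed the stage layers; their mean seeds the background. The
   stacked, globally normalized vector `PRS` drives
   `P(t+1) = (1−γ)·TLc·P(t) + γ·PRS` to an L1 tolerance of 1e-6. Genes are
   ranked by the background block of `P∞` (defaults δ = μ = 0.5, γ = 0.1).
4. **Benchmarking.** ALI / RC / WG control-set schemes; top-k precision and
   recall, AUROC (Mann–Whitney form), AUPRC (step interpolation), computed
   on the ranking restricted to the candidate set.

## Worked example

Simulate a staged dataset with a planted 20-gene disease module
(500 genes, 3 stages × 8 samples, stage-progressive shifts of
0.5/1.5/3 noise-sds), rank, and evaluate:

```r
library(dynetrank)

d  <- simulate_dataset(synthetic_config(seed = 42))
rk <- run_rank(d$expr, d$stages, d$network)   # full multilayer walk
rk
#> ranked_gene_list: 500 genes; top of list:
#>    gene       score
#> 1 g0005 0.007642588
#> 2 g0031 0.003512826
#> 3 g0001 0.003468026
#> 4 g0011 0.003252378
#> 5 g0004 0.003211210

run_evaluate(rk, d$module, scheme = "WG", ks = c(5L, 10L, 50L))
#> evaluation_report (scheme=WG): 20 test vs 480 control genes
#> AUROC = 0.9110, AUPRC = 0.1856
#>   k hits precision recall
#>   5    0       0.0   0.00
#>  10    1       0.1   0.05
#>  50   10       0.2   0.50
```

Scores are stationary probabilities (they sum to at most 1 over the
background layer), so only their order matters. Here half the planted
module sits in the top 50 of 500 genes and the whole-genome AUROC is 0.91;
`mode = "static_only"` (the classical single-network RWR ablation) scores
lower on the same data — the gap is what the dynamic stage layers buy.

Real data enter through `read_expression()`, `read_stage_annotation()`,
`read_edge_list()` (`score_divisor = 1000` for STRING combined scores) and
`read_gene_list()`; `run_rank()` also accepts the file paths directly. A
thin CLI wrapping the same functions lives at `inst/cli/dynetrank.R`
(subcommands `simulate`, `rank`, `evaluate`).

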