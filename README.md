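# prognet

Prognostic module networks from gene co-expression data.

`prognet` is for cancer genomics researchers who want prognostic **gene
modules** — functional units whose joint expression stratifies patient
survival — rather than fragile single-gene signatures. Its premise is that a
module's importance comes from two sources: how stably its expression
predicts survival, and how strongly it cross-talks with other modules. The
package combines both with a PageRank-style propagation over a network whose
*nodes are modules*.

## Method

Given a genes × samples expression matrix and per-sample survival data
(`time`, `event`):

1. **Co-expression network.** Pearson correlations between all gene pairs;
   each gene is linked to its k = 10 most correlated partners (rank-based,
   not threshold-based, so weakly but coherently co-expressed pathways are
   kept). A power-law fit of the degree distribution provides a scale-free
   QC statistic.
2. **Module detection.** An MCODE-style algorithm seeds clusters at vertices
   whose neighborhood has a heavy k-core and grows them greedily; modules
   with fewer than 5 genes are dropped.
3. **Module cross-talk network.** For every module pair, the number of
   co-expression edges crossing the pair is compared against 1000 random
   gene-set draws of the same sizes; pairs with permutation p < 0.05 become
   edges.
4. **Prognostic profiling.** Each module's per-sample statistic is the mean
   expression of its genes, s = (Σᵢ eᵢ)/n. On 400 resamples of 90% of the
   training samples, a univariate Cox model of survival on s is fitted; the
   *significance frequency* (fits with p < 0.05) is the module's prognostic
   prior p_j.
5. **GeneRank prioritization.** Solve
   (I − d·WᵀD⁻¹) r = (1 − d) p with damping d = 0.70, where W is the module
   network adjacency and D its degree diagonal; equivalently the fixed point
   of rⱼ = (1−d)pⱼ + d·Σᵢ wᵢⱼ rᵢ/degᵢ. The top 5% of modules by r are the
   prognostic modules.
6. **Evaluation.** Risk Score = Σ s(positive-coefficient modules) −
   Σ s(negative-coefficient modules); patients split into equal high/low
   groups; log-rank test and hazard ratio per cohort; across cohorts
   Dscore = −Σ log₁₀(pᵢ). Baselines: resampling-rank "control" modules and a
   random-gene-set permutation test. Hypergeometric enrichment against any
   annotation list (cancer genes, drug targets, gene-age classes).

A synthetic-data generator plants co-expressed modules whose latent activity
drives an exponential survival hazard, so the whole pipeline is testable
end to end without any cohort download.

## Worked example

```r
library(prognet)

# synthetic cohort: 6 planted 12-gene modules, 2 of them prognostic
cfg <- synth_config(n_genes = 300, n_samples = 400,
                    module_sizes = rep(12L, 6),
                    beta = c(0.8, 0.8, 0, 0, 0, 0), seed = 7)
dat <- generate_synthetic(cfg)
write_expression(dat$expr, "demo/expression.tsv")
write_clinical(dat$clinical, "demo/clinical.tsv")

res <- run_pipeline(list(expression = "demo/expression.tsv",
                         clinical = "demo/clinical.tsv",
                         outdir = "demo/out", seed = 1,
                         fraction = 0.25))
#> stage network: 300 genes, 400 samples
#> stage network: 300 nodes, 1946 union edges (3000 selections), mean neighbors 12.97
#> stage modules: 10 modules of size >= 5
#> stage modnet: 1 cross-talk edges among 10 modules
#> stage profile: 10 modules profiled (400 resamples)
#> stage rank: 3 modules selected
#> stage evaluate: Dscore 19.32

head(res$ranked[, c("module_id", "sig_frequency", "mean_coefficient",
                    "r", "rank", "selected")])
#>   module_id sig_frequency mean_coefficient           r rank selected
#> 1         2           400       0.78191288 0.300000000    1     TRUE
#> 2         3           400       0.57459166 0.300000000    2     TRUE
#> 3         4             4       0.08393647 0.006911765    3     TRUE
#> 4         8             1      -0.13690851 0.005588235    4    FALSE
#> 5         1             5       0.08655933 0.003750000    5    FALSE
#> 6         6             4       0.08463847 0.003000000    6    FALSE
```

Reading the output: the two planted prognostic modules were detected as
modules 2 and 3 and are significant in all 400 Cox resamples
(`sig_frequency` 400, positive mean coefficient — high expression is
hazardous), so GeneRank puts them on top; the remaining modules sit at the
~5% null level. The training-set Dscore of 19.32 is −log₁₀ of the log-rank
p-value of the high/low risk-group split. The output directory contains the
network (GraphML), module table (TSV), module network (GraphML), prognostic
profiles, GeneRank ranking, survival report, and a checksummed
`manifest.json`.

A shell front end with `simulate` / `run` / `stage` subcommands is installed
at `inst/cli/prognet`.

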