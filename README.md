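# splicefun

Projection of transcriptional units (TUs) and their alternative splice
variants onto the functional space of the proteome, for researchers
studying how alternative splicing diversifies protein function across
organisms.

## The method

The unit of function is the **functional label (FL)**: the unique, sorted,
deduplicated combination of annotation keywords carried by a protein
isoform. Given a table mapping protein isoforms to TUs and keywords, the
package:

1. **Builds FL catalogues** — one FL per distinct keyword combination,
   with deterministic identifiers `FL{scope}{n}` assigned in lexicographic
   order of the combinations, and intersects catalogues across organisms
   to find shared (conserved) function sets.
2. **Classifies TUs** as *monoform* (all annotated isoforms share one FL),
   *polyform* (two or more distinct FLs), or *unannotated*, and reports
   the polyform/monoform percentage, a correlate of organism complexity.
3. **Detects candidate functional switches**: polyform TUs containing an
   isoform pair with disjoint keyword sets (Jaccard index
   `|A∩B| / |A∪B| = 0`).
4. **Fits the three relation histograms** — FLs per TU, TUs per FL, splice
   variants (SVs) per TU — with the two-component mixture

   `P(X = m) = s·P₁(m) + (1−s)·P₂(m)`,   m = 1, …, J,

   where `P₁` is a discretized exponential `a·exp(−b·m)` body and `P₂` a
   generalized discrete Pareto (GDP) tail

   `f(m) = C / (m + b)^(k+1)`,   `C⁻¹ = Σ_{i=1..J} (i + b)^−(k+1)`,

   with `k > 0`, `b > −1`; `b = 0` is the standard discrete Pareto, and
   slope `k + 1 ≈ 2` is the Zipf–Lotka regime. Components are fitted per
   regime (body below the breakpoint, default `m* = 10`; tail at and
   above it), by least squares on frequencies or by multinomial maximum
   likelihood.
5. **Builds Splice-Function Networks (SFNs)**: weighted graphs on FL nodes
   where an edge links two FLs carried by the same polyform TU, with
   weight equal to the number of shared TUs; reports node/edge counts,
   degree heterogeneity (coefficient of variation of degrees), average
   neighbors, components and hub FLs, and exports SIF/GraphML for
   Cytoscape.
6. **Scores keyword over-representation** in TU groups (e.g. polyform vs
   monoform) with an upper-tail hypergeometric test and a modified
   Bonferroni correction (multiply by the number of terms present in the
   study set; report below 1e−4).

A synthetic-data generator (`sim_config()` / `generate_organism()`)
emulates the statistical structure of curated isoform protein sets —
exponential-like FLs-per-TU, heavy-tailed TUs-per-FL, mixture-law
SVs-per-TU, a configurable polyform fraction — so the entire pipeline runs
and is tested without database downloads.

## Worked example

```r
library(splicefun)
cfg <- sim_config(n_tus = 5000L, seed = 2010L)
ds  <- generate_organism(cfg)
ds
#> organism_dataset: synth
#>   proteins: 13403  TUs: 5000
#>   catalogue: 772 FLs (scope 'synth')
#>   classes: monoform=3074 polyform=426 unannotated=1500

tu_summary(ds)
#> synth: 426 polyform / 3074 monoform (13.86%), 1500 unannotated, 2.73 SVs/TU

fit_mixture(svs_per_tu(ds), breakpoint = 10, method = "mle")
#> mixture fit: s = 0.9803, breakpoint m* = 10, J = 44
#>   body:  exponential fit: a = 2168 +/- NA, b = 0.4848 +/- 0.00968 (rmse 14.01)
#>   tail:  GDP fit: k = 16.72 +/- 37.5 (slope 17.7), b = 71.94 +/- 191, J = 44 (rmse 2.071)

g <- build_sfn(ds)
network_stats(g)
#> network_stats: 339 nodes, 505 edges, heterogeneity 2.303, avg neighbors 2.979, 30 components
head(rank_hubs(g, 3))
#>        fl_id degree weighted_degree             keywords
#> 1  FLsynth49     94             132 KW0008;KW0207;KW0333
#> 2 FLsynth756     53              76        KW0356;KW0386
#> 3 FLsynth191     36              52 KW0034;KW0133;KW0305
```

Reading the output: 13.86% is the polyform/monoform percentage (426/3074);
the body rate `b ≈ 0.48` recovers the configured exponential decay of SV
counts, while the GDP tail parameters carry large standard errors at this
sample size — only ~2% of TUs fall in the tail regime, so tail estimates
stabilize at larger `n_tus`. The hub FLs are the keyword combinations
co-occurring with the most other functions through shared polyform TUs.

A shell interface wrapping the same functions ships in
`inst/scripts/splicefun`:

```sh
Rscript inst/scripts/splicefun simulate --out-dir out --seed 2010 --n-tus 5000
Rscript inst/scripts/splicefun classify --input out/dataset.tsv --organism synth --out-dir out
```

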