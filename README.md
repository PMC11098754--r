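# clonetrace

Whole-tissue lineage tracing by genomic DNA barcoding: every starting
cell of a growing tissue (such as a cerebral organoid grown from tens of
thousands of barcoded stem cells) carries a heritable, neutral DNA
barcode, and bulk sequencing of the grown tissue reads out the size of
every surviving clone. `clonetrace` is an R package for the
computational side of such studies, aimed at stem-cell and developmental
biologists who want to simulate, quantify and compare clonal growth:

* **Growth model.** A lineage is a state `(s, a, n)` of symmetrically
  dividing progenitors, asymmetrically dividing self-renewing
  progenitors and postmitotic cells, evolving through three Poisson
  event channels — symmetric division (`s -> s+1`, rate `r_s` per S cell
  per day), transition (`s -> s-1, a -> a+1`, rate `r_a`) and asymmetric
  division (`n -> n+k`, rate `r_n` per A cell), with optional direct
  neurogenesis (`s -> s-1, n -> n+2`). Simulation uses binomial
  tau-leaping with automatic step `dt = 0.01 / max(r)` (per-cell double
  event probability ≈ 5e-5), validated against an exact Gillespie
  sampler. An organoid is 10,000 independent lineages.
* **Synthetic sequencing data.** Semi-random barcode libraries with
  library identifiers, multinomial read sampling, per-base substitution
  errors, cross-sample contamination, and chimeric two-genotype
  scenarios with growth ablation from a given day.
* **Quantification pipeline.** Barcode extraction and index correction,
  directional Hamming-distance clustering of sequencing errors, the 20×
  cross-sample contamination rule, density-based sample-specific read
  thresholds, outlier-sample detection, and reads-per-million (RPM)
  normalization.
* **Distribution statistics.** Rank abundance, top-percentile shares,
  Lorenz-style cumulative contribution, mean/median divergence, and
  in-silico subsampling envelopes.
* **Optimal transport.** Rank-wise 1-D optimal transport between two
  lineage-size distributions under the absolute log2 fold-change cost
  `sum |log2 x_(i) − log2 T(x_(i))|`, with lcm lineage weighting for
  unequal lineage numbers, LOWESS-smoothed fold-change curves averaged
  over replicates, fold-change densities, and permutation nulls.

See the vignette (`vignettes/clonal-lineage-tracing.Rmd`) for the model,
its assumptions, parameter choices and numerical details.

## Worked example

Simulate an organoid in the equal-rates regime and track how clonal
output concentrates as neurogenesis proceeds:

```r
library(clonetrace)

p <- model_params(r_s = 1, r_a = 1, r_n = 0.5, k = 3, t_end = 40,
                  n_lineages = 2000, record_times = c(11, 25, 40), seed = 1)
sim <- simulate_organoid(p)
for (tm in c(11, 25, 40)) {
  sz <- lineage_sizes(sim, tm)
  cat(sprintf("day %2d: top-5%% share %.3f  mean/median %.2f\n",
              tm, top_percentile_share(sz, 5),
              divergence_summary(sz)$mean_median_ratio))
}
#> day 11: top-5% share 0.391  mean/median 3.88
#> day 25: top-5% share 0.602  mean/median 7.88
#> day 40: top-5% share 0.721  mean/median 12.39
mean(cell_type_composition(sim, 40)$contains_s)
#> [1] 0.021
```

The top 5% of lineages hold a growing majority of all progeny (39% →
72%), the mean pulls away from the median, and by day 40 only ~2% of
lineages still contain symmetrically dividing cells — those are the
large, homogeneously growing ones, while lineages that lost their S
cells froze at diverse sizes.

Compare genotypes in a chimeric organoid in which genotype A is
growth-ablated from day 11 (e.g. puromycin on non-resistant cells),
using optimal transport on the organoid-level RPM sizes:

```r
libA <- generate_barcode_library(600, 30, "WT",    identifier = "AACCGG", seed = 2)
libB <- generate_barcode_library(600, 30, "PuroR", identifier = "TTGGCC", seed = 3)
pc <- model_params(r_s = 0.5, r_a = 0.5, r_n = 0.5, k = 3, t_end = 25,
                   n_lineages = 1000, record_times = c(15, 20, 25))
ch <- generate_chimera_scenario(pc, pc, mix_fraction = 0.5,
        ablation = list(start_day = 11, growth_penalty = 0.1),
        libraries = list(libA, libB), seed = 4)
for (tm in c(15, 20, 25)) {
  d <- ch[ch$time == tm, ]
  d$rpm <- d$cells * 1e6 / sum(d$cells)
  tr <- rank_transport(d$rpm[d$genotype == "A"], d$rpm[d$genotype == "B"])
  cat(sprintf("day %d: mean log2 FC (resistant vs ablated) %.2f\n",
              tm, mean_log2fc(tr)))
}
#> day 15: mean log2 FC (resistant vs ablated) 0.67
#> day 20: mean log2 FC (resistant vs ablated) 1.15
#> day 25: mean log2 FC (resistant vs ablated) 1.46
```

The resistant population outgrows the ablated one by an increasing
factor over time, the signature the transport framework is built to
quantify. `fold_change_curve()` and `fold_change_density()` resolve
this mean shift across lineage sizes and across the population.

A full synthetic run — simulate, generate FASTQ, count, filter,
summarize, compare — is driven by a single YAML/list configuration via
`run_pipeline()`; outputs (TSV tables, FASTQ triplets, a key=value log
and a manifest) are byte-identical across runs with the same seed.

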