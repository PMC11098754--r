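---
title: "Modelling and measuring clonal growth with DNA barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring clonal growth with DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`clonetrace` supports whole-tissue lineage tracing by genomic DNA
barcoding, the setting in which every starting cell of a growing tissue
(for example a cerebral organoid grown from roughly 24,000 barcoded stem
cells) carries a heritable, selectively neutral DNA barcode, and bulk
sequencing of the grown tissue reads out the size of every surviving
clone. The package covers the four computational layers of such a study:

1. a stochastic model of clonal growth through symmetric and asymmetric
   stem-cell divisions (`model_params()`, `simulate_organoid()`);
2. a synthetic sequencing-data generator that turns simulated clones into
   barcode libraries and error-laden reads (`generate_barcode_library()`,
   `generate_reads()`, `generate_chimera_scenario()`);
3. a quantification pipeline from raw reads to cleaned, normalized
   lineage-size tables (`extract_barcodes()` through `normalize_rpm()`);
4. statistics of lineage-size distributions and a one-dimensional
   optimal-transport framework for comparing them across conditions
   (`top_percentile_share()`, `rank_transport()`, `fold_change_curve()`).

Because every layer can generate its own inputs, the full pipeline is
testable end to end without any external data.

# The growth model

A lineage (clone) is the set of descendants of one barcoded starting
cell. Its state is a triple of non-negative counts: `s` symmetrically
dividing progenitors (S cells), `a` asymmetrically dividing,
self-renewing progenitors (A cells) and `n` postmitotic cells (N cells,
e.g. neurons). Three event channels modify the state, each a Poisson
process per originating cell:

* symmetric division, rate `r_s` per S cell per day: `s -> s + 1`;
* transition, rate `r_a` per S cell per day: `s -> s - 1`, `a -> a + 1`;
* asymmetric division, rate `r_n` per A cell per day: `n -> n + k`.

The factor `k` abstracts amplification through intermediate progenitors:
one asymmetric event deposits `k` postmitotic cells at once, and the
intermediate generations are not tracked. A `direct_neurogenesis`
variant adds a fourth channel (`s -> s - 1`, `n -> n + 2` at rate
`r_dn`), and a `symmetric_only` variant switches all but the first
channel off. There are no death events, so lineage size `s + a + n` is
non-decreasing and every lineage survives.

## Numerical scheme

Lineages are advanced with a binomial tau-leaping scheme: over a step
`dt`, the number of events in a channel is drawn as
`Binomial(cells, rate * dt)`, evaluated at the step-start state, which
reproduces the exact per-channel mean `rate * cells * dt`. The step is
chosen automatically as `dt = 0.01 / max(rates)`, so the per-cell,
per-channel event probability never exceeds 0.01. What the binomial
draw cannot represent is the same cell firing twice within one step;
for a Poisson process at the maximal rate the probability of that is

```
1 - exp(-0.01) - 0.01 * exp(-0.01)  =  4.97e-5,
```

about 0.005% per step (`step_double_event_prob()`), two orders of
magnitude below the 1% design bound.

Two further numerical choices matter only in edge cases. First, the
symmetric-division and transition draws both read `s` independently, so
their combination can transiently oversubscribe the S pool; removal
draws are then capped (transition first, then direct neurogenesis) so
counts stay non-negative. Under the automatic step rule the cap fires
with probability below 1e-4 and has no measurable distributional
effect. Second, all lineages are advanced in one vectorized stream from
a single seed, so a simulation is reproducible bit for bit given
`seed` and `n_lineages`.

## Validation against an exact sampler

`exact_ssa_reference()` implements the event-by-event Gillespie
algorithm for the same continuous-time Markov model and serves as the
oracle in the test suite. Two analytic limits anchor both samplers: with
only symmetric divisions the model is a Yule process, whose mean size at
time `t` is `exp(r_s * t)` and whose size law is geometric with success
probability `exp(-r_s * t)`; with only transitions the S survival
probability is `exp(-r_a * t)`. The tests verify the tau-leap stepper
against these closed forms and against the SSA by two-sample
Kolmogorov-Smirnov comparison at alpha = 0.01 on 1e4 lineages.

## Default study conditions

An organoid is simulated as 10,000 independent lineages, each started
from one S cell. Event rates are not identifiable from bulk barcode
counts alone beyond their ratios; the reference configuration used
throughout the tests is `r_s = r_a = 1` per day (a progenitor cell cycle
of about one day, and the equal-rates regime that reproduces the
measured organoid distributions - see below), `r_n = 0.5` per day and
`k = 3`. Three regimes follow from the `r_s : r_a` ratio and are used as
qualitative fingerprints:

* `r_s > r_a`: S cells dominate; the distribution approaches the
  pure-symmetric shape;
* `r_s = r_a`: a critical regime in which a shrinking subpopulation of
  lineages retains S cells; retained lineages grow homogeneously large
  while lineages that lost their S cells freeze at diverse sizes - the
  top of the ranked distribution is homogeneous and the tail spans
  orders of magnitude, and the top-5% share of total progeny grows over
  time;
* `r_s < r_a`: S cells deplete and sizes become more uniform.

`fit_rates_grid()` scores candidate rate sets against an observed
distribution by the Kolmogorov-Smirnov statistic between
log-transformed, depth-normalized sizes plus the relative
lineage-count error, with lexicographic tie-breaking; it is a
brute-force grid fit, sufficient for the coarse grids on which the
regimes separate.

# The synthetic sequencing generator

`generate_barcode_library()` builds semi-random barcode libraries:
fixed-length nucleotide strings (default 50 bases) carrying a short
fixed library-identifier at a designed position, the remaining positions
drawn iid uniform from A/C/G/T (mean pairwise Hamming distance 0.75 per
random position). Two libraries with distinct identifiers keep two
co-cultured genotypes separable in one sequencing pool.

`generate_reads()` emulates amplification and sequencing: per sample,
`depth` reads are drawn multinomially with probabilities proportional to
clone cell counts; each base of read 1 and of both sample-index reads is
substituted independently at `substitution_rate` (every substitution
changes the base, so the nominal rate is the observed error rate); and a
`cross_sample_rate` fraction of reads is relabelled with another
sample's indexes, emulating the cross-sample contamination the 20x
filter must remove. Base qualities are constant placeholders: the
pipeline is count-based and never reads them.

`generate_chimera_scenario()` grows a two-genotype organoid in which
genotype A's rates are multiplied by `growth_penalty` from `start_day`
onwards. This abstracts chemical ablation (e.g. puromycin applied from
day 11 to a non-resistant genotype) as growth arrest; the model has no
death events, so cell loss is deliberately not represented. The
generator does **not** implement compensation - genotype B's dynamics
are unchanged by A's penalty - so any replenishment signal measured on
generated data reflects relative composition only.

What the generator does not emulate: PCR duplicates and UMI structure,
quality-score realism, chimeric reads, lineage dropout during early
aggregate formation, and spatial structure. Passing tests therefore
certify the pipeline's arithmetic and filtering logic under the stated
noise model, not robustness to every artefact of real libraries.

# The quantification pipeline

Stages run in a fixed order; each only merges or removes mass:

1. **Extraction** (`extract_barcodes()`): the viral barcode is the first
   50 bases of read 1; the sample is identified from the concatenated
   index pair, error-corrected against the sample sheet
   (`correct_sample_barcodes()`, unique neighbor within Hamming distance
   1; the known indexes must be pairwise more than 2 mismatches apart).
   Unassignable reads are tallied, never silently dropped.
2. **Clustering** (`cluster_viral_barcodes()`): sequencing errors are
   absorbed by directional ratio clustering - visiting barcodes in
   descending count order, a barcode merges into an accepted seed within
   Hamming distance 2 whose raw count is at least 10 times its own.
   Eligibility uses raw counts, which makes the outcome independent of
   absorption order. A pigeonhole segment index (any two barcodes within
   distance `d` share one of `d + 1` contiguous segments) keeps the
   search near-linear; an exhaustive double-loop reference implementation
   certifies it in the tests.
3. **Cross-sample filter** (`filter_cross_sample()`): a barcode found in
   another sample with a 20-fold or higher count (inclusive) is removed
   from the lower sample - low-level occurrences of a barcode dominating
   elsewhere are contamination, not biology.
4. **Read threshold** (`estimate_read_threshold()`,
   `apply_read_threshold()`): see below.
5. **Outlier samples** (`detect_outlier_samples()`): under independent
   draws from a library of complexity `B`, two samples with `n_i` and
   `n_j` barcodes share about `Binomial(n_i, n_j / B)` of them; samples
   with a binomial upper-tail probability below `alpha = 1e-3` for any
   partner, or with fewer than 10 lineages or 100 reads, are flagged and
   excluded downstream (but retained, flagged, in the table). When no
   library complexity is supplied, the observed distinct-barcode count
   is used - a lower bound on `B`, hence a conservative (over-)estimate
   of expected overlap.
6. **Normalization** (`normalize_rpm()`): surviving counts become reads
   per million per sample; ranks are assigned by descending RPM with
   lexicographic tie-breaking, so the ranking is a deterministic
   permutation.

## The read threshold

The sample-specific threshold must separate true clones from the
residual noise floor (unmerged error barcodes, collision satellites).
The classical knee construction - the point of maximum distance between
the log-log rank-count curve and its end-to-end chord - works when the
clone counts form a tight plateau, but fails when clone sizes themselves
span orders of magnitude: the convex clone ladder then dominates the
chord distance and the knee lands inside the clone region. The default
estimator therefore works on the density of log10 counts: the
lowest-count mode is the noise floor, and the threshold is placed where
that mode's density has decayed to 5% of its peak, accepted only if
another mode lies beyond it. A bandwidth floor of 0.3 decades merges
adjacent small integer counts into one noise mode. Degenerate inputs
(uniform counts, a single barcode, no second mode) fall back to a
configurable floor, default 2, which at least removes singletons. The
chord construction remains available as `method = "chord"`. Thresholds
are stored on the table, so re-applying the threshold stage is a no-op.

# Distribution statistics

`top_percentile_share()` (share of total output held by the largest
`ceiling(p% * N)` lineages; equipotent growth gives about `p%`, clonal
domination approaches 1), `size_range_orders()` (log10 max/min),
`cumulative_contribution_curve()` (Lorenz-style curve),
`divergence_summary()` (median, mean, mean/median ratio, top-1% share)
and `lineage_count_over_time()` (replicate mean with n-1 standard
error, undefined for a single replicate) quantify where a distribution
sits between the equipotent, dynamic and clonal-domination regimes. All
are invariant to barcode relabeling and proportional count rescaling.

`subsample_lineages()` draws random lineage subsets without replacement
at a given fraction and reports the median and 5th-95th percentile
envelope of any statistic over the draws - the in-silico version of
asking how small a subset of starting cells recapitulates whole-tissue
behaviour. Subsampling is lineage-wise by default (the question is about
subsets of starting cells); read-wise binomial thinning is available as
`mode = "reads"`. Note that envelope width need not shrink with the
fraction for *relative* statistics such as the subsample's share of
total (whose variance peaks at one half); it does for internal
statistics such as the mean.

# Optimal transport between lineage-size distributions

To compare two samples `x` (sizes `x_1..x_N`) and `y` (sizes `y_1..y_M`)
the package uses one-dimensional optimal transport. First
`harmonize_thresholds()` applies the higher of the two read thresholds
to both samples and renormalizes both to RPM. If `N != M`, each lineage
of `x` counts as `lcm(N, M) / N` lineage units and each of `y` as
`lcm(N, M) / M`, so both sides carry `lcm(N, M)` units
(`lcm_weights()`). The transport map minimizes the total absolute log2
fold change `sum |log2 x_(i) - log2 T(x_(i))|` over unit bijections; for
this convex one-dimensional cost the optimum is rank-wise pairing of the
two sorted unit sequences, which `rank_transport()` computes with a
virtual expansion (runs of units sharing a (source, target) lineage pair
are stored once, with a weight), so astronomically large lcm values cost
nothing. `brute_force_transport()` certifies optimality by exhaustive
permutation search on instances of up to 9 units.

One wrinkle deserves note: stated without absolute values, the signed
sum of log2 fold changes is identical for *every* bijection (it
telescopes to the difference of the two samples' summed logs), so a
minimization over maps is only meaningful under a convex cost such as
the absolute difference; the implementation uses exactly that, which is
also the cost under which rank-wise mapping is the textbook optimum.

Downstream, `fold_change_curve()` removes the top 1% largest source
lineages (few, highly variable; ceiling on the count, source side only -
a symmetric trim can be had by trimming `y` beforehand), aggregates fold
changes per source lineage, resamples each replicate's graph onto a
common 200-point log-spaced size grid, smooths with LOWESS (span 0.3 by
default; the span is a smoothing choice, not a model parameter) and
averages across replicates, reporting a per-grid-point lineage density
alongside (curve thickness in rank plots). `fold_change_density()` gives
the lineage-unit-weighted kernel density of fold changes: a uniformly
responding population shows one mode, heterogeneous replenishment shows
several. `transport_permutation_null()` provides the reference interval
for the mean fold change under random relabeling; replicate
self-comparisons should fall inside it.

**Normalization level for genotype subsets.** In chimeric designs the
two genotypes are sequenced in one pool, so their sizes share one
sample-level RPM normalization. Comparing genotype B to genotype A
*within* one organoid should therefore use the organoid-level RPM of
both subsets (their relative contributions carry the signal). Comparing
the same genotype *across* organoids (e.g. B under ablation vs B
untreated) should renormalize each subset, otherwise the other
genotype's perturbation leaks into the comparison through the shared
denominator. The transport functions operate on whatever sizes they are
given; the choice of normalization level is the caller's, and the
acceptance analyses use the two conventions as just described.

# Problem sizes and determinism

The test suite runs entirely on generated data: organoid simulations of
300-10,000 lineages over horizons of up to 40 days, SSA reference
samples of 3,000-10,000 replicates, and an end-to-end recovery
experiment of 2 x 500 clones spanning three orders of magnitude at 1e6
reads per sample with 1% substitution error and 0.1% cross-sample
bleed - sizes at which every check runs in seconds to a few minutes
while keeping Monte-Carlo intervals tight. All randomness flows from
explicit seeds; a seeded `run_pipeline()` run is byte-identical across
repetitions, and no stage mutates its input files.

# Known limitations

* The growth model has no death, no spatial structure and no
  cell-cycle correlations; `k` is a literal per-event multiplier, so
  intermediate-progenitor sublineages are not resolved.
* Ablation is modelled as growth arrest, not cell removal, and the
  generator contains no compensation mechanism; measured replenishment
  on synthetic chimeras is compositional.
* The clustering and threshold defaults (distance 2, ratio 10, noise-
  mode edge at 5%) are practical choices validated on the generator's
  error model, not universal constants; all are configurable.
* Index correction assumes a sample sheet whose index pairs are more
  than two mismatches apart; denser index sets need a smaller
  `max_index_distance` or unique dual indexes.
* `fit_rates_grid()` evaluates a finite grid; it selects among candidate
  regimes rather than performing continuous maximum-likelihood
  estimation.
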