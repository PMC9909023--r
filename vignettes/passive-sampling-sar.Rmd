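---
title: "Methods: passive sampling, the Coleman null, and what the simulator does and does not establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive sampling and the Coleman null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passar)
```

## The model

`passar` analyses one question: does the increase of microbial richness with
habitat area follow from *passive sampling* alone — larger habitats
intercepting more colonists from a regional pool — or is something else
required? Two pieces of machinery carry the analysis.

**The power-law SAR.** Richness S against superimposed area A is fitted as
an ordinary least-squares line in log–log space, log S = C + z·log A. The
slope z is invariant to the log base and the area unit; the intercept C is
not, so the pipeline converts areas to cm² before fitting (areas below 1 m²
would otherwise force C < 0, which makes the intercept awkward to read as a
log-richness at unit area). Slope inference uses the t distribution with
n − 2 degrees of freedom; for a simple regression the slope t-test and the
whole-model F-test coincide, so only the former is reported.

**The random-placement null.** Coleman's expectation
E(S_j) = Σ_i [1 − (1 − a_j/A_T)^{n_i}] gives the richness an island of area
a_j would hold if every individual landed independently and uniformly over
the region of area A_T. It is evaluated through `log1p`/`expm1` so that
abundances in the 10⁵–10⁷ range neither underflow nor lose the tiny absence
probabilities that drive the expectation's approach to S. The species
weights n_i default to total read counts over all source samples
(`n_mode = "reads"`); occupancy counts (`n_mode = "incidence"`) are
selectable. The abundance reading is the one that makes the published
per-area expectations attainable; the incidence reading would saturate the
rare-class expectation far faster than observed tables show. A_T defaults
to the summed area of all source samples, because a largest island equal to
A_T would force expectation = observation exactly and make the comparison
vacuous; it can be overridden wherever the sampled islands cover only part
of the region of interest.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `abundant_min` | 0.001 | fraction | abundant class: pooled relative abundance strictly above 0.1% |
| `rare_max` | 0.0001 | fraction | rare class: strictly below 0.01%; exact boundary hits fall to moderate (the thresholds are strict inequalities, so the between-interval is closed) |
| `n_models` | 8 | — | independent island-model series, one SAR fit each |
| `group_sizes` | 1..K−1 | samples | K−1 groups from K samples keeps the largest group a proper subset, so its area stays below A_T |
| `n_mode` | `"reads"` | — | species weights in the null (see above) |
| `A_T` | Σ sample areas | m² | region area of the null |
| ACE rare cutoff | 10 | counts | standard Chao–Lee choice |

Abundance classes are computed on the *pooled* table (the grand total over
all samples), not per sample: a taxon has one class, and the classes
partition the taxon set — which the class-stratified expectations require
(they are additive over a partition).

## The island-model combination procedure

Each island model is a series of groups of 1, 2, …, K−1 samples drawn
uniformly at random and superimposed: counts add, areas add. Two readings of
the sampling scheme were open, and both are implemented:

* *independent draws per size* (default): the draw for size k is
  independent of the draw for size k+1. The alternative, `nested = TRUE`,
  grows one permutation by accretion; it guarantees monotone richness within
  a model but correlates the points of one fit.
* *distinct members within a group* (default): drawing the same sample twice
  into one group would double its area without adding any observable
  individuals and would break the exact area ladder (0.36, 0.72, …, 2.52 m²
  for eight 0.36 m² samples), so `within_replacement = TRUE` exists only as
  the literal alternative reading.

Repetition of the same combination *across* groups and models is allowed —
with 8 samples there are only 8 singletons, so it is unavoidable.

## What the synthetic generator emulates

The generator states a world in which passive sampling is true by
construction, scaled to a desk-size version of an amplicon survey:

* a regional pool of 5,000 species and 200,000 individuals (the order of a
  high-throughput run's retained reads), log-series distributed. Fisher's
  alpha is derived from (S, N) by solving S = α·log(1 + N/α) — with S and N
  both fixed, α is not free — giving a rare-dominated pool (~65% of taxa
  below the 0.01% line under the defaults, matching the rare-species
  dominance that motivates the analysis);
* eight islands of 0.36 m², by default jointly covering the region
  (A_T = 2.88 m², no missed individuals), so realized totals equal pool
  abundances and the Coleman null holds exactly;
* placement is one multinomial draw per species over the k islands plus a
  "missed" residual — distributionally identical to per-individual dart
  throwing, and O(S) instead of O(N);
* integerization of SAD draws floors the scaled abundances, clamps at one
  individual per species, and assigns the remainder to the largest
  fractional parts, so the total is exact and — when the scale factor is
  near 1, which the derived α guarantees — singletons stay singletons;
* per-species occupancy multipliers in (0, 1] depress a species' landing
  probability. With multipliers below 1 on rare species *and* a region
  larger than the summed islands, the individuals that do land are spread
  area-proportionally over the islands only, while a homogeneity-assuming
  expectation computed from realized totals over the full region
  underestimates their occupancy — most strongly for species with one or
  two surviving individuals. This reproduces the *direction* of the
  empirical finding (the null underestimates rare richness, worst in small
  islands), which is all the synthetic world can honestly claim.

What a green test does **not** establish: real surveys have read counts that
are not individual counts, compositional sequencing depth effects, spatial
aggregation, and taxa whose detection probability varies for reasons other
than abundance. The simulator has none of these; magnitudes measured on it
(mean slopes, deficit sizes) do not transfer to real data.

## Numerical and design choices

* **Seeds.** One user seed is split (`split_seed`) into named sub-streams
  for pool, placement and island draws, so stages can be varied
  independently; every derived seed stays below 2³¹.
* **Paired test.** Differences are expected − observed; t = mean/(sd/√n),
  df = n − 1, two-sided p. A zero SD with non-zero mean reports an infinite
  t with p = 0 and a warning; zero SD and zero mean reports t = 0, p = 1.
* **Beta decomposition.** Podani family: Repl = 2·min(b,c)/den,
  RichDiff = |b−c|/den with den = a+b+c (Jaccard) or 2a+b+c (Sørensen);
  counts are binarized. The Baselga family is out of scope. The replacement
  *contribution* aggregates Σ Repl / Σ D over pairs.
* **UniFrac.** Unweighted: unique over covered branch length, presence
  based. Weighted defaults to the normalized form (bounded in [0, 1]);
  the raw form is available. Branch masses accumulate in postorder;
  multifurcating input trees are accepted. Note that an edge whose entire
  subtree is present in only one community counts as unique — for fully
  disjoint communities the unweighted distance is 1 regardless of topology.
* **Rank ties** break lexicographically by taxon ID; threshold-boundary
  taxa go to the moderate class — both pinned by tests for determinism.
* **ACE caveat.** Published ACE values in this experimental system (13–17
  against richness of 766–1,546) cannot come from the standard Chao–Lee
  estimator, which is bounded below by richness; `passar` implements the
  standard estimator (validated against vegan) and treats such published
  values as non-reproducible. An all-singleton sample has zero coverage and
  yields an infinite ACE with a warning.
* **Config files** for the CLI are JSON (the one parser guaranteed in the
  deployment environment); explicit flags override file values.

## Known limitations

* No rarefaction or coverage standardization; unequal sequencing depth is
  the user's problem before the table enters the pipeline.
* No spatially explicit placement, distance decay, or within-island
  aggregation — the design this package serves explicitly excludes them.
* The paired t-test treats per-area differences as independent; in a single
  realized table the island groups share samples, so the test is better
  read as descriptive than strictly inferential when applied to one table
  (the published analysis does the same).
* Published mean slopes and replacement contributions are properties of the
  real, deposited data set; the package reproduces the machinery and the
  qualitative phenomena, not those numbers.
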