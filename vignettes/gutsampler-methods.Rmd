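---
title: "Sampling-design diagnostics for broiler gut microbiome surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling-design diagnostics for broiler gut microbiome surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsampler)
```

## What this package is for

Three practical questions recur in 16S rRNA amplicon studies of broiler
chickens:

1. **How many birds from one flock are enough?** Birds raised together share
   much of their microbiota ("within-flock clonality"), so each additional
   bird adds less new information than the last.
2. **Are the two cecal pouches of one bird interchangeable replicates?**
3. **Is a non-destructive cloacal swab a usable proxy for internal
   alimentary-tract (AT) communities?**

`gutsampler` answers these from an ASV (amplicon sequence variant) count
table, sample metadata, a taxonomy and a rooted phylogenetic tree. The raw
read processing that produces those inputs (denoising, taxonomy assignment,
tree building) is out of scope: the pipeline starts at the count table.

Because the deposited sequencing data of any particular flock is not needed
to test the *machinery*, the package ships a synthetic flock generator with
known ground truth; every analysis stage is validated against that ground
truth and against independent brute-force oracles.

## The pipeline

Stages run in a fixed dependency order (`run_pipeline()`):

1. **Organelle / kingdom filtering** — features whose lineage mentions
   chloroplasts or mitochondria at any rank, or that lack a kingdom
   assignment, are removed (`filter_nonbacterial()`).
2. **Contaminant scoring** (`decontam_combo()`) — combines a *frequency*
   test (is a feature's relative abundance proportional to 1/DNA
   concentration, the physical signature of a reagent contaminant?) with a
   *prevalence* test (is it enriched in sequenced negative controls?).
   The frequency evidence compares the residual sum of squares of the
   contaminant model (slope fixed at −1 in log10 frequency vs log10
   concentration) against the constant model; significance comes from
   permuting concentration labels (≥1000 permutations) rather than from the
   reference tool's analytic F-type statistic — both models have one free
   parameter, and the permutation null avoids reproducing undocumented
   internals. Prevalence uses a one-sided Fisher exact test, appropriate for
   the very small negative-control counts typical of these designs (two
   controls here). The two p-values combine by Fisher's method (χ², 4 df);
   features with combined score below the threshold (default 0.1, the
   reference tool's default) are flagged.
3. **Named-taxon removal** (`remove_named_taxa()`) — exact rank-qualified
   label matches; by default the two *Lactobacillus* species
   (*L. acidipiscis*, *L. helveticus*) that negative controls flag in this
   study system.
4. **Cumulative sum scaling** (`css_normalize()`) — per sample, counts are
   divided by the cumulative count up to the `l`-th quantile of the
   sample's positive counts (nearest-rank-lower convention) and rescaled.
   Defaults: `l = 0.5`, scale 1000. The adaptive quantile selection of the
   original CSS method is not reproduced; `l` is a fixed, documented
   parameter.
5. **Diversity** — Shannon diversity (natural log by default; the base is a
   parameter), Bray-Curtis distances (via vegan), weighted UniFrac
   (own implementation, raw variant by default, normalized selectable),
   PCoA (classical metric scaling; negative eigenvalues are reported, never
   silently dropped) and ANOSIM.
6. **Sufficiency** (`accumulate()`, `sample_size_at_threshold()`) — per AT
   site, the mean over random bird orderings of new / cumulative / unique
   ASV counts as birds are added, in the tradition of pan-genome accumulation
   curves. The sufficient flock size at threshold `t` is the smallest `n`
   such that bird `n + 1` adds fewer than `t` new ASVs *relative to the
   running union* (the final-union denominator is available as a variant).
   Both cecal pouches count as separate sampling units at the cecum site.
7. **Cecal pairs** (`pair_report()`) — per bird: the shared-abundance
   fraction (mean over the two pouches of the read mass carried by features
   present in both; pooled and min variants available), the shared-ASV
   fraction (Jaccard index of the presence sets; per-pouch mean variant
   available), and whether each pouch's nearest neighbour among cecum
   samples is its pair mate.
8. **Site contrasts** — distance from every site to the same bird's cloacal
   swab (pouches averaged within bird first), family-level
   Pearson/Spearman correlation of a chosen family (default
   Enterobacteriaceae) between each site and the swab, per-bird
   distance-decay regression, and the cecal enrichment contrast.

### Statistical conventions

* **ANOSIM** (`anosim()`): `R = (mean between-group rank − mean within-group
  rank) / (M/2)` over the `M = n(n−1)/2` ranked pairwise distances
  (mid-ranks for ties). The permutation p-value is
  `(1 + #{R* ≥ R}) / (n_perm + 1)`; when all distinct label arrangements fit
  the permutation budget the null is enumerated exactly, so small designs
  get exact p-values. Default 999 permutations, consistent with a p-value
  floor of 0.001.
* **Distance decay** (`distance_decay()`): within one bird, community
  similarity (1 − distance) for every sample pair is regressed on the
  difference of anatomical ordinals (crop = 1 … cloacal swab = 9; the two
  cecal pouches share ordinal 7, so physical distance is ordinal, not
  metric). Significance is a one-sided Mantel-style permutation test that
  permutes site ordinals within the bird, again with exact enumeration when
  feasible. The anatomical flow order is used (proventriculus before
  gizzard); an `ordinal` metadata column can override it.
* **Cecal enrichment** (`cecal_enrichment()`): per feature, the log2 fold
  change of cecal over non-cecal mean normalized counts (pseudocount 1) with
  a two-sided permutation test on the difference of group means of
  `log2(count + 1)`; labels are permuted at the whole-sample level so every
  feature shares one permutation null, and q-values come from
  Benjamini-Hochberg. This is a deliberate permutation-based design rather
  than a negative-binomial Wald contrast: the package's purpose is the
  sampling-methodology analysis, not an NB-GLM reimplementation, and the
  substitution is surfaced in the output as `method = "permutation-LFC"`.
  The default significance level is 0.01 for this contrast and 0.05
  elsewhere.

## The synthetic flock generator

`flock_model()` / `generate_flock()` emulate a single market-age broiler
flock: **9 birds**, sampled at **10 AT locations** (crop, proventriculus,
gizzard, duodenum, jejunum, ileum, both cecal pouches, colon, cloacal swab),
a **target depth of 30,000 reads** per true sample, and **two negative
controls**. The generative model:

* **Site gradient.** Each site's base composition lives in log space. Moving
  one ordinal step aborad adds a per-feature *directional trend*
  (`gradient_trend_sd`, default 0.35) plus white noise (`gradient_step_sd`,
  default 0.30). The trend accumulates linearly along the tract, so
  between-site divergence grows with anatomical separation; a pure random
  walk was rejected because in composition space Bray-Curtis saturates and
  the orad half of the tract becomes indistinguishable from the swab's
  vantage point, which no longer resembles the monotone aborad similarity
  gradient this design is meant to emulate.
* **Clonality.** Every bird perturbs the site composition by a lognormal
  per-feature effect shared across its sites (`bird_effect_sd`, default
  1.0; 0 gives a clonal flock) and carries `rare_pool_per_bird` (default 2)
  private low-abundance ASVs. Together with a heavy-tailed baseline
  abundance distribution (`base_abundance_sd`, default 2.0) this yields
  collector-curve behaviour in which the second or third bird still adds
  more than 10% new ASVs while the eighth adds on the order of 1% — the
  sampling regime the package is designed to diagnose. These defaults were
  fixed once, by simulation at design time, and are not tuned per analysis.
* **Cecal pouch pairs.** The two pouches are independent
  Dirichlet-multinomial draws from a shared bird-cecum composition. The
  Dirichlet concentration is calibrated by bisection so the *expected*
  shared-abundance fraction equals `pair_overlap` (default 0.95), using the
  closed form `E = Σ p_i (1 − P0_i)` where `P0_i` is the beta-binomial zero
  probability — no Monte-Carlo calibration is needed. Targets above the
  detection-limited maximum (the multinomial limit) fail before any count is
  drawn. `pair_overlap = 1` is the zero-pouch-noise degenerate case:
  both pouches receive the same draw.
* **Contaminants.** `n_contaminants` (default 8) features whose expected
  frequency in true samples is `contaminant_strength / dna_conc` (default
  strength 0.3, about 2% of reads at typical concentrations) with lognormal
  noise (σ = 0.3); they dominate the negative controls, whose DNA
  concentrations sit in the lowest decile. This mirrors exactly the
  inverse-concentration signature the frequency test assumes, so sensitivity
  tests are well-posed.
* **Planted enrichment.** `n_planted_enriched` (default 10) features hold an
  explicit bird-independent relative-abundance slice, flat across sites
  except for an `enrichment_fold` (default 8) multiplier in the ceca. The
  slice lives outside the softmax because a flat log-abundance row would
  still drift in *relative* abundance through the changing softmax
  denominator, confounding the planted fold with the gradient; and it is
  bird-independent because the fold itself is the ground truth the recovery
  tests measure.
* **Bookkeeping.** DNA concentrations are lognormal; depths are lognormal
  around the target with 5%-accurate means; taxonomy labels come from a
  small fixed lineage pool (including Enterobacteriaceae and Lactobacillus,
  so family-level operations and named-taxon removal are exercised); the
  tree is random bifurcating with exponential branch lengths; every
  generative parameter is recorded in a JSON manifest from which
  `regenerate_from_manifest()` rebuilds the flock bit-identically.

### What the generator does and does not emulate

It reproduces the *structure* the pipeline must detect: a monotone aborad
gradient, within-flock clonality, correlated pouch pairs, contamination with
a physical signature, and a known enrichment contrast. It does **not**
emulate real taxon identities beyond the label pool, chimeras, PCR error,
compositional correlations between specific taxa, or flock-to-flock
variation. Passing tests therefore demonstrate that the statistics recover
known structure at realistic sizes and noise levels — not that any specific
biological flock will show these effect sizes.

## Numerical choices and degenerate inputs

* Quantiles in CSS use the nearest-rank-lower convention; `s_j = 0` is an
  error naming the sample.
* Permutation p-values use the `(1 + #exceedances)/(n + 1)` convention with
  a 10⁻¹² tie guard; exact enumeration replaces sampling whenever the
  number of distinct relabelings fits the budget.
* Nearest-neighbour ties break to the lexicographically smallest sample id,
  with a warning.
* All-zero samples are dropped (with a warning) by relative-abundance
  conversion, and are an error where a statistic is undefined
  (Bray-Curtis on a pair of empty samples, Shannon on an empty vector).
* Features absent everywhere are skipped by the enrichment contrast with a
  warning; zero-variance vectors yield `r = NA` in family correlations
  rather than an error.
* Samples present in the count table but missing from metadata are a hard
  error: silent dropping hides labelling bugs.

## Problem sizes used by the test suite

Unit tests run on hand-sized fixtures. Oracle checks use exhaustive
enumeration for flocks of up to 5 birds, 100 random 8-leaf trees for
weighted UniFrac, and the 3-partition enumeration for 4-sample ANOSIM. Null
calibrations use 1000 simulated datasets for ANOSIM and distance decay and
500 for the enrichment test, each with 99 permutations (the 1/100 p-value
granularity makes the 5% rejection rule exact). Ground-truth recovery uses
20 default flocks for pair overlap and single pinned-seed default flocks for
enrichment recovery and the structural findings. These sizes keep the whole
suite fast while leaving the Monte-Carlo error well inside the asserted
tolerance bands.

## Known limitations

* The decontam-style score is not numerically identical to the reference
  tool (permutation frequency test, Fisher exact prevalence test); it is
  designed to agree in its decisions on clear cases, and its operating
  characteristics are validated against planted ground truth instead.
* CSS uses a fixed quantile; samples with pathological count distributions
  may warrant the original method's adaptive quantile.
* Physical distance in the decay analysis is ordinal; centimetre distances
  along the tract are not modelled.
* ANOSIM assumes exchangeability under the null; with the two pouches of a
  bird in the same group the within-bird correlation makes the by-site test
  slightly anticonservative. The paired structure is respected in the
  analyses where it matters (pouches averaged within bird before swab-proxy
  and correlation analyses, to avoid pseudo-replication; a per-pouch mode
  is available).
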