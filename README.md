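# gutsampler

Sampling-design diagnostics for poultry gut microbiome surveys, built on ASV
(amplicon sequence variant) count tables from 16S rRNA sequencing.

Broiler studies face three recurring design questions: how many birds from
one flock must be sampled before additional birds stop adding new community
members; whether the two cecal pouches of a bird can be treated as
replicates; and whether a non-destructive cloacal swab approximates the
communities of internal alimentary-tract (AT) locations. `gutsampler`
implements the full analysis chain for answering them from a count table,
sample metadata, taxonomy and a rooted phylogeny — plus a synthetic flock
generator with known ground truth so the whole pipeline is testable without
deposited sequencing data.

## Methods at its core

* **Bird-accumulation curves.** For a random ordering of birds at one site,
  `new(k) = |ASV(b_k) \ ∪_{j<k} ASV(b_j)|`, `cumulative(k) = |∪_{j≤k}
  ASV(b_j)|`, and `unique(k)` counts ASVs seen in exactly one of the first
  `k` birds; curves average over orderings (exact enumeration on small
  flocks). The sufficient flock size at threshold `t` is the smallest `n`
  such that `new(n+1)/cumulative(n) < t`, evaluated at `t = 0.10` and
  `t = 0.01`.
* **Cecal pair similarity.** Shared-abundance fraction (mean over pouches of
  the read mass on features present in both) and shared-ASV fraction
  (Jaccard index `|A∩B|/|A∪B|`), plus nearest-neighbour concordance in a
  community distance matrix.
* **Swab proxy assessment.** Per-site mean distance to the same bird's
  cloacal swab (Bray-Curtis `Σ|x−y|/Σ(x+y)` or weighted UniFrac
  `Σ_b l_b |p_A(b) − p_B(b)|`), family-level Pearson correlations between
  sites and swabs, and per-bird distance-decay regressions of community
  similarity on anatomical separation with Mantel-style permutation tests.
* **Supporting machinery.** Negative-control contaminant scoring combining a
  permutation frequency test (relative abundance ∝ 1/DNA concentration)
  with a Fisher exact prevalence test via Fisher's method; cumulative sum
  scaling normalization; Shannon diversity; PCoA; ANOSIM with exact
  enumeration on small designs; a permutation log-fold-change contrast of
  cecal vs non-cecal samples with Benjamini-Hochberg correction.

See `vignettes/gutsampler-methods.Rmd` for the full model descriptions,
parameter defaults and design rationale.

## Worked example

```r
library(gutsampler)

fl <- generate_flock(flock_model(seed = 1))
fl
#> Synthetic flock: 9 birds, 92 samples, 622 observed features (seed 1)
#>   planted: 8 contaminants, 10 cecum-enriched (fold 8.0)

meta <- fl$metadata[!fl$metadata$is_negative, ]
tab  <- asv_table(unclass(fl$table)[, meta$sample_id, drop = FALSE])
norm <- css_normalize(tab)$table
dm   <- bray_curtis(norm)

anosim(dm, meta$site[match(rownames(dm), meta$sample_id)], seed = 2)
#> ANOSIM: R = 0.6288, p = 0.001 (sampled, 999 permutations)

pair_report(norm, meta, dm)
#> Cecal pair similarity over 9 birds:
#>   shared abundance: mean 0.9592 (range 0.9401-0.9759)
#>   shared ASVs (Jaccard): mean 0.5536 (range 0.4906-0.6098)
#>   nearest neighbour is pair mate: 83% of birds

flock_sufficiency(tab, meta, seed = 3)$summary
#>   threshold n_sites_reached     mean min max                                 unreached_sites
#> 1      0.10               9 2.444444   2   4
#> 2      0.01               3 7.000000   6   8 duodenum,jejunum,ileum,cecum,colon,cloacal_swab

distance_decay(dm, meta, "B1", seed = 4)
#> Distance decay [B1]: slope = -0.0757, r = -0.7860, p = 0.001 (45 pairs)
```

Read in order: AT locations host clearly distinct communities (ANOSIM
R = 0.63 at the permutation floor); the two cecal pouches share ~96% of
their read mass but only ~55% of their distinct ASVs, so pouches are good
whole-community replicates and poor rare-lineage replicates; after 2–4 birds
(mean 2.4) a new bird adds under 10% new ASVs, while the 1% threshold needs
6–8 birds where it is reached at all; and within a bird, community
similarity falls off with anatomical distance (negative slope, permutation
p at the floor), which is why the swab resembles the colon far more than the
crop.

`run_pipeline(run_config(...))` chains every stage (filtering, contaminant
removal, CSS, diversity, sufficiency, pairs, contrasts) and writes TSV/JSON
outputs plus a run manifest that reproduces the run byte-identically from
its seed.

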