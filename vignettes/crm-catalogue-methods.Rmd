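---
title: "Methods: building and annotating a TF binding-site catalogue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and annotating a TF binding-site catalogue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crmcat)
```

# Scope and model

crmcat integrates many transcription-factor (TF) ChIP-seq peak sets into a
single genome-wide catalogue and annotates it.  The pipeline has six
analytical stages, each exposed as ordinary functions over plain
data.frames in 0-based half-open (BED) coordinates:

1. **Quality gate** (`qc_report()`): strand cross-correlation metrics
   (NSC, RSC), FRiP and a 0–5 score decide which datasets enter the
   catalogue.
2. **Non-redundant sites** (`merge_tf_peaks()`): per TF, peaks from all
   retained datasets are merged by ≥ 1 bp overlap; the merged site's summit
   is the rounded mean of the member summits.
3. **CRM catalogue** (`build_crms()`): sites of all TFs are merged again;
   regions bound by ≥ 2 distinct TFs are cis-regulatory modules (CRMs),
   regions bound by one TF are singletons.
4. **Localization** (`assign_category()`, `tss_profile()`,
   `conservation_profile()`, `resource_recovery()`): genomic-category
   assignment, TSS-proximity profiles stratified by binding complexity,
   summit-centred conservation aggregation, and recovery of external
   element sets.
5. **Co-localization network** (`pairwise_matrix()`,
   `specificity_outliers()`, `build_and_partition_network()`): a
   placement-null overlap test per site pair of TFs, an asymmetric
   percentage matrix, box-plot outlier fences for specificity, and a
   weighted Louvain partition.
6. **Enrichment and saturation** (`tf_enrichment()`,
   `saturation_curve()`): hypergeometric TF enrichment in user region sets
   (e.g. variant enhancer loci) and CRM counts under random TF
   subsampling.

Every stage can be exercised against the synthetic-data generator
(`sim_config()` and the `simulate_*`/`plant_*` functions), which plants a
known ground truth and is fully deterministic given its seed.

# Interval semantics

All merging uses *at least 1 bp of overlap* under half-open semantics:
book-ended features (`end == next start`) are **not** merged.  Merged
regions are the connected components of the overlap relation, so two
same-TF sites can be fused into one CRM by a bridging site of another TF.
Summit averages are rounded half-up; a mean of member summits always lies
inside the merged interval, the clamp in the code is purely defensive.

# Quality metrics

The cross-correlation profile correlates, for each shift *d*, the per-base
plus-strand 5′-read counts with the minus-strand counts shifted left by
*d*, over the overlapping part of each chromosome, combining chromosomes
by length-weighted averaging.  Then:

* `NSC = cc(fragment peak) / cc(minimum)` — the background level is the
  profile minimum over the shift range;
* `RSC = (cc(fragment) − cc(min)) / (cc(read length) − cc(min))` — the
  read-length ("phantom") peak is excluded from the fragment-peak argmax
  within ± 10 bp (configurable).

Thresholds follow the ENCODE-style two-per-metric scheme: NSC 1.05 and
1.10, RSC 0.8 and 1.0, each counted when *attained* (`>=`; boundary
datasets at exactly a threshold are kept, which is the generous reading of
"exceeds" and is configurable).  FRiP ≥ 1 % adds one point.  Datasets with
score ≤ 1 or fewer than 100 peaks are discarded.  FRiP uses all provided
5′ positions; no deduplication is attempted.

Two numerical caveats, both visible in the test suite:

* On sparse toy genomes the profile minimum can be negative, which makes
  NSC negative for both signal and noise data; the gate is then carried by
  RSC and FRiP.  This is a small-genome artefact, not a property of
  genome-scale data.
* Uniform background reads contain **no** phantom peak (the simulator has
  no mappability structure), so RSC on pure noise is a ratio of two noise
  terms and is unstable.  A failed experiment is nevertheless discarded
  because it also yields very few peaks, which trips the 100-peak floor —
  the same reason the floor exists in the original scoring scheme.

# The placement null

For a query interval of length *q* and a reference site set, the p-value
is the fraction of all placements of a length-*q* interval — wholly inside
one segment of a domain — whose distance to the nearest reference is at
most the observed distance.  Distance is the closest-base distance: 0 iff
the intervals share a base, 1 for book-ended intervals, gap + 1 in
general.  The observed placement always counts, so p ∈ (0, 1], p is exact
(a counting argument, no approximation) and increases with distance.  The
domain defaults to the union of the analysed sites padded by 10 kb
(`colocalization_domain()`): a whole-genome null would make every overlap
look significant once site density is low, while the padded union asks
"given that we are in regulatory neighbourhoods, is this proximity
surprising?".  The margin is exposed because this choice is a genuine
degree of freedom.

A site pair of TFs (q as query, r as reference) contributes the percentage
of q's sites with p ≤ 0.05 to the asymmetric matrix.  Per query row,
partners above `Q3 + 1.5·IQR` are *moderately* and above `Q3 + 3·IQR`
*strongly* specific (strict `>`, type-7 quartiles — the convention must be
pinned for the fences to be reproducible).  The network keeps TFs with at
least one call, collapses directions (stronger level wins), weights edges
2/1 for strong/moderate, and partitions with weighted Louvain at
resolution 0.51 after a seeded node relabelling, mirroring the
"randomize" behaviour of interactive tools while staying reproducible.

**Known limitation.**  Box-plot fences can only flag a minority of a row.
If one TF's true partners exceed ~25 % of its row (e.g. co-binding blocks
of 10 TFs in a 30-TF panel), Q3 falls *inside* the high group and the
moderate fence exceeds 100 %, so no call can be made for any TF and no
network exists.  The regime the rule is designed for — and where the
pipeline provably recovers planted structure (adjusted Rand index ≥ 0.8 in
the tests) — is specific partner groups small relative to the panel, e.g.
blocks of 5 in 30 TFs, matching the situation of hundreds of TFs with
small subnetworks for which the rule was conceived.

# Enrichment

The enrichment universe is the catalogue itself: *N* regions (CRMs and
singletons), *K* of them containing the TF, *n* hit by the query set, *k*
both.  `P(X ≥ k)` is the upper-tail hypergeometric probability;
Benjamini–Hochberg across TFs is the default correction (configurable:
none/bonferroni/BH).  "Hit" defaults to ≥ 1 bp overlap (`bp1`); a
`placement` mode re-uses the placement null with p ≤ α instead, for
analyses that want distance-aware overlap calls.  Region-level counting
was chosen over peak-level counting because it makes "random expectations"
a clean sampling-without-replacement null; this is stated prominently
because other reasonable universes (e.g. all peaks) would shift the
numbers.  Ranking ties are broken by descending fold then TF name so
reports are deterministic.

# Saturation

For each panel size the curve draws TF subsets uniformly *without
replacement* (a "selection" of TFs), rebuilds the catalogue from the
chosen TFs' sites and counts multi-TF regions only (singletons excluded;
`include_singletons = TRUE` reports totals).  Each (size, replicate) pair
has its own seeded substream so adding sizes or replicates never
reshuffles existing draws.  Medians are smoothed with `lowess`
(tricube-weighted local linear regression, span 0.3, 2 robustness
iterations — the smoothing parameters are cosmetic and documented rather
than load-bearing).

# The synthetic generator

`sim_config()` defaults describe a deliberately small but self-consistent
study: a 10 Mb two-chromosome genome, 120 genes, 30 TFs in 6 co-binding
blocks of 5, 800 planted modules plus 25 % singletons, 3 datasets per TF
(80 % sensitivity, 10 bp summit jitter, 50 bp width noise, 10 false peaks
each), 200 bp fragments read as 36 bp tags with 10 % uniform background.
The module count is set so that a typical dataset exceeds the 100-peak
retention floor — a default study should pass its own quality gate.  Site
placement enforces a 1 kb minimum gap so planted modules stay distinct
under jitter; `promoter_bias` (default 0.25) sends that fraction of sites
TSS-proximal (Normal(0, 500 bp) around a random TSS), and can be supplied
as a function of module size to plant complexity-dependent promoter
enrichment.  A module picks one block, includes each of its TFs with
probability 0.8 and every other TF with probability 0.02, redrawing until
≥ 2 TFs — so TF sets are conditional-on-size Bernoulli draws.
`singleton_rate` is the *fraction of all truth sites* that are
single-TF sites.

Randomness is organised as one master seed with deterministic named
substreams (genome / sites / one per dataset / reads / queries), so
changing the number of datasets never moves a gene or module.

What the generator does **not** emulate — and what green tests therefore
do not certify on real data: no sequence or motif content, no mappability
or duplicate-read structure (hence no phantom peak), no chromatin-state
covariates, no inter-site spacing correlations, and peak callers'
systematic width biases.  The generator validates the *statistical
machinery* (merging, counting, nulls, recovery), not biological
conclusions.

# Problem sizes

The shipped tests run the oracle comparisons at up to 500 peaks × 200
random instances, exhaustive placement-null enumeration on domains up to
100 kb, the full hypergeometric sweep to N = 60, network recovery on
30 TFs × 300 modules over 10 seeds, and 50-replicate saturation curves —
sizes chosen so the whole suite completes in minutes on one CPU while
keeping every Monte-Carlo margin wide relative to its assertion.

# Degenerate inputs

Empty peak files parse to empty frames; empty catalogues give all-zero
distributions; a query set disjoint from the catalogue yields k = 0 and
p = 1 for every TF (with a warning); an all-background read set fails the
gate; a TF row with fewer than 4 finite percentages yields no specificity
calls (warning); sites that fit in no domain segment are skipped with a
warning and shrink the percentage denominator.  Chromosome names are
compared as exact text — real-data users must normalise "chr" prefixes
themselves.
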