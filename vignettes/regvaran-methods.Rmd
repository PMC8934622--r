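---
title: "Models and design choices in regvaran"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in regvaran}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regvaran` builds a typed catalog of regulatory regions, scores each
region's intolerance to sequence variation, and uses both — together with
functional-element tracks, impact-prediction scores, population allele
frequencies and HPO-driven gene ranks — to tier non-coding variants from a
VCF. This vignette explains the underlying models, the tunable parameters,
the synthetic-data generators used for validation, and the numerical
decisions taken where the design was genuinely open.

## Coordinates and containers

All in-memory objects are standard Bioconductor containers: regions and
functional elements are `GRanges` (1-based, closed intervals, the
IRanges convention), the database is an S4 `RegulatoryDB` bundling regions,
link tables, gene models and a `GenomeModel`. Every text interface uses the
convention native to its format: BED files (both the extended region BED and
feature BEDs) are 0-based half-open, region source tables declare their
dialect (`coords = "bed"` or `"one_based"`) and are converted on ingest,
and VCF positions are 1-based as usual. Keeping the interior uniformly in
the IRanges convention and converting only at the boundary confines
off-by-one risk to two well-tested functions (`normalizeSource`,
`exportBed`/`importBed`).

## Building the region catalog

**Normalization.** Each source table must provide chromosome, start, end
and a type mappable onto the five-type vocabulary (bivalent, enhancer,
insulator, promoter, silencer). Records with non-positive spans, unmappable
types or unknown chromosomes are dropped and counted per reason — the
rejection report travels with the returned object. A source missing a
mandatory column is rejected outright.

**Redundancy collapsing.** Two same-type regions are redundant when their
reciprocal overlap, min(overlap/len_A, overlap/len_B), reaches a threshold.
The default of 0.8 is deliberately conservative: a high reciprocal
requirement cannot chain distant elements into mega-regions through a
string of marginal overlaps. Merging acts on connected components of the
pairwise relation and is iterated to a fixed point, which makes
`collapseRegions` idempotent — a property the test suite asserts on random
catalogs. Merged regions take the union span and the set-union of sources,
methods, tissues and directly-annotated genes. Regions of *different* types
are never merged, even at identical coordinates: types are distinct
evidence strata, and a promoter call and an enhancer call at the same locus
are two claims, not one.

**Gene assignment.** The closest gene minimizes the gap distance between
region span and gene span (0 when they overlap or touch); the closest TSS
minimizes |region midpoint − TSS|, with the TSS taken strand-aware (gene
start on `+`, gene end on `-`). Both tie-break toward the
lexicographically smaller gene id so that results are reproducible across
platforms. Gene links carry one of four evidence classes — `direct`
(annotated in a source), `closest_gene`, `closest_tss`, `eqtl` — the last
supplied as a pre-computed link table, since eQTL inference itself is out
of scope for this package. Phenotype links (`gwas`/`hpo`/`curated`) are
likewise consumed pre-computed.

**Storage.** The database serializes to a single-file SQLite store (tables
`regions`, `gene_links`, `phenotype_links`, `genes`, `genome`, `excluded`)
and to an extended BED (chrom, start, end, id, constraint, strand, type,
sources, genes). Both round-trip exactly; the BED round-trip is
byte-identical, which the tests check.

## The variation-constraint model

For each region we model the observed variant count by ordinary least
squares on five covariates: region length (bp), GC fraction, and the
fractions of the region overlapped by segmental duplications,
low-complexity regions and exonic sequence (all in [0, 1], computed on
merged feature intervals). The linear model is used as stated — counts are
not transformed, and length enters raw — both choices switchable if a user
prefers a log-length or studentized-residual variant (`studentized = TRUE`
ranks internally studentized residuals instead).

The *constraint value* maps the residual e_i = expected_i − observed_i to
[0, 1] through the mid-rank empirical CDF:

c_i = (#{e_j < e_i} + 0.5 · #{e_j = e_i}) / n.

This choice is bounded, distribution-free, invariant to monotone
transformations of the residual scale, gives identical values to tied
residuals, and composes naturally with percentile-based flagging. A region
is flagged *constrained* when its constraint value is strictly greater
than the 99th percentile of the constraint distribution, where the
percentile is the inverse-ECDF (type-1) empirical quantile: with distinct
residuals this flags exactly 1% of regions up to integer rounding (100 of
10 000), and never more than ⌈n/100⌉. Interpolating quantile definitions
undercount by one at round sample sizes, which is why the type-1 quantile
is used.

Two structural properties follow from the construction and are asserted as
tests: adding a constant to all observed counts leaves the ranking
unchanged (the intercept absorbs it), and the values are
permutation-equivariant. Constant covariate columns (e.g. no region
overlaps any segmental duplication in a small genome) carry no information
and are dropped from the design with a zero coefficient; genuinely
collinear columns abort the fit with a message naming the offending pair,
since silently dropping one of two informative covariates would change the
expectation model.

Variant counting is site-based: one count per VCF position inside the
region, multi-allelic records counting once. FILTER status is ignored by
default.

## Evaluating a region set

**Matched controls.** For each chromosome the sampler re-places the *exact
size multiset* of the source regions uniformly over the chromosome minus
excluded intervals (mock centromeres/telomeres). Re-using the sizes rather
than re-drawing them makes the control size distribution match the source
by construction (Kolmogorov–Smirnov distance 0), so region-level
enrichment comparisons are not confounded by size. Sampling is
deterministic under a seed, and the caller's RNG stream is left untouched.

**Enrichment.** Fisher's exact test on the 2×2 table of regions versus
controls hitting/not hitting a feature, where "hit" means overlapping at
least one feature base. The counting unit is the region: with size-matched
controls, region-level counting is the natural unconfounded design. The
reported odds ratio is the sample OR (ad)/(bc); the 0.5 Haldane correction
is applied — and flagged — only when a zero cell occurs. The p-value is
the exact two-sided hypergeometric probability.

**Conservation and score distributions.** Per-region summaries over
per-position tracks: the fraction of *covered* bases with value strictly
above each threshold (defaults 1, 1.5, 2, the conventional conservation
cutoffs), plus median and maximum. Score tracks are genuinely partial
(some published scores cover a small fraction of the genome), so
uncovered bases are excluded from denominators rather than imputed as 0;
a region with no covered base gets an undefined summary and is counted, not
silently dropped. Region-versus-control comparisons use the Mann–Whitney U
test with mid-rank ties; the p-value comes from exact enumeration when both
samples have ≤ 8 observations (the exact path works under ties, which
`stats::wilcox.test` refuses) and from the normal approximation with tie
and continuity correction otherwise.

## Benchmarking impact scores

Scores are compared on a labeled set with a 1:10 positive:negative ratio
(the generator default is 72:720 at desk scale). The AUC is computed as the
Mann–Whitney probability — concordant pairs plus half the ties over
n_pos·n_neg — which equals trapezoidal integration of the empirical ROC
curve and is invariant under monotone score transforms. Operating
thresholds sweep the finite set of observed score values, with "score ≥
threshold" called positive (ties called positive):

- `thr_tpr90`: the **largest** threshold retaining TPR ≥ 0.9 — the most
  stringent cutoff that still keeps sensitivity; its FDR is reported
  alongside.
- `thr_fdr50`: the **smallest** threshold achieving FDR ≤ 0.5 — the most
  sensitive cutoff that controls the false discovery rate; undefined and
  flagged when no cutoff reaches it (e.g. anti-concordant scores).
- `thr_maxacc`: the maximum-accuracy cutoff, ties broken toward the higher
  threshold.

Variants missing a score are excluded per-score (not imputed) with the
exclusion count reported, since missingness differs between scores. Genome
coverage per track is distinct covered positions over genome length. An
optional composite column — the mean of AUC and maximum accuracy, a
convenience ranking metric of this package, not a published statistic — is
off by default and excluded from any validation.

## Annotation and tiering

A small variant's overlap span is its affected reference bases
(POS … POS+len(REF)−1). Score lookup for indels takes the maximum over
affected positions; insertions, which affect a junction rather than a
span, use the two flanking bases. Structural variants (symbolic ALT)
span POS … END (or POS+|SVLEN|−1); breakends are annotated at the breakend
position only, each mate independently. An SV missing both END and SVLEN
is skipped and counted. SVs receive regions and controlled genes but no
tier: a large variant overlapping dozens of elements would make a single
evidence level meaningless.

The tier thresholds (`levelConfig`) are: AF gate 0.01, *strict* (<), so AF
exactly 1% fails; constraint gate 0.7, *inclusive* (≥); functional-element
classes TFBS/DNase/UCNE; per-score FDR50 thresholds from the benchmarking
module or user configuration; HPO-percentile presets 0.90 (gating), 0.95
(likely disease-related) and 0.99 (strongly disease-related). A variant
with no AF annotation passes the rarity gate by default — absence from a
population database is itself evidence of rarity — and is flagged
`RV_AFMISS`; `missing_af = "strict"` reverses this. Multi-allelic records
are tiered per ALT allele. Levels are nested by construction: the code
evaluates level k only after level k−1 holds, so the sets {level ≥ k} can
only shrink with k, and the test suite counts them on simulated VCFs.

Annotation never touches records or genotypes, declares all `RV_*` INFO
fields in the header, and strips any previous `RV_*` fields before writing
new ones, making re-annotation a replacement rather than an accumulation.

## Trio filters

The recessive filter requires proband 1/1 with both parents 0/1; the
dominant filter requires affected carriers with unaffected parents 0/0.
Missing genotypes fail the variant (fail-safe) and are counted; non-diploid
autosomal genotypes are skipped with a warning. Compound-heterozygote
pairing is restricted to one gene at a time, requires the proband
heterozygous at both sites, and infers phase from parental genotypes only
(no read-backed phasing): an allele carried by exactly one parent has a
determined origin; a pair with one paternal-only and one maternal-only
allele is in trans; pairs whose phase cannot be resolved (an allele carried
by both parents) are kept and flagged `phase_ambiguous` rather than
discarded — in a diagnostic setting a possible compound heterozygote is
worth human review. Alleles carried by neither parent have no transmitted
origin and are excluded from pairing. Pairs are classified
coding+coding / coding+regulatory / regulatory+regulatory; whether the
coding partner must additionally pass its own pathogenicity filter is left
to a caller-supplied predicate on the input table, since conventions
differ between pipelines.

## Synthetic data: what it does and does not emulate

The generators produce, deterministically under a seed: a genome of two
1-Mb chromosomes with mock telomeres (10 kb) and centromeres (50 kb);
~2000 regions with log-uniform sizes in [100, 1000] bp (the size range
typical of regulatory-element catalogs) including ~5% planted
high-overlap duplicates; 200 genes; functional-element tracks; partially
covered score tracks with a configurable positive-shift (expected AUC
pnorm(shift/√2)); labeled variant sets at 1:10; and trio VCFs with
Hardy–Weinberg background genotypes (child alleles drawn from parents) and
scenario spikes (recessive, dominant de novo, compound-het trans pair) at
AF below the rarity gate. Desk-scale defaults keep every pipeline stage in
seconds; the acceptance checks use 5000–10 000 regions or variants where
distributional claims need headroom.

The simulations deliberately do *not* model mutation-rate heterogeneity,
trinucleotide context, linkage disequilibrium, sequencing error or
population structure. Passing tests therefore demonstrate that the
machinery is correct — coordinates, counting, ranking, tiering,
segregation logic — not that the constraint metric or the tiering would
achieve any particular sensitivity on real genomes, where covariate
structure and variant density are far richer.

## Numerical and edge-case policies

- Percentile flagging uses strict inequality against the type-1 empirical
  quantile (see above); at n = 5 and the 99th percentile nothing is
  flagged, and with all residuals tied every region sits at constraint 0.5
  and nothing is flagged.
- The expectation model requires n ≥ 60 regions (ten per coefficient).
- Mid-rank ECDFs are used everywhere a rank percentile appears (constraint,
  gene rank tables), so tied inputs always share identical outputs.
- Empty feature sets yield overlap fraction 0; an empty control set is an
  error for enrichment (the test would be meaningless).
- `queryDetails` treats unknown region ids as a reported "not found" list,
  not an error, so batch lookups survive stale id lists.
- Closest-gene and closest-TSS ties break lexicographically; max-accuracy
  threshold ties break toward the higher (more stringent) cutoff.

## Known limitations

Interval queries scan the in-memory `GRanges` rather than an on-disk
spatial index, which is ample at catalog sizes up to a few hundred
thousand regions but would need tabix/bigBed backing at full-genome,
multi-million-region scale. Consequence-field updating understands the
common snpEff `ANN` and bcftools `BCSQ` layouts only. The trio logic
covers autosomal recessive/dominant and compound-heterozygous patterns;
X-linked and imprinting models are out of scope.
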