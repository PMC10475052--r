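---
title: "Quantifying culture-collection recruitment in amplicon communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying culture-collection recruitment in amplicon communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultrecruit)
```

## The question

Classical plating recovers only a small fraction of marine prokaryotes —
the "great plate count anomaly". Two distinct questions hide behind that
statement: what fraction of the *cells* in a water sample forms colonies
(cfu/ml against flow-cytometry cells/ml), and what fraction of the
community's *diversity* and *read abundance*, as seen by 16S amplicon
sequencing, is represented by strains sitting in a culture collection.
`cultrecruit` computes both, for communities characterized by amplicon
sequence variants (ASVs) across ocean depth layers (surface, deep
chlorophyll maximum, mesopelagic, bathypelagic) and plankton size
fractions (free-living 0.2–0.8 µm up to large particles 20–200 µm).

The recruitment statistic is defined at the strictest resolution the data
allow: an ASV is *recruited* iff its sequence is 100% identical, over its
full length and without gaps, to a region of some isolate's 16S sequence.

## Matching model

Isolates are Sanger-sequenced with primers different from the amplicon
primer pair, so sequences are only comparable over the span both amplify —
the V4–V5 hypervariable region delimited by the degenerate primers 515F-Y
(`GTGYCAGCMGCCGCGGTAA`) and 926R (`CCGYCAATTYMTTTRAGTTT`).

**Region extraction.** Primer sites are located by a Hamming-window scan
under IUPAC set semantics: a window base matches a primer code iff its
expansion is a subset of the code's expansion (an `N` in the window
matches everything). Extraction is conservative — zero mismatches by
default — and the extracted region *excludes* the primer-annealing spans,
because amplicon reads are primer-trimmed before denoising, so ASVs carry
no primer sequence. If the forward site is absent on the plus strand the
reverse complement is tried; if only the forward site is found the region
runs to the sequence end; if neither is found the whole oriented sequence
is used. This fallback is deliberate: partial Sanger reads often begin
inside V4, and the containment rule below still enforces full ASV
coverage, which is the binding constraint. Regions shorter than 100 nt
(configurable) are excluded from matching and reported. A separate
diagnostic, `primer_mismatch_profile()`, reports the minimum achievable
mismatch count per primer per isolate — the right tool for asking whether
the amplicon primers could in principle capture an organism that never
matched any ASV.

**Containment.** A pair (isolate, ASV) is reported iff the ASV occurs as
an exact, contiguous, gap-free substring of the isolate's extracted
region. The direction is asymmetric on purpose: the ASV must be fully
covered, the isolate may extend beyond it; an isolate region shorter than
an ASV can never match it. The matcher seeds on the leading 31-mer of
each ASV and verifies every candidate by full string comparison, so the
index is purely an accelerator — its semantics are those of a naive scan,
and the test suite asserts exact equivalence on hundreds of random
instances with planted containments and one-substitution decoys.

**Ambiguity policy.** Under the default `STRICT` policy an ambiguity code
in an isolate sequence never matches, so matching cannot create false
positives. An `EXPAND` mode accepts a region code when the ASV base lies
in its expansion; every STRICT pair is an EXPAND pair. We default to
STRICT because the statistic is defined at 100% identity and ambiguity
codes record uncertainty, not evidence.

## Rarefaction

Percentages are computed on rarefied tables so samples are compared at
equal sampling effort. Each sample is subsampled *without replacement*
(multivariate hypergeometric — reads are physical draws from a finite
pool, not a multinomial) to the minimum retained sample total, 1000
permutations by default, and the reported cell is the round-half-even of
the permutation mean; unrounded means are kept and used for downstream
ranking so ties are not created by rounding. The draw is realized by the
exact sequential-conditional scheme (each taxon's count is a
hypergeometric conditional on the remainder), vectorized over
permutations; every single draw sums exactly to the depth and zeros stay
zero. Sample *i* uses the derived seed `seed + 1009 * i`, so results are
independent of evaluation order. Samples below the target depth are
dropped with a warning before rarefying.

Collector and rarefaction curves use random permutations of sample order
(mean and sd of cumulative richness over orderings), with two exact
anchors verified in the tests: at k = 1 the expected value is the mean
per-sample richness, and at k = n the curve hits total richness with zero
variance. Isolates are dereplicated into 100%-identity OTUs (identical
extracted regions; OTU id = lexicographically smallest member id) before
their accumulation curve is drawn.

## Recruitment percentages and copy-number correction

Per sample, with the matched ASV set M (the union over isolates — an ASV
hit by several isolates counts once):

* `pct_asvs` = 100 · |present ∩ M| / |present|, where *present* means
  rarefied count > 0. The denominator is the per-sample richness, not the
  dataset-wide ASV count, which reproduces per-sample box distributions;
  dataset-pooled variants can be derived from the same table.
* `pct_reads` = 100 · (reads on M) / (total reads).

Stratum summaries are unweighted means ± sample sd over samples within
(dataset, layer[, size fraction]); a single-sample stratum reports sd as
absent rather than zero.

PCR-based read counts overestimate taxa with many rRNA operon copies, and
readily cultured copiotrophs tend to have many. The correction divides
`pct_reads` by the *median* operon copy number of the isolated genera
(single-divisor method; a per-genus correction would require copy numbers
for every matched taxon and is left as an explicitly labelled
experimental route). Reported percentages use one-decimal precision with
a trailing `.0` collapsed (7.97 → "8").

Sensitivity switches: recruitment can be computed on raw tables
(`rarefy = FALSE`), and ASVs can be excluded by rank-qualified taxonomy
labels (e.g. `domain:Archaea`, `phylum:Cyanobacteria`) before rarefying —
heterotroph-targeted media never capture those groups, so excluding them
shrinks only the denominator.

## Rank-abundance classes and occurrence categories

Mean relative abundance is the unweighted mean over samples of per-sample
proportions. Biosphere classes: ABUNDANT above 1%, RARE below 0.01%, MID
between. The class definitions carry strict inequalities on both sides of
MID, leaving the boundary values open; we close both boundaries into MID
and document it (`classify_biosphere`). Ranking ties are broken
lexicographically by ASV id for determinism.

Genus occurrence across isolation stations: UBIQUITOUS when found in more
than 80% of stations, WIDESPREAD at 50% or more, REGIONAL above 25%,
LOCAL otherwise. The mixed strict/inclusive boundaries reproduce the
verbal categories the field uses; all three thresholds are exposed as
arguments so the policy is a visible configuration, not a hidden
constant.

## Statistical tests

Group comparisons are nonparametric throughout: a tie-corrected
Kruskal–Wallis omnibus (chi-square approximation, k − 1 df) followed by
post hoc pairwise two-sided Wilcoxon rank-sum tests, Holm-adjusted by
default (the conventional default of the function family; configurable
to Bonferroni or none). Identical observations give H = 0, p = 1 rather
than an error. Cultivability comparisons are routed through the same
nonparametric path rather than ANOVA, keeping one consistent testing
route; with exactly two groups the omnibus reduces to the rank-sum test.
For small samples the exact rank-sum null is used when tie-free (the
standard behaviour of the underlying routine; forceable either way via
`exact =`), and the suite checks the p-values against full enumeration of
the rank-sum distribution. A validation harness,
`type_one_error_sim()`, estimates the empirical type-I error under an iid
null; note that because ranks are discrete, H = 0 has small positive
probability, so the rejection rate at `alpha = 1` is slightly below 1
under the `p < alpha` rule.

## The synthetic generator

`simulate_study()` builds a complete study with known truth:

* **Community**: lognormal taxon abundances (meanlog 0, sdlog 2 —
  at these settings a handful of taxa exceed 1% and a long sub-0.1% tail
  is typical), 300 taxa by default; random unambiguous ASV sequences of
  373 nt (the V4–V5 span between the default primers), pairwise distinct.
  Sequence realism is unnecessary because the matcher is exact; only
  distinctness matters.
* **Planted recruitment**: a culturable subset (25 heterotrophic
  bacterial taxa by default, drawn with a mild abundance bias) whose
  summed relative abundance is rescaled per stratum to the planted read
  fraction: 3% (surface), 2% (DCM), 8.5% (mesopelagic), 28%
  (bathypelagic) in the free-living fraction, boosted 1.4× on particles.
  These defaults mirror the field pattern of deep and particle-attached
  enrichment of culturable copiotrophs.
* **Counts**: per-sample multinomial draws with probabilities
  proportional to abundance × copy number, 5 samples per stratum at
  50 000 reads ± 5%.
* **Copy numbers**: under the default "inflated" model, culturable genera
  draw from a lognormal with median 3.5 operons (sdlog 0.25) and all
  other taxa have one copy. Restricting the inflation to the culturable
  subset makes the single-median correction identifiable — the planted
  bias is then almost entirely removable by dividing by the true median,
  which is what the correction claims to do. A "none" model (all copies
  1) isolates the recruitment statistic itself.
* **Isolates**: 200 isolates drawn from the culturable taxa with
  probability ∝ abundance^β (β = 1, the copiotroph bias); with coverage
  guaranteed (at least one isolate per culturable taxon — the collection
  inventories its culturable subset, and this makes the planted read
  fraction the exact expectation of `pct_reads`). Each isolate sequence
  embeds its source ASV verbatim between concrete realizations of the
  primer sites with random flanks, so extraction and matching are
  exercised end to end. 11% of isolates (the default) receive one
  substitution inside the region and become unmatchable, emulating
  isolates absent from the sequenced community.
* **Stations**: per-layer lognormal cell densities and Beta-distributed
  cultivability (means ≈ 0.3% photic, ≈ 1.3% mesopelagic and
  bathypelagic, the deep layers more dispersed), with the drawn fractions
  recorded as truth.

What the generator does *not* emulate: sequencing error and chimeras
(ASVs are taken as correctly denoised inputs), taxonomic structure beyond
labels, spatial autocorrelation between stations, and within-genus copy
number variation. Passing the planted-recovery tests therefore
demonstrates correctness of the computation on idealized inputs, not
robustness to upstream denoising artifacts.

## Problem sizes and numerical choices

The test suite runs the matcher-equivalence property on 500 instances (up
to 500 ASVs × 100 regions), the hypergeometric convergence check at
20 000 permutations, planted-fraction recovery at 10 samples × 50 000
reads for f ∈ {0.05, 0.25, 0.5} with 1000-permutation rarefaction, and
the test-size simulation at 10 000 replicates — sizes chosen so each
property is measured against 3 Monte-Carlo standard errors while the
suite completes in about a minute. Determinism is enforced by mandatory
seeds in the generator and rarefier; round-half-even is used wherever a
permutation mean is rounded, to avoid systematic upward bias.

## Limitations

* The 100% identity criterion is deliberately rigid; a single sequencing
  error in either dataset breaks a match, so recruitment percentages are
  lower bounds. No relaxed-identity mode is provided.
* The single-median copy-number correction over- or under-corrects any
  individual taxon; it is unbiased only in aggregate and only insofar as
  the matched taxa share the isolated genera's copy-number distribution.
* The chi-square approximation to the Kruskal–Wallis null is slightly
  conservative at small group sizes (empirical size ≈ 0.044–0.046 at 4
  groups × 10 observations); an exact permutation route is available for
  tiny designs.
* Occurrence categories depend on the station inventory: absence from a
  station is not evidence of absence from the water.
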