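---
title: "Detecting ROH islands as selection signatures in multi-breed SNP panels"
author: "rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ROH islands as selection signatures in multi-breed SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

When a livestock population is intensively selected — for coat colour, body
size, racing ability — the haplotype carrying the favoured allele sweeps
toward fixation and drags a stretch of surrounding genome with it. In
SNP-array data this leaves a characteristic footprint: many individuals of
the breed carry long **runs of homozygosity (ROH)** over the same genomic
interval. A region where the ROH of more than half of a breed's individuals
overlap is called an **ROH island** and is read as a putative signature of
selection. Comparing island catalogues across breeds then separates
breed-specific ("private") targets of selection from regions shared across
related breeds.

`rohscan` implements this analysis as a reusable pipeline for PLINK-format
genotype panels: SNP quality control, per-individual ROH calling under
explicit segment constraints, per-breed incidence tracks and island calling
at a strict sharing threshold, cross-breed island overlap with
private-island classification, candidate-locus genotype statistics with an
exact Hardy–Weinberg test, and identity-by-state PCA for population
stratification. Because array genotypes of the kind this method is applied
to are rarely public, the package also ships a multi-breed panel simulator
with implanted autozygous tracts and a truth set, which is what the test
suite exercises end to end.

## ROH calling model

A candidate segment in one individual is a run of consecutive mapped SNPs
on one chromosome. Six constraints define a reportable ROH; all are
re-checked by an independent validator (`validate_segments()`):

| constraint | default | meaning |
|---|---|---|
| `min_length_bp` | 500,000 | span (last − first SNP position) of at least 500 kb |
| `min_hom_snps` | 81 | more than 80 homozygous SNPs (het and missing excluded from the count) |
| `max_het_in_segment` | 1 | at most one heterozygote tolerated |
| `max_missing_in_segment` | 2 | at most two missing genotypes tolerated |
| `min_density_bp_per_snp` | 50,000 | average of at least one SNP per 50 kb |
| `max_gap_bp` | 100,000 | no two consecutive SNPs further than 100 kb apart |

"More than 80 homozygous SNPs" is read strictly (≥ 81) and counted over
homozygous calls only. "Greater than 500 kb" is implemented as
`length_bp >= 500000`, matching how PLINK's kb threshold behaves on real
data; a literal strict reading is available via `roh_params(strict_gt =
TRUE)`. Segment length is `end_bp - start_bp` (not `+ 1`), again the PLINK
convention.

**Exact caller.** `call_roh_exact()` is the normative semantics: a greedy
left-to-right scan per chromosome. The gap, heterozygote and missing rules
are *hereditary* (every sub-run of a feasible run is feasible), so the scan
extends a run until adding the next SNP would violate one of them, emits
the maximal run, and restarts at the violating SNP. A heterozygote that
could close either of two adjacent runs therefore attaches to the left one
— a deterministic tie-break. Each maximal run is then kept only if it
passes the three threshold rules (length, homozygous count, density).
Segments never overlap and never span chromosomes.

**Windowed caller.** `call_roh_windowed()` reproduces the overlapping-window
screen of PLINK 1.x: all windows of 50 consecutive SNPs with at most 1
heterozygote and 5 missing calls are "hits"; each SNP's hit proportion is
taken over the windows covering it, and SNPs at or above proportion 0.05
form candidate runs that are handed to the exact machinery. The window
parameters are PLINK 1.x defaults — the underlying method description for
this analysis does not state them — so they are exposed in `roh_params()`
and the exact caller is the reference the tests compare against. On
all-homozygous chromosomes and chromosomes with a single isolated
heterozygote the two callers provably agree, and the suite checks this
segment-for-segment on hundreds of random chromosomes; on noisier input the
window screen may trim a few SNPs from candidate-run edges, which is the
expected behaviour of the screen, and every reported segment still
satisfies all six constraints. A chromosome with fewer SNPs than one window
falls back to the exact caller.

`sroh()` sums segment lengths per individual (Mb) and averages per breed
over *all* sampled individuals, including those without any ROH.

## Islands, overlaps and private islands

For each breed, `incidence_track()` computes per SNP the fraction of the
breed's individuals whose ROH covers that SNP — the denominator is the full
breed sample size, and an individual contributes at most once per SNP.
`call_islands()` then reports maximal map-contiguous runs of SNPs with
incidence **strictly** greater than the threshold (default 0.5: "more than
50%"). Two deliberate choices:

* Islands are runs over map order and are **not** split at physical gaps:
  sharing defines the island, and gap control already happened at segment
  calling.
* No minimum island length or SNP count is imposed; a single-SNP island is
  valid and flagged (`single_snp`).

`cross_breed_overlaps()` joins islands of *different* breeds that share at
least 1 bp (closed intervals — abutting islands do not overlap) into
connected components; components with two or more breeds become overlap
regions, with no minimum overlap length. Same-breed islands are never
joined directly but may co-occur in a component through a third breed.
Region bounds are reported both as the union extent and as the envelope of
the pairwise intersections, so either convention can be compared
downstream. An island is **private** exactly when it belongs to no region;
`classify_private()` enforces the conservation identity
`n_private + islands-in-regions = n_total`.

## Candidate loci

`genotype_frequencies()` tabulates per-breed genotype counts at named SNPs;
fractions are over non-missing calls by default. `hwe_exact_test()` is the
standard two-sided exact conditional test of Hardy–Weinberg proportions:
given the allele counts, the p-value is the total probability of all
heterozygote counts whose conditional probability does not exceed the
observed one. It is computed from the log-gamma form of the conditional
distribution; the test suite checks it against an independent
ratio-recurrence enumeration for every genotype table up to n = 50 at
1e-12. `genes_in_islands()` intersects a user-supplied annotation (BED,
0-based half-open, or 1-based TSV) with islands using the same ≥ 1 bp
convention; per-breed gene counts deduplicate symbols across islands. No
remote database is ever queried.

## Population stratification

`ibs_matrix()` computes pairwise identity by state — the mean over SNPs
non-missing in both samples of half the shared allele count — via indicator
matrix products, so panels of hundreds of samples by tens of thousands of
SNPs stay fast. A pair with no shared non-missing SNP is an error naming
the pair. `pca_from_similarity()` uses the classical multidimensional
scaling construction: double-centre the similarity, eigendecompose, scale
eigenvectors by the square root of the non-negative eigenvalues. The exact
PCA internals of early PLINK are not documented, so this standard
construction is fixed and stated. Negative eigenvalues, which can appear
when centring a similarity that is not positive semi-definite (e.g. under
heavy missingness), are dropped from the variance normalisation. Signs are
fixed (largest-magnitude loading positive) for reproducible plots.

## The simulator and what it does (not) emulate

`simulate_panel()` draws a shared SNP map (uniform positions per
chromosome at a target spacing), per-SNP founder allele frequencies
(uniform on 0.05–0.95 by default), and per-breed genotypes at
Hardy–Weinberg proportions. Each implanted tract draws **one founder
haplotype** and sets every carrier homozygous for it across the tract — so
tracts behave like true autozygosity and survive the density and gap rules
exactly as real ROH would, rather than being independently homozygous per
site. Carrier counts are `round(fraction × n)` with half rounding up, which
makes the >50% threshold testable at exact boundaries. Genotyping error
(replacement by a uniformly random genotype) and missingness are applied
*after* implanting, so noise can create heterozygotes inside real tracts
and exercise the one-heterozygote allowance. All randomness flows through
per-(breed, tract, chromosome) sub-seeds hashed from the base seed:
identical seeds reproduce panels byte-for-byte, and resizing one breed
never changes another breed's genotypes.

The simulator deliberately does **not** model linkage disequilibrium,
genetic drift, pedigree structure or mutation. Background genotypes are
independent across SNPs, which makes background ROH (at the 81-SNP / 500 kb
thresholds) astronomically unlikely; real breeds do carry background
autozygosity, so passing tests demonstrate correct *detection machinery*,
not calibrated false-positive rates on real data. `expected_incidence()`
documents this approximation: the expected incidence inside a tract is the
carrier fraction plus a background coverage term taken as 0 for default
designs.

## The demonstration design

`demo_design()` fixes the study conditions the test suite and the
acceptance script run under: 12 breeds × 30 individuals, five 20-Mb
chromosomes at 5 kb spacing (~20,000 SNPs), genotyping error 0.002 and
missingness 0.01, and fourteen implanted tracts — five private (carrier
fraction 0.8), three shared by two breeds, two shared by three breeds, and
four decoys at fractions ≤ 0.4 that must stay below the sharing threshold.
Tracts are 2 Mb, four times the minimum segment length, so that a segment
split by a chance cluster of missing calls (the two-missing allowance makes
a third missing call break a run) still leaves both halves individually
callable; with tracts near the 500 kb minimum, such splits would leave
remnants straddling the threshold and make per-SNP incidence fragile for no
methodological gain. These problem sizes keep a full pipeline run in tens
of seconds on one CPU while preserving every structural feature the
analysis must recover.

```{r demo, eval = FALSE}
scan <- run_pipeline(pipeline_config(design = demo_design(), out_dir = "demo_out"))
print(scan)
summary(scan)
plot(scan, chrom = "5")
```

## Numerical and degenerate-input choices

* QC order is fixed (unplaced → sex chromosomes → missingness) so reports
  reconcile; the missingness rule is strict (> 10% removed, exactly 10%
  kept); samples are never filtered. QC that removes every SNP warns
  rather than errors.
* Zero-SNP panels round-trip through the PLINK writer/reader as valid
  empty files; missing genotypes use the PLINK `01` code and are never
  conflated with a dosage.
* A breed with zero samples, a SNP absent from the map, an unsorted map, a
  tract outside its chromosome, or carrier fractions for unknown breeds
  are all validation errors raised before compute.
* Island threshold exactly met (incidence = 0.5 at n even) yields no
  island; one extra carrier yields exactly one.
* `hwe_exact_test` ties are compared with a 1e-12 relative tolerance on the
  probability ordering, the conventional guard against floating-point
  equality.

## Known limitations

* The windowed caller is a screen plus exact trimming; it is validated
  against the exact caller's semantics, not against any particular PLINK
  binary's output.
* No LD in the simulator means island length distributions on real data
  are not represented; only implanted structure is recoverable by design.
* GO/KEGG enrichment and remote gene retrieval are out of scope; gene
  context requires a user-supplied annotation file.
* The IBS-PCA is a stratification plot aid, not a kinship estimator;
  variance shares on real data depend on array content and sampling.
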