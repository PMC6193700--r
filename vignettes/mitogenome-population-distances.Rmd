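---
title: "Mitogenome population distances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitogenome population distances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomixr)
```

## The problem

Complete mitochondrial genomes (~16,569 nt, maternally inherited,
non-recombining) are a standard instrument for tracing maternal population
history, in particular for ancient-DNA cohorts where nuclear data are
sparse. `mitomixr` implements a full analysis chain for such data: sequence
alignment and variant recoding into a matrix usable by sequence-based
differentiation statistics; pairwise Fst with permutation significance,
Slatkin linearization and ordination; the Shared Haplogroup Distance (SHD),
a frequency-overlap distance over sub-haplogroup profiles; and MITOMIX, an
exhaustive admixture-combination search over candidate source populations.
A forward simulator produces haplogroup hierarchies, population profiles
and per-sample mitogenomes so every stage is testable without any sequence
database.

## Alignment and variant recoding

Each sample is aligned globally against the reference (rCRS coordinates)
with a Needleman–Wunsch/Gotoh dynamic program that is aware of IUPAC
ambiguity codes, which are frequent in ancient-DNA consensus calls. Column
scores are organized by ambiguity class: exact A/C/G/T identity scores 6;
columns whose two base sets intersect score by the more ambiguous symbol's
class — 3 for two-fold codes (R, Y, M, W, S, K), 2 for three-fold (B, D, H,
V), 1 for N; disjoint base sets score −12. Gaps are affine: a run of length
L costs −24 − 6·(L − 1).

Three conventions had to be fixed where the weight table alone does not
determine behavior, and are deliberate design choices of this package:

* **One-sided ambiguity.** A column pairing an unambiguous base with a
  compatible ambiguity code (A against R) scores by the ambiguous symbol's
  class rather than as a mismatch. The aligner's purpose is tolerating
  uncertain calls, and the weight classes are named by ambiguity level, so
  the more ambiguous member of the column decides the class.
* **Gap-run convention.** `gap_open` is charged for the first position of a
  run and `gap_extend` for each further position (the common Gotoh
  convention, consistent with |open| > |extend|). Terminal gaps are charged
  like internal ones: inputs are complete mitogenomes of near-equal length,
  so free end gaps would reward truncation.
* **Deterministic traceback.** Among co-optimal alignments the traceback
  prefers a substitution column over a gap, then a gap in the query row
  over a gap in the reference row. This makes outputs bit-reproducible;
  tests rely on it.

Variant calling reads the alignment into reference-coordinate records. `N`
in the query is missing data, never a variant; an ambiguity code whose base
set contains the reference base is an uncertain reference call; codes
excluding it are substitutions. Insertions are anchored at the preceding
reference position and indel runs are emitted per base, matching the
single-event granularity of the recoding step.

Sequences with more than 500 missing-or-uncertain nucleotides (N plus any
ambiguity letter; the cutoff is strict — exactly 500 is kept) are dropped
before matrix construction. The filter is meant for modern database
sequences; ancient samples are exempted by configuration, since their
missingness is handled per locus.

For the differentiation statistics, indels are recoded as pseudo-SNP
columns: for each distinct insertion event carriers receive `T` and
non-carriers `C`; for each deletion event carriers receive `C` and
non-carriers `T`. SNP columns carry literal alleles (alternate for
carriers, reference letter otherwise, N/ambiguity preserved). Known
length-variation hotspots are excluded by default: the C-insertions at
309, 315 and 16193, the 522–524 and 3106 deletions, and the hypervariable
positions 16182, 16183 and 16519 (both coordinate conventions of the
522/523–524 deletion are listed). Whether the three SNP-position hotspots
are excluded from the Fst input is switchable (`include_snp_hotspots`),
since excluding them is common for haplotype reporting but debatable for
distance estimation.

Samples with strictly identical recoded rows are reported as clusters of
potential direct maternal relatives; `N` is *not* treated as a wildcard
there, because wildcard matching would merge unrelated low-coverage
samples.

## Fst: TN93-Γ distances and distance-based AMOVA

Pairwise population differentiation uses the Tamura–Nei (1993) distance
with gamma-distributed rate heterogeneity (shape 0.325 by default, the
value standard for human mtDNA), computed in closed form with the two
transition classes separated from transversions. Base frequencies are
estimated from each sequence pair pooled, and sites where either letter is
not an unambiguous A/C/G/T are excluded pairwise (complete deletion is
available as an option). Two numerical choices matter:

* **Saturation.** The TN93 estimator diverges when a correction term's
  argument reaches zero, which recoded variable-position strings can do
  (two populations fixed for different haplotypes are 100% divergent by
  construction). The argument is floored at 1e-8, yielding a large finite
  distance; the AMOVA downstream only needs the relative magnitudes, and
  the fixed-haplotype case still yields Fst exactly 1 because the
  within-group variance vanishes.
* **Distances as squared deviations.** The AMOVA variance decomposition
  consumes the molecular distances directly as squared inter-individual
  deviations (the convention of distance-based AMOVA with molecular
  distance matrices, where e.g. a count of pairwise differences is itself
  the squared Euclidean distance between haplotype indicator vectors).

Fst here is therefore the distance-based fixation index (Φst): the
among-population variance component over the total, estimated from the
within- and among-group sums of squares of the TN93 distance matrix.
Negative estimates are legitimate (a finite-sample property when true
differentiation is near zero) and are reported as computed. Significance
comes from permuting individuals between the two populations (10,000
permutations by default) with the p-value the fraction of permuted
statistics at least as large as the observed one, without the +1
correction, so a p of exactly 0 is possible as in standard permutation
reports.

For ordination, Fst values are first clamped at 0 and Slatkin-linearized
(Fst/(1 − Fst)); classical Torgerson scaling (`stats::cmdscale`) embeds
the matrix in two dimensions. Clamping is needed because linearized
negative values are negative "distances" that break double-centering.

## Shared Haplogroup Distance

Populations are summarized by their sub-haplogroup frequency profiles.
The raw SHD between profiles *f* and *g* is

SHD(f, g) = 1 − Σ_h min(f_h, g_h),

one minus the shared frequency mass. This is the unique symmetric overlap
complement meeting the metric's stated extremes — 0 for identical
profiles, 1 for disjoint sub-haplogroup sets — and it equals half the L1
distance between the frequency vectors, so it satisfies the triangle
inequality. Its key analytic property links it to admixture: if a target
population is a convex mixture w·A + (1 − w)·B of sources with disjoint
profiles, then SHD(target, A) = 1 − w exactly. The distance is
proportional to the admixing ratio, which is what makes the MITOMIX search
meaningful.

The *corrected* SHD additionally credits frequency mass stranded in a
sub-haplogroup whose direct progenitor or progeny lineage (one
nomenclature step, resolved from an explicit tree or by label-prefix
stripping) carries unmatched mass on the other side: such mass counts as
shared at a partial credit (default weight 0.5), paired greedily along
parent–child edges so each unit of mass is credited at most once. This is
a deliberately simple parameterization of the idea that recent mutation
and lineage fixation blur terminal haplogroup labels between closely
related populations; the published variant of the correction involves
mutation- and fixation-rate terms whose exact algebra is specified in a
companion reference rather than reproduced here, so the parameterized
credit should be read as this package's own scheme. Setting
`correction_weight = 0` recovers the raw, uncontested metric, and the
corrected value never exceeds the raw one.

SHD uses frequencies only — sample sizes are kept as metadata but do not
weight the distance — so small ancient cohorts are comparable with large
modern databases, at the cost of higher estimation noise in small
profiles.

## MITOMIX

MITOMIX decomposes a test population over a candidate pool: for every
source-set size K between `k_min` and `k_max` (defaults 1 and 6 — in
practice mixtures beyond 6 sources stop improving the fit) it enumerates
every K-subset and every mixing-proportion vector on a grid (default 1%
steps, matching the integer percentages in which such components are
conventionally reported) and ranks hypotheses by the SHD between the test
profile and the mixed profile. Proportions in a solution are strictly
positive: a source at 0% is exactly the smaller-K solution, so allowing
zeros would only duplicate entries. Ties are broken deterministically
(smaller K, then lexicographic source labels, then weights).

The search is exhaustive by design; an admissible pruning bound keeps it
tractable. For a subset S, no convex combination of its profiles can
exceed the elementwise maximum, so 1 − Σ_h min(test_h, max_{k∈S} f_kh)
lower-bounds the achievable SHD; subsets whose bound exceeds the current
`top_n` cutoff are skipped. The bound never discards an optimal solution,
and the test suite asserts that pruning on/off returns identical results.
The number of weight vectors per subset is the composition count
C(m − 1, K − 1) with m = 1/grid_step, so e.g. K = 3 at 1% resolution
enumerates 4,851 vectors per subset.

Near-optimal solutions are summarized per source as min–max proportion
ranges across the `top_n` best hypotheses, the form in which admixture
components of this kind are usually quoted. An epoch filter restricts the
pool to populations contemporaneous with or older than the test population
(equal epochs retained), for decompositions of ancient cohorts.

## The synthetic-data generator

The simulator emulates exactly the statistical structure the analyses
assume:

* a haplogroup hierarchy whose labels extend their parent's label by one
  segment, as in mtDNA nomenclature (`H` → `H1` → `H1a`), with `depth`
  counting label-extension levels below the root, so each major clade has
  `branching^(depth-1)` leaf descendants;
* per-haplogroup defining variants that are strictly nested along
  lineages (a child carries all of its parent's variants), drawn once per
  model at distinct reference positions;
* populations as frequency profiles over leaf haplogroups; admixed
  populations as convex combinations of source profiles;
* per-sample genomes built from the reference by applying the drawn
  haplogroup's defining variants, adding Poisson-distributed private SNPs
  and masking each site to N with a Bernoulli missing rate.

Private mutations never hit defining-variant positions, so the simulated
haplogroup ground truth is unambiguous; insertions are single-nucleotide
and deletions single-position, matching the per-event granularity of the
recoding rules. The reference defaults to the rCRS length of 16,569 nt,
but any length from 100 nt is accepted and the test suite runs on
300–800 nt toys so the full pipeline (including the quadratic aligner)
stays fast. Every sampling function takes an explicit seed and leaves the
global RNG state untouched.

What the simulator does *not* emulate — and hence what green tests do not
certify about real data: coalescent genealogy within haplogroups,
recurrent mutation and homoplasy at hypervariable sites (hotspots are
modeled only as an exclusion list), contamination and damage patterns of
ancient DNA, heteroplasmy, and database-scale unevenness of population
sampling. Conclusions about real cohorts still require the usual
aDNA-specific quality control upstream.

## Problem sizes and determinism

The test suite runs the complete pipeline on three synthetic populations
of 6–8 samples over 300–800 nt references, Fst null calibrations on 160
samples at 100–1,000 permutations, and admixture searches over pools of
3–5 candidates at 1–10% grids; these sizes make the whole suite run in
about two minutes while leaving every statistical check at 3-sigma or
better resolution. Alignment is O(n·m) in time and memory per pair (three
byte traceback matrices), so full 16.5 kb mitogenomes are alignable but
budget roughly a gigabyte per concurrent alignment. All stochastic stages
derive named substreams from the single pipeline seed; reruns with the
same configuration are bit-identical, which the manifest's content digests
make checkable.

## Known limitations

* Φst is the only AMOVA design offered (two groups, no hierarchical
  levels).
* The corrected SHD is a one-step, fixed-credit scheme, not a calibrated
  mutation-rate model; treat corrected values as a sensitivity analysis
  around the raw metric.
* The exhaustive search is exponential in K; with the default 1% grid,
  pools beyond ~20 candidates need coarser grids or smaller `k_max` to
  stay desk-scale.
* The VCF writer emits the minimal 8-column body (sites and carrier
  lists), not per-sample genotype columns.
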