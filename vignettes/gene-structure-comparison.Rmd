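---
title: "Comparing automatic and manually curated gene models repertoire-wide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing automatic and manually curated gene models repertoire-wide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annodiff)
```

## The question

Automated gene annotation pipelines (MAKER-style) produce the bulk of the
protein-coding gene models used in comparative genomics, and research
communities then manually curate a small fraction of them — typically a
few percent, chosen by biological interest rather than at random. annodiff
quantifies what that curation does to *repertoire-wide* gene structure:
whether the distributions, set-wide medians and correlative trends of
structural properties differ between the automatic models and their
curated successors, and whether the curated subset is representative of
the full gene set at all.

## Gene sets

One run analyses one species, given four inputs: the genome assembly
(FASTA), the automatic annotation AUTO (GFF3), the official gene set OGS
(GFF3, the non-redundant merge of curated, de novo and untouched
automatic models) and a provenance map linking curated OGS models to
their automatic predecessors. From these, five (sub)sets are built:

* **AUTO** — all automatic models; **OGS** — all official models;
* **MAN-SUB** — curated models with an automatic predecessor;
* **AUTO-SUB** — the distinct predecessors of the MAN-SUB models;
* **MAN-ADD** — de novo models without a predecessor.

Curation splits and merges models, so predecessor links may be
one-to-many or many-to-one; AUTO-SUB holds each predecessor once. The
provenance map is a deliberate, explicit 3-column TSV
(`ogs_gene_id`, `auto_gene_id`, `status`) rather than an attempt to parse
curation attributes out of GFF3 — attribute conventions vary too much
between projects for the latter to be robust. A merged model lists its
predecessors comma-separated; OGS models absent from the map default to
"unchanged automatic". How a curation project records these links is its
own business; any bookkeeping can be flattened into this format.

## Per-transcript properties

All property analyses consider a single transcript per gene: the one with
the greatest *summed exon length*. Genomic span would be an alternative
reading of "longest", but the analysis concerns coding structure, and a
short-spanned transcript with more coding sequence is the better
representative; ties (identical coding lengths) break to the
lexicographically smallest transcript id so runs are deterministic.

Because UTRs are rarely annotated consistently across projects, exons are
identified with coding sequence: a transcript parsed from GFF3 uses its
exon features when they agree with its CDS features, the CDS features
when the two disagree (with a warning), and whichever is present when
only one is. Per transcript we measure: unspliced (pre-mRNA) length in
bp; protein length in aa as `floor(coding bp / 3)` (a
`subtract_stop_codon` flag subtracts one; the default does not, and is a
declared convention, not an inference — annotation projects are
inconsistent about whether the stop codon is inside the terminal CDS);
exon count and intron count (always `exon_count - 1`); the
per-transcript median exon and intron lengths; and the per-transcript
median exon and intron GC contents. Intron-based fields of single-exon
transcripts are undefined (`NA`) and are excluded — with reported counts
— from set-wide medians and intron-based correlations; they are *not*
dropped from exon-based analyses. GC of a feature is
`100 * (G+C) / (A+C+G+T)` over its bases; ambiguity codes count toward
neither numerator nor denominator, and an all-ambiguous feature has
undefined GC. Assembly-level GC ("GC without ambiguity") uses determined
(A/C/G/T) positions only, while coding and intronic proportions divide by
the *full* assembly size including ambiguity. Overlapping gene models are
summed as-is in these proportions, not union-merged; a merge option
exists but the plain sum matches the definition "summed lengths of all
exonic sequences relative to genome size".

## Statistical comparisons

Every unordered pair among the five sets is compared for each of five
properties (unspliced length, protein length, exon count, median exon
length, median intron length) with both a two-sample Kolmogorov-Smirnov
test (sensitive to any distributional difference) and a two-sample
Wilcoxon rank-sum test (sensitive mainly to location). Bonferroni
correction is applied per test type over all tests of that type in the
invocation — one species per invocation, so the family is e.g. 10 pairs x
5 properties = 50 KS tests. Pooling species into one family would be the
alternative; since species are analysed as independent runs, the
per-invocation family is the coherent choice here. Significance is
flagged at adjusted p <= 0.05.

Gene structure data are heavily tied (counts, integer lengths), which the
textbook small-sample machinery in `stats` refuses. The tests therefore
run in two regimes. For small samples (`n1 + n2 <= 40` by default) the
p-value is computed exactly over the permutation distribution of group
labels, tie-aware, by dynamic programming: lattice-path counting over tie
groups for the KS statistic, and subset rank-sum convolution (on doubled
average ranks, which are integers) for the Wilcoxon statistic. For large
samples the asymptotic forms are used via `stats::ks.test` (Kolmogorov
distribution at effective size `n1*n2/(n1+n2)`) and `stats::wilcox.test`
(normal approximation with tie-corrected variance and continuity
correction), and are declared approximate under ties. The exact regime is
what makes the package's p-values agree with brute-force enumeration to
within 0.02 at tiny sample sizes — the normal approximation alone can be
off by ~0.09 at n = 2 + 2.

Spearman's rank correlation (Pearson on average ranks, via
`stats::cor(method = "spearman")`) is computed per set for four pairs:
exon count vs median exon length, exon count vs median exon GC, intron
count vs median intron length, intron count vs median intron GC; the
intron pairs use only transcripts with at least one intron. Coefficients
are reported without p-values: at gene-repertoire sample sizes trivially
small effects are "significant", so the coefficient itself is the
informative quantity.

## Representativeness by fixed-size subsampling

Whether a subset (MAN-SUB, AUTO-SUB, MAN-ADD) is representative of its
full set is assessed non-parametrically: draw, 1000 times, a subsample of
1000 models *without replacement* from the full set, compute the Spearman
coefficient of a property pair on each, and ask whether the subset's
coefficient falls inside the interval spanned by the 1000 resampled
coefficients. The default interval is the min-max range — consistent
with speaking of a value "lower than the interval minimum" — with a
percentile mode (default 2.5-97.5, linear interpolation) available as a
robust alternative; min-max as the default is an assumption, flagged as
such. Boundary equality counts as inside. Membership may overlap
*across* replicates; only within-replicate sampling is without
replacement. This is a subsampling procedure, not a jackknife estimator:
no bias correction or pseudo-values are involved, despite the family
resemblance. If the full table has fewer usable rows than the subsample
size the run stops with advice to lower `n_subsample` — silent clamping
would quietly change the statistics.

Reproducibility: a master seed generates one sub-seed per replicate up
front, so replicate *k* is identical regardless of how many replicates
follow it, and reruns under one seed are bitwise identical. Under
exchangeability, a random same-size subset escapes the min-max interval
of *m* replicates with probability about `2/(m+1)` — about 0.2% at the
default 1000 replicates — so "outside" classifications of curated
subsets are not subsampling noise.

## The synthetic data generator

Real curated annotations with provenance records are scarce, so the
package carries a first-class generator whose outputs exercise every
pipeline stage with known ground truth:

* **Genome**: i.i.d. background sequence at a configurable GC content
  (default 35%, AT-rich as is typical for insect genomes), with ambiguity
  (N) runs covering a configurable fraction (default 3%, run length 5 kb)
  placed away from gene loci. Realized GC is checked against the target
  (±1 point) at generation.
* **Automatic annotation**: by default 2000 non-overlapping gene models.
  Exon counts are `1 + NB(size = 2, mu = 5)` — right-skewed with median
  5, matching typical insect repertoire medians of 4-6; the `mu` value
  was chosen so the theoretical CDF brackets 0.5 with enough margin
  (0.44/0.55) that the sample median at n = 2000 is stable. Exon,
  intron and intergenic lengths are log-normal (medians 250 bp, 400 bp,
  1.5 kb; dispersions 0.6, 0.9, 0.7). Exon lengths are rounded to
  multiples of 3 so coding length stays divisible by 3 under every
  perturbation operator. Exonic sequence is rewritten at a configurable
  GC offset over background (default +10 points), giving the exon/intron
  GC contrast seen in real genomes; intron GC follows background. A
  fraction of multi-exon genes (default 20%) gets a second, strictly
  shorter isoform so longest-transcript selection is actually exercised.
  A manifest records every gene's true structural properties.
* **Curation**: `round(manual_fraction * n)` models (default 5%, inside
  the 3.5-6.9% band seen in practice) are perturbed by operators
  emulating documented curation actions — 3' boundary shift
  (extend/trim), terminal exon addition/removal, merging adjacent models
  (one OGS model, two predecessors), splitting at an intron (two OGS
  models, one predecessor) — with configurable mix and magnitudes.
  A de novo fraction (default 1%, matching the 0.3-2.2% band) of short
  1-3-exon "receptor-like" models is inserted into intergenic gaps, so
  MAN-ADD is structurally distinct by construction. The count of curated
  models is deterministic (a rounded fraction, sampled without
  replacement), so realized MAN-SUB/MAN-ADD percentages recover the
  configured fractions up to the small distortion that merges and splits
  introduce into the OGS denominator.

Deliberate non-realism: no codon structure, splice-site motifs, repeats
or expression evidence; genes never overlap or nest in the automatic
annotation (boundary extensions during curation may create overlaps,
which is itself realistic). Passing tests on these data therefore
demonstrate the correctness of the *accounting, measurement and
statistical machinery*, not robustness to the sequence-level messiness of
real assemblies.

## Numerical conventions

* Coordinates are 0-based half-open internally (lengths are `end -
  start`), 1-based inclusive in all GFF3 and emitted tables.
* Set-wide medians use the mean of central values at even n, so
  half-values like 8562.5 are expected; per-transcript `NA`s are excluded
  per property with reported counts.
* Reported percentages round to one decimal, half away from zero;
  unrounded values are kept alongside.
* Undefined GC propagates as `NA` and never silently becomes zero.
* Degenerate statistical inputs are explicit: empty samples error,
  identical pooled samples give p = 1, zero rank variance gives an `NA`
  coefficient, and an `NA` coefficient yields an `NA` classification.

## Problem sizes in the shipped tests

The test suite validates the statistics against brute-force enumeration
at n1 + n2 <= 12 (where full enumeration is cheap and exact), structural
properties against straight-line recomputation on 200-500-gene
annotations, parameter recovery on a 2000-gene bundle, and resampling
coverage at 200 replicates x 200 subsamples over a 5000-row table. These
sizes were chosen as the smallest at which each property is
distinguishable from noise; the pipeline defaults remain at the
1000 x 1000 resampling scale.

## Limitations

* Exons are equated with CDS throughout; annotations with rich UTR
  structure lose that information on input.
* Trans-spliced and cross-scaffold gene models are rejected, not
  modelled.
* The asymptotic KS p-value under heavy ties is approximate; for
  borderline decisions at moderate n, use `method = "exact"`.
* The Bonferroni family covers one invocation; meta-analyses across many
  species should consider their own correction.
* Predecessor links must be supplied; the package deliberately does not
  infer them from coordinate overlap.
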