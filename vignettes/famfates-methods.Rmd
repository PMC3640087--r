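---
title: "Methods: duplication epochs, QTL co-localization and paralog fates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplication epochs, QTL co-localization and paralog fates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famfates)
```

# Scope and model

`famfates` re-implements, as tested and composable stages, the bespoke
computations of genome-wide gene-family surveys in paleopolyploid plant
genomes — the soybean-style setting of one ancient whole-genome
triplication (the gamma WGT) followed by two whole-genome duplications
(the legume WGD and the recent *Glycine* WGD).  The stages are:

1. **Annotation and gene order.**  Genes live on chromosomes with 1-based
   inclusive coordinates (GFF3 convention; BED is converted at import).
   Each chromosome carries a 0-based *rank* in start-coordinate order,
   with ties broken lexicographically by gene id so every pipeline run is
   deterministic.  The rank is the substrate for "consecutive in the
   genome" decisions.
2. **Duplication modes.**  Each gene receives exactly one mode with the
   priority `WGD_SEGMENTAL > TANDEM > PROXIMAL > DISPERSED > SINGLETON`.
   Segmental calls require anchorage in a *valid* intra-species collinear
   block (at least 5 anchor pairs, no consecutive-anchor gap above 20
   intervening genes — the usual MCScanX acceptance rule).  Tandem means
   a homolog at rank distance 1 (chains of consecutive homologs are all
   tandem); proximal means a homolog within 10 ranks (configurable);
   dispersed means homologs exist but none of the positional predicates
   hold.  The priority order follows the convention of the standard
   duplicate-gene classifiers; the literature rarely states it
   explicitly, so it is documented here as a package decision.
3. **Ks and epoch dating.**  Block age is summarized by the arithmetic
   mean Ks over anchors with finite values.  Mean Ks below 0.3 dates the
   divergence after the *Glycine* WGD, above 1.5 after the gamma WGT, and
   the closed interval [0.3, 1.5] after the legume WGD.  The boundary
   values fall in the middle interval: the customary phrasing ("less
   than", "more than", "between") leaves the boundaries open, and a
   closed middle interval makes the three intervals a partition.
4. **QTL co-localization.**  QTL physical positions are uncertain, so a
   locus is the mapped *marker point*, and a gene is associated with a
   locus when the gap between the marker and the gene *span* is at most
   the window (default 2 Mb on each side).  Distance is the number of
   bases strictly between the closest boundaries, 0 on overlap.  Traits
   are seed-relative by case-insensitive keyword match (default:
   `seed`, `pod maturity`, `beginning pod`, `full maturity`, `yield`),
   configurable because trait vocabularies differ between QTL databases.
5. **Expression.**  RPKM is `1e9 * C / (N * L)` with `C` the read count,
   `N` the library's total mapped reads and `L` the gene's total exon
   length.  Relative expression divides each RPKM column by the
   geometric mean of the reference genes' RPKM in that sample (the
   qPCR-style multi-reference normalization).  A reference gene with zero
   RPKM anywhere is an error by default — silently flooring a reference
   hides a broken normalization; an explicit `pseudo` floor is opt-in.
   Detection is `value > tau` with `tau = 0`: the source data distinguish
   only "detected" from "undetectable", so any nonzero signal counts.
6. **Paralog divergence and fates.**  For each pair and tissue the bin is
   `BOTH_UNDETECTED`, `ONE_UNDETECTED`, or a fold-ratio bin of
   `r = max/min`: `LOW` for `r` in `[1, 2]`, `MID` for `(2, 10]`, `HIGH`
   above 10 (left-open, right-closed, so the ratio bins partition
   `[1, Inf)`).  Percentages use the full `n_pairs * n_tissues`
   denominator; with 46 pairs and 17 tissues this is 782, the denominator
   that makes the published percentages (30.2 / 14.5 / 10.6 / 4.9 for
   counts 236 / 113 / 83 / 38) come out exactly, with `BOTH_UNDETECTED`
   as the unprinted remainder.

# Fate classification

The published analyses state the qualitative patterns —
nonfunctionalization when one member of a pair is never expressed,
subfunctionalization when both members are expressed but in diverged
domains — without a decision rule.  The package's rule, over the tissues
where at least one member is detected:

* `NONFUNCTIONALIZATION` when the `ONE_UNDETECTED` fraction is at least
  `silence_frac` (default 0.8) *and* the silenced member is the same gene
  in at least `silence_frac` of those tissues;
* `SUBFUNCTIONALIZATION` when both members are detected somewhere and the
  diverged fraction (`MID`, `HIGH` or `ONE_UNDETECTED`) is at least
  `div_frac` (default 0.5), without a consistent silenced member in the
  sense above;
* `CONSERVED` when the `LOW` fraction exceeds `1 - div_frac`;
* `AMBIGUOUS` otherwise, including pairs undetected everywhere.

The checks run in that order, so a pair with a high but not
fully-consistent one-sided silencing pattern falls through to the
subfunctionalization test rather than being forced into a silencing
call.  Both thresholds are explicit configuration; 0.8 demands that
silencing be the dominant and directionally consistent signal before the
stronger claim is made, and 0.5 asks only that divergence affect at
least half of the informative tissues.

# Ka/Ks estimator

Block Ks values are usually supplied with the collinearity scan; when
they must be computed from pre-aligned CDS pairs the package implements
the Nei–Gojobori (1986) counting method with Jukes–Cantor correction:
per-codon synonymous site counts are the fraction of the nine
single-nucleotide mutations that preserve the amino acid, averaged over
the two sequences; differences between codons are averaged over all
mutational pathways; proportions are corrected by
`-3/4 * log(1 - 4p/3)`, returning `NaN` at saturation (`p >= 3/4`).
Two conventions are fixed and shared with the validation oracle:
mutations that create a stop codon count as nonsynonymous, and pathways
through stop codons are included (a step between two stop codons counts
as synonymous).  Sequences must be pre-aligned and in frame — codon
alignment is out of scope; codons containing ambiguous nucleotides are
skipped with a warning.

# The synthetic-data generator

The generator exists so that every stage can be validated against known
truth; its defaults *are* the study conditions it emulates and are not
tuned per test:

* **Genome history.**  One ancestral chromosome of 20 genes undergoes the
  triplication and the two duplications with per-event retention 0.70 /
  0.75 / 0.85 on new copies, giving 12 chromosomes and on the order of
  160 surviving family genes — the scale of a large plant
  transcription-factor family.  Collinear blocks arise one per
  chromosome pair from the shared ancestral genes, and anchor Ks values
  are drawn uniformly from disjoint per-event ranges (gamma 1.6–2.5,
  legume 0.4–1.4, *Glycine* 0.05–0.28) chosen inside the three epoch
  intervals, so epoch recovery is exact by construction; deliberately
  overlapping ranges can be configured for robustness experiments.
* **Single-gene duplicates.**  19 tandem, 14 proximal and 30 dispersed
  copies (the proportions reported for the type-I side of such families)
  are inserted with valid-block anchors as sources, so the source keeps
  its segmental label under the mode priority and each insert carries
  its programmed mode.  Dispersed copies are inserted first, proximal
  copies (rank gaps 2–8) second and tandem copies last, so later inserts
  cannot break the programmed adjacency of earlier ones.
* **QTL map.**  70% of 60 loci are planted at a uniform distance in
  `[0, window)` from a random gene boundary; the rest go to a gene-free
  chromosome, out of reach of any association.  Half the loci are
  seed-relative.
* **Counts.**  17 samples reuse the tissue labels of the seed-development
  RNA-seq design, with the 11 seed tissues as the default seed subset
  (the seedling cotyledon `CoS` counts as non-seed: it is a
  post-germination tissue).  46 designated pairs receive programmed
  fates: 30% nonfunctionalized (one member forced to zero everywhere),
  the rest split between subfunctionalized (complementary seed/non-seed
  domains at high/low negative-binomial means 300/5, so fold ratios are
  large but both members stay detectable) and conserved (equal means).
  Remaining genes draw a profile class at proportions mirroring
  genome-wide family surveys (18% seed-only, 6% non-seed-only, 15%
  silent).  Counts are negative binomial with size 10; the three
  reference genes get equal means in every sample with counts floored at
  1, because the relative-expression contract requires positive
  reference signal (constitutive expression).  Library sizes add a
  1e7-read background for the rest of the transcriptome.

What the generator does *not* emulate: sequence evolution (Ks values are
drawn, not evolved — except the optional synonymous-only CDS mode used
to validate the estimator), mapping/quantification noise, shared-segment
mosaicism between overlapping blocks, marker-order error, and
batch/tissue covariance in expression.  Passing the recovery tests
therefore demonstrates the correctness of the *computations*, not the
biological accuracy of any particular survey.

# Numerical and degenerate-input choices

* Ranks tie-break by gene id; equidistant nearest features tie-break by
  smaller feature start; clustering ties resolve by row order through
  `stats::hclust`.
* Gene-wise z-scores use the population standard deviation (denominator
  `n`), stated so worked examples are reproducible; constant rows are
  excluded and reported.
* Clustering uses average linkage (UPGMA) on `1 - Pearson` distance, the
  common default of expression-clustering tools; single and complete
  linkage are available.  Cluster count is user-set (`k` or a cut
  height): the published 13-cluster figure has no stated cut criterion,
  so cluster-count reproduction is not attempted.
* Genes undetected in all tissues are excluded from clustering (they are
  constant rows under any normalization).
* Blocks failing the validity rule are parsed and reported but excluded
  from mode and epoch evidence; blocks with no finite anchor Ks keep an
  unassigned epoch.
* A gene without exon records falls back to its span as a single exon,
  with a warning; an empty annotation, a reference gene at zero, a
  frame-broken CDS and a k-above-row-count cut are errors.

# Validation problem sizes

The test suite validates the mode classifier against a brute-force
predicate oracle on 100 simulated genomes of ~500 genes (64 ancestral
genes), the window association against an all-pairs oracle, the NG86
estimator against a mutation-enumeration oracle on 1000 random 20-codon
pairs, and the UPGMA tree against a naive re-agglomeration oracle on 100
random 6x5 matrices; epoch, planted-association, silenced-fraction and
fate recovery run at the generator's default scale.  These sizes were
chosen to exercise every code path at the scale of the emulated study.

# Known limitations

* Collinearity detection itself (anchor chaining) is out of scope; blocks
  are inputs.
* The "transposed duplication" interpretation of dispersed genes flanked
  by transposable elements is left to the user: the package exposes
  nearest-feature distances but makes no transposition call.
* Inter-species origin inference is evidence-based and coarse: a
  subfamily anchored in an outgroup-collinear block is dated before the
  oldest event, otherwise to the oldest epoch among its blocks; absence
  of evidence yields "untraceable", not a date.
* Whether published block Ks values were averaged before or after
  thresholding cannot always be determined; the package thresholds block
  means, and a supplied per-pair Ks column takes precedence over
  recomputation.
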