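---
title: "Models and methods behind sgescore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sgescore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgescore)
```

This vignette documents the statistical models, the parameter choices, and
the design decisions in `sgescore`, in the spirit of a methods section a
maintainer can audit.

## Coordinate frame and library design

A `target_region` is an amplicon in coding-strand orientation with an exon
annotation, a CDS phase (how many bases of the first exonic codon lie
upstream of the region), and a design window. Coordinates are **1-based and
intervals closed**, the native R/Bioconductor convention; HGVS-style
strings in reports are derived from the `cdna_offset`. `enumerate_snvs()`
produces all `3 × window length` substitutions.

Consequence annotation translates the affected codon of the spliced exonic
sequence — codons split across exon junctions are assembled from the
spliced CDS before translation, using the standard genetic code table. One
mutually exclusive label per variant: a new in-frame stop is `nonsense`, an
unchanged amino acid `synonymous`, otherwise `missense`; intronic positions
1–2 nt from an exon boundary are `canonical_splice`, 3–8 nt
(`splice_region_range`, the Sequence Ontology convention; configurable) are
`splice_region`, deeper positions `intronic`. Exonic (coding) consequence
takes precedence near junctions, so the taxonomy partitions the library.
Positions in a codon whose remaining bases fall outside the region raise an
error rather than guessing an incomplete translation.

## Read processing

Mate pairs are merged by an exhaustive ungapped overlap scan (all overlaps
of at least `min_overlap = 10` nt, scored as matches minus mismatches; ties
go to the longer overlap). Disagreeing overlap bases resolve to the
higher-quality call. Merged products are kept when their length lies in
`[30, 300]` nt and their mean phred quality is at least 30 — the standard
assembly settings for short amplicons. Pre-merged reads are accepted
directly and skip this step.

Read classification applies the single-SNV filtering rule: a full-length
read is compared base-by-base against the amplicon; exactly one mismatch at
a designed (position, alt) pair inside the design window counts for that
variant, zero mismatches for the reserved wild-type row, one undesigned (or
out-of-window) mismatch is discarded as `undesigned_snv`, and two or more
mismatches as `multi_snv`. Reads of the wrong length are `indel` when they
anchor to the amplicon (exact 12-nt terminal anchor on either end, or a
unit-cost edit-distance optimum containing a gap within an edit budget of
30% of the amplicon length); otherwise `unalignable`. Counting conserves
reads exactly: counted + discarded = input, per sample. Wild-type reads are
tallied (useful QC context) but excluded from all score denominators, which
are defined over variant-assigned reads only.

## Abundance scoring

The raw score is the weighted average of a variant's within-bin
frequencies, with default weights 0.1 / 0.15 / 0.2 / 1 from the lowest to
the highest abundance bin; two-gate (reporter-negative/positive) sorts use
weights 0 / 1, i.e. the variant's relative frequency in the positive gate.
Bins with zero variant-assigned reads contribute nothing; variants with no
reads anywhere are flagged `NA`, never scored zero. Variants under the
read-support floor (default 10 variant reads across bins per replicate,
configurable) are likewise reported unscored — the floor exists because a
frequency ratio over a handful of reads is dominated by sampling noise.

Normalization anchors each experiment: `s_v = (w_v − med_nonsense) /
(med_syn − med_nonsense)`, which pins the synonymous median at exactly 1
and the nonsense median at exactly 0 and makes scores comparable across
exon libraries. At least 5 scored variants of each anchor class are
required; an experiment whose synonymous median does not exceed its
nonsense median has no dynamic range and errors out as degenerate.
Classification z-scores each variant against the mean and sd of the
synonymous normalized scores (a median/MAD option exists for
outlier-contaminated anchors but is not the default): z above −2 is
`normal`, below −3 `low`, and the band between — with boundary ties read
strictly — `indeterminate`. Replicates are combined by averaging
per-replicate normalized scores (default) or by pooling counts; averaging
keeps replicates equally weighted regardless of depth.

## Fitness scoring and mechanism

Fitness is the log2 ratio of pseudocounted frequencies, endpoint (day-14
cells) versus reference (plasmid library), with pseudocount 0.5 on both
sides so fully depleted variants stay finite. Classification mirrors the
abundance logic: z against the synonymous ratio distribution, depleted at
z < −2 (one-sided; a three-class mode with an indeterminate band is
available for symmetry). Because every ratio is taken against the pool,
selection elsewhere in the library shifts all ratios by the mean growth
factor; the score table therefore also reports synonymous-median-centered
ratios, on which neutral variants sit at zero by construction. Classes use
z-scores and are unaffected by centering.

With two genetic backgrounds, mechanism labels follow the decision table:
depleted on the partial-function background ⇒ `dominant_negative`
(expected to be depleted on the null background as well); depleted only on
the null background ⇒ `loss_of_function`; depleted on the partial but not
the null background is biologically incoherent and flagged `discordant`;
indeterminate or missing classes give `unscored`.

## Clinical calibration

`oddspath()` implements the Bayesian likelihood ratio
`[P2 (1 − P1)] / [(1 − P2) P1]` with prior P1 taken over **all** classified
truth variants — indeterminate-class variants keep their labels in the
prior totals but form no calibrated class. When a class cell is zero, one
variant of the opposing classification is added **to the class counts
only**, leaving the prior untouched; this is the conservative zero-cell
treatment of the ClinGen calibration framework. Evidence strengths use
that framework's interval scheme (pathogenic 2.08 / 4.33 / 18.7 / 350;
benign 0.48 / 0.23 / 0.053 / 0.00286), stored in an editable
`evidence_thresholds()` object. The combiner is the point-based system
(±1/2/4/8 by strength; ≥10 pathogenic, 6–9 likely pathogenic, 0–5 VUS,
−6…−1 likely benign, ≤−7 benign). Predictor scores enter as evidence via
`revel_evidence()` with ClinGen-recalibrated REVEL cutpoints; hotspot
(PM1) and allele-frequency (PM2) evidence are deliberately not generated
by this package, matching gene-specific practice of dropping evidence
that is circular with functional or predictor data.

## Screen scoring

Guide log2 fold changes are computed after normalizing the endpoint to the
reference by the median count ratio of the non-targeting controls (robust
to a large depleted fraction; total-count normalization is the fallback).
Gene scores are the arithmetic mean of the gene's guide values across
replicates. Significance is an empirical two-sided test: the null is the
mean of `guides_per_gene` non-targeting guide values resampled with
replacement (10,000 draws by default, seeded; exhaustive enumeration is
available for tiny nulls), p-values carry the add-one correction, and calls
are made at Benjamini–Hochberg q ≤ 0.05 by sign. This resampling test is a
transparent reconstruction — no specific published screen-analysis method
is being reimplemented — and that is its main caveat: it treats guides as
exchangeable and ignores count-level overdispersion beyond what the
controls carry.

## The synthetic-data generator

The generator is first-class, tested code; its defaults describe the study
conditions the pipeline is validated under.

* **Sort-seq forward model.** Each variant contributes
  `cells_per_variant = 2000` cells (plus a 2% unedited wild-type fraction);
  a cell's fluorescence ratio is the variant's latent score times lognormal
  noise with sd 0.35 on the log2 scale — multiplicative cytometry noise of
  roughly ±27% per cell. Gates are quartiles of the pooled ratio
  distribution (the pooled median for two-gate mode), so bin occupancy
  adapts to the library composition exactly as sorter gates set on the
  pooled population do. Per-bin reads are multinomial draws from the bin's
  cell composition at `reads_per_variant_per_bin = 500`; sequencing noise
  adds substitution errors at `error_rate = 0.001`/base and indels at
  `indel_rate = 0.0002`/read.
* **Latent classes.** Nonsense and canonical-splice variants are damaging;
  synonymous and deep-intronic variants are normal; missense and
  splice-region variants are damaging with probability
  `missense_low_prop = 0.35`, in line with the observed fraction of
  damaging missense variants in a constrained structural domain. Latent
  normalized scores are drawn at 1 ± 0.05 (normal) and 0.05 ± 0.03
  (damaging, floored at 0.01). The class spreads were chosen so the
  synonymous and nonsense score distributions are bimodal and cleanly
  disjoint — the defining qualitative feature of a working abundance
  assay, in which every nonsense variant scores far below the z = −3
  line. Wider normal-class spreads are available for stress-testing, but
  they describe a noisier assay than the one modeled here.
* **Growth model.** Exponential outgrowth over `doublings = 9` (a 14-day
  culture at roughly 1.5 days/doubling): endpoint weights are
  `p0 (1 + s)^g` with `s = −0.4` for damaging variants, multinomially
  sampled at 1,000 reads/variant; plasmid representation is lognormal with
  log-sd 0.3 (a realistic 2–3× spread between well- and poorly-represented
  library members). Dominant negatives (20% of damaging missense) carry
  `s < 0` on both backgrounds; loss-of-function variants only on the null
  background.
* **Screens.** Two guides per gene plus 200 non-targeting controls; 10% of
  genes essential with the same selection-per-doubling model; the neuron
  endpoint grows out of the realized iPSC endpoint so iPSC-essential genes
  are already depleted before the differentiation contrast.
* **What it does not emulate.** PCR chimeras and jackpotting, index
  hopping, quality-score-dependent errors (qualities are constant Q37 and
  error injection explicit), sorter impurity beyond gate stochasticity,
  cell-cycle or differentiation bottlenecks (a bottleneck is expressible
  only through `cells_per_variant`), and linkage between nearby edits.
  Passing recovery tests therefore demonstrates that the estimators invert
  this forward model at realistic noise — not that real libraries are free
  of those artifacts.

All simulation entry points are deterministic given (config, seed):
identical inputs give byte-identical FASTQ files and count tables.

## Numerical choices and degenerate inputs

* Boundary ties (z exactly −2 or −3) are `indeterminate`; the thresholds
  are read as strict inequalities on both sides.
* All-zero count rows are `NA` scores, flagged and propagated, never 0.
* `normalize_scores()` errors when anchors overlap (no assay separation);
  `classify_*()` error on zero synonymous spread rather than emitting
  infinite z-scores.
* Merge-overlap ties resolve to the longer overlap (shorter insert), the
  conservative choice for nested amplicons; anchoring uses exact 12-nt
  terminal matches before paying for an edit-distance alignment.
* The pseudocount 0.5 (fitness, screens) is the Haldane–Anscombe-style
  half-count on both numerator and denominator.
* Empirical p-values use the add-one correction, so no p is ever 0 and
  seeded reruns are reproducible.

## Problem sizes used by the test suite

The validation suite exercises the pipeline at the scales the methods are
meant for while staying desk-sized: a 450-SNV library (150 mutagenized
positions) at 2,000 cells/variant and 500 reads/variant/bin for abundance
recovery; a full two-background growth experiment at 1,000 reads/variant
with 20-seed averaging for the neutrality check; and ten replicate neutral
screens of 500 genes × 2 guides with 200 non-targeting controls and 10,000
resamples for false-discovery calibration. Exhaustive oracles (full-CDS
retranslation, all-offset overlap scans, complete single-mutation
injection, enumeration of all small evidence profiles and tiny resampling
nulls) back the unit tests at toy scale.

## Known limitations

* The consequence annotator handles SNVs only — by design, since SGE
  libraries are SNV libraries — and does not score splice-altering exonic
  variants as such; they carry their coding label.
* Abundance and fitness classification assume the synonymous class is
  overwhelmingly neutral; a contaminated anchor set shifts both the center
  and the spread (the robust option mitigates, not removes, this).
* OddsPath calibration inherits every bias of the clinical truth set;
  with few truth variants in a class the zero-cell adjustment dominates
  and the resulting strength should be read as a cap, not an estimate.
* The screen test is a reconstruction (see above) and its q-values are
  calibrated only against the exchangeability null that the non-targeting
  controls define.
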