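# sgescore

Variant scoring for saturation genome editing (SGE) experiments in induced
pluripotent stem cells (iPSCs) and their differentiated derivatives.

## The problem

SGE installs every possible single-nucleotide variant (SNV) across a target
exon into cells at the endogenous locus, then phenotypes the pooled library
by sequencing. Two readouts are supported here:

* **Sort-seq protein abundance.** Cells are FACS-sorted into bins by the
  ratio of variant-tagged to wild-type-tagged fluorescence and each bin is
  sequenced. A variant's abundance score is the weighted average of its
  across-bin frequencies,

  `w_v = Σ_b ω_b f_vb / Σ_b f_vb`,

  with bin weights `ω = (0.1, 0.15, 0.2, 1)` from the lowest to the highest
  abundance bin (or `(0, 1)` for two-gate organoid sorts). Scores are
  anchored per experiment so that the median synonymous variant scores 1 and
  the median nonsense variant 0, then classified against the synonymous
  distribution: z > −2 is normal abundance, z < −3 is low, in between is
  indeterminate.

* **Growth-based fitness.** For an essential gene, variant effect is the
  log2 ratio of a variant's frequency after ~14 days of outgrowth versus
  the input plasmid library, z-scored against synonymous variants and
  classified depleted vs functionally normal. Running the same library on a
  *null* and on a *partial-function* background allele separates simple
  loss-of-function variants (depleted only when the second allele is null)
  from dominant negatives (depleted even with a partly functional second
  allele).

Functional classes become clinical evidence through OddsPath, the Bayesian
likelihood ratio

`OddsPath = [P2 (1 − P1)] / [(1 − P2) P1]`,

where P1 is the proportion of pathogenic variants among all classified
truth variants and P2 the proportion within a score class. OddsPath maps to
ACMG PS3/BS3 evidence strengths on the ClinGen interval scheme, and a
point-based combiner (supporting/moderate/strong/very strong = 1/2/4/8
signed points) reclassifies variants of uncertain significance (VUS).

The package also scores pooled CRISPR knockout screens (guide log2 fold
changes versus a plasmid library, gene means, and an empirical resampling
test against non-targeting controls) and ships a seeded synthetic-data
generator with known truth for every assay mode, so the whole pipeline is
testable without raw sequencing data.

## Worked example

Simulate a one-exon target with 150 mutagenized exonic positions, score the
sort-seq experiment, and calibrate the classes against a simulated clinical
truth set:

```r
library(sgescore)

region  <- simulate_region(length = 174, n_exons = 1, seed = 7)
designs <- enumerate_snvs(region)
cfg     <- sim_config()
truth   <- assign_true_effects(designs, cfg, seed = 7)
sortseq <- simulate_sortseq(truth, region, designs, cfg, seed = 7)

scores <- score_abundance(sortseq$counts, designs)
scores
#> SGE abundance score table: 522 designed variants, 522 scored
#> class
#>        normal indeterminate           low
#>           370            14           138

summary(scores)
#> Class by consequence:
#>                   class
#> consequence        normal indeterminate low
#>   canonical_splice      0             0  12
#>   intronic             22             2   0
#>   missense            219            11  93
#>   nonsense              0             0  18
#>   splice_region        21             0  15
#>   synonymous          108             1   0
#>
#> Anchors: synonymous median = 1, nonsense median = 0

labels <- simulate_truth_labels(truth, cfg, seed = 7)
cal <- calibrate_classes(
  setNames(as.character(scores$class), scores$variant_id),
  labels$truth_set)
cal
#> Functional-evidence calibration: prior P1 = 0.2871 (29 PLP, 72 BLB)
#>   class nP nB         P2    oddspath code strength
#>     low 27  0 0.96428571 67.03448276  PS3   strong
#>  normal  2 69 0.02816901  0.07196402  BS3 moderate
```

Every nonsense and canonical-splice variant is recovered as low abundance,
the anchors hold exactly, and with this simulated truth set a low-abundance
call carries strong pathogenic evidence (OddsPath 67, PS3 strong) while a
normal call carries moderate benign evidence. `score_fitness()` and
`score_screen()` follow the same pattern for the growth and knockout-screen
readouts; see the methods vignette (`vignettes/sge-methods.Rmd`) for the
models, parameter choices, and limitations.

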