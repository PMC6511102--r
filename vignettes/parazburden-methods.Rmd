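---
title: "Methods: paralog conservation z-scores and regional missense burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog conservation z-scores and regional missense burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parazburden)
```

## The scientific problem

When a cohort of patients carries rare variants in one gene, two questions
recur: *where* on the protein do the patient variants sit relative to
variation tolerated in the general population, and *are* the patient
missense variants concentrated in a functionally critical region? For
syntaxin-1B — a 288-residue presynaptic SNARE protein in which variants
cause a spectrum of fever-associated epilepsies — the critical region is
the SNARE motif, the coiled-coil that zippers with SNAP-25 and
synaptobrevin to drive vesicle fusion. parazburden implements the four
variant-level computations such a study needs, plus a synthetic-data
generator that makes every stage testable without access to any external
variant database.

## Variant model

Variants are protein-level (HGVS p.) only; transcript-level parsing is
out of scope. The grammar covers missense (`p.Val88Phe`), stop-gain
(`p.Lys93*`), frameshift (`p.Ser10Alafs*7`, where the trailing integer is
the distance in codons to the new stop) and a whole-gene deletion token.
One- and three-letter residue codes are both accepted on input because
published variant lists mix them freely; canonical output is three-letter.
A whole-gene deletion has no residue coordinate, so it is excluded from
every position-based analysis (density, z-scores, enrichment) and appears
only in class counts and the genotype–phenotype crosstab. For the
crosstab, frameshift and stop-gain pool into a single "truncating"
category: both predict nonsense-mediated decay, i.e. the same
haploinsufficiency mechanism.

The package ships a 17-variant syntaxin-1B cohort fixture
(`stx1b_variants()`): 8 missense, 5 frameshift, 3 stop-gain, 1 whole-gene
deletion, annotated with family, phenotype group (GEFS+/GGE/DEE/FE) and
inheritance. Three family-to-variant pairings are inferred from group
constraints rather than stated in the source cohort description; the
fixture's comment header flags them.

## Domain map

The domain architecture of syntaxin-1B (Ha/Hb/Hc helices, linker, SNARE
motif, transmembrane region) is published only schematically, so numeric
boundaries are user input, never package truth. The shipped default
(`stx1b_domain_map()`: SNARE 192–254, TMR 266–288, Habc helices between
residues 28 and 144) comes from standard protein annotation (UniProt
P61266, helix bounds by homology with syntaxin-1A) and is explicitly
non-authoritative: any region-level result should cite the map actually
used. Intervals are 1-based inclusive and non-overlapping; uncovered
residues form the implicit region `"other"`.

## Sliding-window mutational density

The density at a coding-nucleotide position is the fraction of positions
in its surrounding window that carry at least one population variant.
Design choices the underlying idea leaves open, fixed here:

* **Window placement.** The window is centred; for the default length 10
  it covers `[i − 5, i + 4]`. For even windows the extra position sits on
  the left — arbitrary but fixed and documented.
* **Edges.** The window is truncated at the sequence ends and the divisor
  is the *actual* truncated window size, not the nominal length.
  Dividing by the nominal length would bias the first and last five
  positions downward by up to a factor of two; with the actual divisor,
  a fully saturated position set gives density exactly 1 everywhere.
* **Counting unit.** Distinct variant *positions*, not alleles or
  carriers. Multi-allelic sites count once.
* **Projection to residues.** Each residue gets the mean of its three
  codon-position densities. The mean (rather than the max) yields the
  smooth per-amino-acid profile appropriate for plotting against a
  domain map.

Window length defaults to 10 nucleotides. Valid windows are 1 to the
coding length; the density is monotone in the position set (adding a
variant position never lowers any value) and bounded in [0, 1] — both
properties are enforced by tests against a brute-force window-enumeration
oracle for all coding lengths up to 60.

## Paralog conservation z-scores

The idea: residues that the whole paralog family refuses to vary are
candidates for function the family shares; a patient variant at such a
residue is more suspicious. The pipeline consumes a pre-computed
paralog-family alignment (aligned FASTA; alignment construction is out of
scope) and proceeds in three steps.

**Column scoring.** The original analysis scored columns with an
interactive alignment viewer whose exact metric is not reproducible from
its description, so the package ships two documented scorers behind one
interface and records the scorer name in every output:
`identity_fraction` (default) — the fraction of non-gap residues equal to
the column's modal residue; `property_class` — the fraction sharing the
modal physicochemical class (hydrophobic AVLIMFW, polar STNQY, positive
KRH, negative DE, special GPC). Both lie in [0, 1]. Gaps enter neither
the modal count nor the denominator; all-gap columns are rejected at
load time.

**Residue mapping.** Column scores attach to residues of a focal protein
through its gap structure; columns where the focal protein is gapped map
to no residue and never enter its statistics.

**Per-protein standardisation.** For focal protein *p* with column
scores *c₁…c\_L* over its own non-gap columns, the para_zscore of residue
*i* is *(cᵢ − mean\_p)/sd\_p*, with the n−1 standard deviation (the
denominator convention is stated because the source description does
not). Normalisation is per protein, not pooled across the family, so
every member's profile has mean 0 and sd 1 over its own residues (the
package enforces this to 1e−9). A residue is called *paralog-conserved*
when its z-score is strictly positive. A protein whose columns all score
identically has no meaningful z-scale and raises a degenerate-profile
error rather than returning zeros.

## Enrichment testing

The burden comparison asks whether patient missense positions concentrate
in a region relative to population missense positions. The counting unit
on both sides is the distinct residue position. Two complementary nulls
are reported, clearly labelled, because the original study names its test
only by its p-value:

* **Fisher's exact test** on the 2×2 table (patient/population ×
  in/out-of-region), two-sided by probability ordering — the sum of
  hypergeometric probabilities of all tables, at fixed margins, no more
  probable than the observed one. The reported odds ratio is the sample
  odds ratio `(a·d)/(b·c)` (infinite when `b·c = 0`), not the conditional
  MLE. Degenerate margins return p = 1 with a flag. The implementation is
  verified against exhaustive `choose()`-based enumeration over **all**
  2×2 tables with row margins up to 30, and spot-checked against
  `stats::fisher.test`.
* **A permutation test** whose null draws the same number of patient
  positions uniformly without replacement from all residues, with
  statistic the in-region count and the add-one estimator
  `(1 + #[null ≥ observed])/(n_perm + 1)`.

The distributional comparison of para_zscores at patient vs population
variant sites uses a two-sided Mann–Whitney rank-sum test with midrank
ties: exact enumeration of all rank assignments when the pooled sample
size is at most 12, otherwise the normal approximation with tie-corrected
variance and a 0.5 continuity correction. The two branches agree within
0.02 on balanced samples of six per side, and both are cross-checked
against `stats::wilcox.test` on tie-free data.

**Reproducibility of random streams.** Every stochastic routine takes a
single integer seed and draws from R's Mersenne-Twister stream seeded
once, so a result is exactly reproducible from (seed, n_perm) on any
platform running R ≥ 4.1. A counter-based per-replicate substream was
considered and rejected: base R provides no counter-based generator, and
a seeded MT stream delivers the same reproducibility guarantee here.

## Synthetic data: what it emulates and what it does not

`gen_paralog_family()` emulates a 7-member paralog family over 288
residues with a planted conserved block at 180–250: an ancestor drawn
uniformly over the 20 amino acids, per-column substitution probability
0.05 inside the block and 0.5 outside, substitutions uniform over the 19
alternatives, and gaps (rate 0.05) only outside the block so block
columns always map to focal-protein residues. `gen_cohort()` emulates
the burden setting: 120 distinct population positions drawn uniformly
(the order of the per-gene distinct missense-position count in large
population databases for a constrained ~300-residue protein), 8 distinct
patient positions drawn with weight 5 inside a region covering 72/288 =
25% of the protein.

These generators deliberately omit several features of real data:
substitution biases (no BLOSUM-like exchangeability), indel evolution,
phylogenetic correlation between members, mutational hot-spots (CpG),
coverage-dependent ascertainment, and allele frequencies. Passing the
ground-truth-recovery tests therefore demonstrates that the *pipeline
machinery* recovers planted signal — not that real patient cohorts will
show enrichment, which depends on biology and on the population snapshot
used.

## Calibration facts worth knowing

Two properties of the default study conditions are dictated by the
discreteness of small-sample statistics and are worth stating plainly:

* The permutation test's rejection rule `p ≤ 0.05` cannot attain size
  0.05 with 8 patient positions and a 25% region: the attainable
  upper-tail probabilities of the in-region count jump from 0.111 to
  0.0255, so the exact size is 0.0255. The test is conservative, not
  broken; empirical measurements near 0.025 are the correct behaviour.
* The power of Fisher's exact test against the planted 5× enrichment at
  these sample sizes is almost exactly 60%, so 200-replicate estimates
  fluctuate on either side of 0.60 depending on the seed set.

## Problem sizes

The validation suite runs the generators at their default sizes
(7 × 288 families; 8 + 120 position cohorts), 200 replicates for
ground-truth recovery, 500 replicates at `n_perm = 999` for the size
check, and the full enumeration over 2×2 tables with margins ≤ 30
(246,016 tables); the whole suite completes in well under a minute of
compute per property. These sizes were chosen as the smallest at which
the binomial error of the estimated rates is clearly below the decision
margins.

## Known limitations

* Transcript-coordinate (c.) notation, genomic liftover and
  allele-frequency weighting are out of scope by design.
* The two conservation scorers approximate, and do not reproduce, the
  interactive viewer score used in the original analysis; rankings are
  expected to agree, numeric values are not comparable.
* Domain boundaries are user input; the shipped syntaxin-1B defaults are
  annotation-derived and non-authoritative.
* No multiple-testing correction across regions is applied — the design
  assumes a single pre-specified region of interest.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
dir <- tempfile(); dir.create(dir)
fam <- gen_paralog_family(family_spec(gap_rate = 0, seed = 11))
write_paralog_fasta(fam, file.path(dir, "family.fasta"))
ch <- gen_cohort(cohort_spec(seed = 11))
write_cohort_tsv(ch, file.path(dir, "patient.tsv"), file.path(dir, "population.tsv"))

cfg <- run_config(
  variants_tsv = system.file("extdata", "stx1b_variants.tsv", package = "parazburden"),
  alignment_fasta = file.path(dir, "family.fasta"),
  population_tsv = file.path(dir, "population.tsv"),
  domains_yaml = system.file("extdata", "stx1b_domains.yaml", package = "parazburden"),
  focal_protein = "P1", region = "SNARE", n_perm = 999, seed = 11,
  out_dir = file.path(dir, "out")
)
report <- run_all(cfg)
report
```

The report echoes the full configuration (scorer, window, region
boundaries, `n_perm`, seed), and rerunning with the same config and seed
reproduces it byte for byte.
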