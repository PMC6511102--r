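# parazburden

Variant-level statistics for protein genotype–phenotype studies:
where do a patient cohort's variants sit on the protein, how does that
compare with variation tolerated in the general population, and are the
patient missense variants enriched in a functionally critical region?

The package grew out of the analysis pattern used for syntaxin-1B
(*STX1B*), a 288-residue presynaptic SNARE protein in which
heterozygous variants cause fever-associated epilepsies ranging from
benign GEFS+ to developmental and epileptic encephalopathy. It is,
however, generic over any protein with a domain map, a paralog family
and a population variant background. It provides:

* **HGVS p. variant parsing and classification** — missense
  (`p.Val88Phe`), stop-gain (`p.Lys93*`), frameshift
  (`p.Ser10Alafs*7`), whole-gene deletion; one- and three-letter codes;
  genotype–phenotype crosstabs with frameshift/stop-gain pooled as
  truncating.
* **Sliding-window mutational density.** For each coding-nucleotide
  position *i*, the fraction of positions in a centred window (default
  10 nt, truncated at the edges with the actual window size as divisor)
  that carry a population variant, projected to residues by codon mean.
  Distinct variant positions are the counting unit.
* **Paralog conservation z-scores (para_zscore).** Per-column
  conservation of a paralog-family alignment (two documented scorers:
  modal-residue identity fraction, or modal physicochemical class),
  mapped through the focal protein's gap structure and standardised per
  protein: *z&#8342; = (c&#8342; − mean&#8346;)/sd&#8346;* with the n−1
  standard deviation. Residues with *z* > 0 are called
  paralog-conserved.
* **Regional enrichment tests.** A 2×2 Fisher exact test
  (probability-ordering two-sided p, sample odds ratio) and a uniform
  permutation test over distinct residue positions, plus a Mann–Whitney
  comparison (exact for pooled n ≤ 12, midrank ties) of para_zscores at
  patient vs population variant sites.
* **A seeded synthetic-data generator** for paralog families with a
  planted conserved block and patient/population cohorts with planted
  regional enrichment, so every stage is verifiable against known
  ground truth without downloading any variant database.

## Worked example

The package ships a 17-variant syntaxin-1B cohort and a default
(annotation-derived, user-replaceable) domain map:

```r
library(parazburden)

cohort <- stx1b_variants()
classify_counts(cohort_variants(cohort))
#>            missense           stop_gain          frameshift whole_gene_deletion
#>                   8                   3                   5                   1

dm <- stx1b_domain_map()
crosstab_genotype_phenotype(cohort, dm, "SNARE")
#>       missense_in_SNARE missense_elsewhere truncating deletion
#> GEFS+                 0                  0          4        0
#> GGE                   1                  0          1        0
#> DEE                   2                  3          3        1
#> FE                    0                  2          0        0
```

The crosstab shows the study's central genotype–phenotype pattern: the
mild GEFS+ families all carry truncating variants (haploinsufficiency),
while SNARE-motif missense variants cluster in the severe DEE group.

On synthetic data with known ground truth — a 7-member family with a
conserved block planted at residues 180–250, and a cohort with 5×
patient enrichment in residues 180–251:

```r
fam <- gen_paralog_family(family_spec(gap_rate = 0, seed = 11))
pz  <- para_zscore(column_conservation(fam), fam, "P1")
round(region_z_summary(pz, dm, "SNARE"), 3)   # SNARE overlaps the planted block
#>   mean    q25 median    q75      n
#>  1.253  0.950  1.528  1.528 63.000

ch  <- gen_cohort(cohort_spec(seed = 11))
pat <- lapply(ch$patient_positions, function(p) parse_hgvs_p(sprintf("p.Ala%dVal", p), "GENE"))
enrichment_test(pat, ch$population, domain_map("ROI", 180, 251, 288), "ROI",
                n_perm = 999, seed = 11)
#> Enrichment in ROI: patient 7/8 in-region vs population 30/120
#>   OR = 21, Fisher p = 0.0006823, permutation p = 0.004 (n_perm = 999, seed = 11)
```

The planted block shows the expected high mean para_zscore (+1.25 vs a
whole-protein mean of 0), and the planted enrichment is detected by
both the exact and the permutation test. `run_all()` chains all stages
(variants → density → para_zscore → enrichment → report) from a single
config and writes a deterministic, provenance-stamped text report; a
thin command-line wrapper lives at `inst/cli/parazburden.R`. See the
methods vignette (`vignettes/parazburden-methods.Rmd`) for the model
details and design decisions.

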