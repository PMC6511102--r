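# Independent oracles and small fixture builders shared across tests.

# Brute-force sliding-window density: per-position window enumeration,
# no cumulative sums.
oracle_sliding_density <- function(positions, L, window) {
  half <- window %/% 2
  vapply(seq_len(L), function(i) {
    w <- max(1, i - half):min(L, i + window - half - 1)
    mean(w %in% positions)
  }, numeric(1))
}

# Exhaustive two-sided Fisher p by probability ordering, using plain
# choose() arithmetic (no dhyper, no fisher.test).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0) {
    return(1)
  }
  support <- max(0, k - r2):min(k, r1)
  pr <- choose(r1, support) * choose(r2, k - support) / choose(N, k)
  pobs <- pr[match(a, support)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Linear-scan region lookup for a position (first covering interval wins).
oracle_region_scan <- function(position, dm) {
  for (i in seq_len(nrow(dm))) {
    if (dm$start[i] <= position && position <= dm$end[i]) {
      return(dm$name[i])
    }
  }
  "other"
}

# A tiny hand-checkable alignment: 3 members, 5 columns.
tiny_alignment <- function() {
  paralog_alignment(
    c("alpha", "beta", "gamma"),
    c("AAC-D",
      "AVCTD",
      "ALC-E")
  )
}

# The 17 canonical HGVS strings of the shipped cohort fixture.
fixture_hgvs <- function() {
  c("p.Val88Phe", "p.Cys144Phe", "p.Glu210Lys", "p.Leu221Pro",
    "p.Ala246Pro", "p.Ser258Gln", "p.Arg261Gln", "p.Ile282Thr",
    "p.Ser10Alafs*7", "p.Gln52Argfs*2", "p.Glu128Glyfs*2",
    "p.Asn189Alafs*5", "p.Thr285Aspfs*75",
    "p.Lys93*", "p.Tyr140*", "p.Arg245*",
    "whole_gene_deletion")
}

# Write a synthetic pipeline input set (gap-free family so the focal
# protein spans the full 288-residue domain map) and return a run_config.
make_pipeline_config <- function(dir, seed = 11L, n_perm = 199L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- gen_paralog_family(family_spec(gap_rate = 0, seed = seed))
  write_paralog_fasta(fam, file.path(dir, "family.fasta"))
  ch <- gen_cohort(cohort_spec(seed = seed))
  write_cohort_tsv(ch, file.path(dir, "patient.tsv"), file.path(dir, "population.tsv"))
  file.copy(system.file("extdata", "stx1b_variants.tsv", package = "parazburden"),
            file.path(dir, "variants.tsv"))
  file.copy(system.file("extdata", "stx1b_domains.yaml", package = "parazburden"),
            file.path(dir, "domains.yaml"))
  run_config(
    variants_tsv = file.path(dir, "variants.tsv"),
    alignment_fasta = file.path(dir, "family.fasta"),
    population_tsv = file.path(dir, "population.tsv"),
    domains_yaml = file.path(dir, "domains.yaml"),
    focal_protein = "P1",
    population_space = "residue",
    region = "SNARE",
    n_perm = n_perm,
    seed = seed,
    out_dir = file.path(dir, "out")
  )
}
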