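test_that("HGVS p. parsing handles the three consequence classes and both code styles", {
  cases <- list(
    list(s = "p.Val88Phe", class = "missense", pos = 88L, ref = "Val", alt = "Phe"),
    list(s = "p.V88F", class = "missense", pos = 88L, ref = "Val", alt = "Phe"),
    list(s = "p.Lys93*", class = "stop_gain", pos = 93L, ref = "Lys", alt = "Ter"),
    list(s = "p.K93*", class = "stop_gain", pos = 93L, ref = "Lys", alt = "Ter"),
    list(s = "p.Tyr140Ter", class = "stop_gain", pos = 140L, ref = "Tyr", alt = "Ter"),
    list(s = "p.Ser10Alafs*7", class = "frameshift", pos = 10L, ref = "Ser", alt = "Ala"),
    list(s = "p.S10Afs*7", class = "frameshift", pos = 10L, ref = "Ser", alt = "Ala"),
    list(s = "p.Thr285Aspfs*75", class = "frameshift", pos = 285L, ref = "Thr", alt = "Asp")
  )
  for (cs in cases) {
    v <- parse_hgvs_p(cs$s, "STX1B")
    expect_s3_class(v, "protein_variant")
    expect_identical(v$vclass, cs$class)
    expect_identical(v$position, cs$pos)
    expect_identical(v$ref_aa, cs$ref)
    expect_identical(v$alt_aa, cs$alt)
  }
  expect_identical(parse_hgvs_p("p.Ser10Alafs*7", "STX1B")$fs_ter_offset, 7L)
  expect_identical(parse_hgvs_p("p.Thr285Aspfs*75", "STX1B")$fs_ter_offset, 75L)

  del <- parse_hgvs_p("whole_gene_deletion", "STX1B")
  expect_identical(del$vclass, "whole_gene_deletion")
  expect_true(is.na(del$position))
})

test_that("malformed strings and unknown residue codes raise distinct errors", {
  expect_error(parse_hgvs_p("Val88Phe", "STX1B"), class = "parazburden_parse_error")
  expect_error(parse_hgvs_p("p.", "STX1B"), class = "parazburden_parse_error")
  expect_error(parse_hgvs_p("p.Val88", "STX1B"), class = "parazburden_parse_error")
  expect_error(parse_hgvs_p("p.Val88Val", "STX1B"), class = "parazburden_parse_error")
  expect_error(parse_hgvs_p("p.Ter88Phe", "STX1B"), class = "parazburden_parse_error")
  # bad amino-acid codes are a different condition class than bad syntax
  expect_error(parse_hgvs_p("p.Xyz88Phe", "STX1B"), class = "parazburden_aa_error")
  expect_error(parse_hgvs_p("p.Val88Xyz", "STX1B"), class = "parazburden_aa_error")
})

test_that("parse/format round trip is the identity on all 17 fixture variants", {
  for (s in fixture_hgvs()) {
    expect_identical(format_hgvs_p(parse_hgvs_p(s, "STX1B")), s,
                     info = s)
  }
  # one-letter input canonicalises to the three-letter form
  expect_identical(format_hgvs_p(parse_hgvs_p("p.A246P", "STX1B")), "p.Ala246Pro")
})

test_that("classify_counts sums to input length, is permutation-invariant and additive", {
  vs <- lapply(fixture_hgvs(), parse_hgvs_p, gene = "STX1B")
  counts <- classify_counts(vs)
  expect_identical(sum(counts), length(vs))
  expect_identical(classify_counts(list()),
                   c(missense = 0L, stop_gain = 0L, frameshift = 0L,
                     whole_gene_deletion = 0L))
  expect_identical(classify_counts(vs[1])["missense"], c(missense = 1L))

  set.seed(42)
  for (i in 1:5) {
    expect_identical(classify_counts(sample(vs)), counts)
  }
  split_at <- 6L
  expect_identical(
    classify_counts(vs[1:split_at]) + classify_counts(vs[-(1:split_at)]),
    counts
  )
})

test_that("assign_domain matches a linear-scan oracle on random domain maps", {
  dm1 <- domain_map("A", 1, 10, 20)
  v1 <- parse_hgvs_p("p.Met1Val", "G")
  expect_identical(assign_domain(v1, dm1), "A")        # inclusive start
  expect_identical(assign_domain(parse_hgvs_p("p.Met10Val", "G"), dm1), "A")
  expect_identical(assign_domain(parse_hgvs_p("p.Met11Val", "G"), dm1), "other")
  expect_identical(assign_domain(parse_hgvs_p("whole_gene_deletion", "G"), dm1), "all")
  expect_error(assign_domain(parse_hgvs_p("p.Met21Val", "G"), dm1),
               class = "parazburden_param_error")

  set.seed(7)
  for (rep in 1:10) {
    L <- sample(10:60, 1)
    # random non-overlapping intervals via sorted breakpoints
    n_dom <- sample(1:4, 1)
    bp <- sort(sample(L, 2 * n_dom))
    dm <- domain_map(paste0("D", seq_len(n_dom)),
                     bp[seq(1, 2 * n_dom, 2)], bp[seq(2, 2 * n_dom, 2)], L)
    for (pos in seq_len(L)) {
      v <- parse_hgvs_p(sprintf("p.Ala%dVal", pos), "G")
      expect_identical(assign_domain(v, dm), oracle_region_scan(pos, dm))
    }
  }
})

test_that("genotype-phenotype crosstab matches a hand tally and ignores record order", {
  dm <- domain_map("ROI", 5, 10, 20)
  cohort <- data.frame(
    gene = "G",
    hgvs_p = c("p.Ala6Val", "p.Ala12Val", "p.Lys3*"),
    family_id = c("F1", "F2", "F3"),
    phenotype_group = c("DEE", "DEE", "GEFS+"),
    inheritance = c("de_novo", "unknown", "inherited"),
    stringsAsFactors = FALSE
  )
  tab <- crosstab_genotype_phenotype(cohort, dm, "ROI")
  expect_identical(tab["DEE", "missense_in_ROI"], 1L)
  expect_identical(tab["DEE", "missense_elsewhere"], 1L)
  expect_identical(tab["GEFS+", "truncating"], 1L)
  expect_identical(sum(tab), 3L)
  expect_identical(as.integer(rowSums(tab)),
                   c(1L, 0L, 2L, 0L))  # GEFS+, GGE, DEE, FE family totals

  shuffled <- cohort[c(3, 1, 2), ]
  expect_identical(crosstab_genotype_phenotype(shuffled, dm, "ROI"), tab)

  empty <- cohort[0, ]
  expect_true(all(crosstab_genotype_phenotype(empty, dm, "ROI") == 0L))

  expect_error(crosstab_genotype_phenotype(cohort, dm, "nope"),
               class = "parazburden_config_error")
  dup <- cohort
  dup$family_id <- "F1"
  expect_error(crosstab_genotype_phenotype(dup, dm, "ROI"),
               class = "parazburden_config_error")
})

test_that("the shipped cohort fixture loads, validates and covers all four phenotype groups", {
  co <- stx1b_variants()
  expect_identical(nrow(co), 17L)
  expect_identical(anyDuplicated(co$family_id), 0L)
  expect_setequal(unique(co$phenotype_group), c("GEFS+", "GGE", "DEE", "FE"))
  expect_identical(as.integer(table(co$phenotype_group)[c("GEFS+", "GGE", "DEE", "FE")]),
                   c(4L, 2L, 9L, 2L))
  # truncating-only GEFS+ group, as in the source cohort
  gefs <- cohort_variants(co[co$phenotype_group == "GEFS+", ])
  expect_true(all(vapply(gefs, `[[`, character(1), "vclass") %in%
                    c("frameshift", "stop_gain")))
})

test_that("variant line lists parse with comments and blanks skipped", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "p.Val88Phe", "", "p.Lys93*"), f)
  vs <- read_variant_lines(f, "STX1B")
  expect_length(vs, 2L)
  expect_identical(vs[[2]]$vclass, "stop_gain")
})
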