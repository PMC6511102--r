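test_that("burden tables count distinct missense positions and match a linear scan", {
  dm <- domain_map("ROI", 1, 20, 20)
  pop <- position_set(c(2, 5, 9), 20)
  pat <- lapply(c("p.Ala3Val", "p.Ala7Val", "p.Ala7Gly", "p.Lys9*"),
                parse_hgvs_p, gene = "G")
  bt <- build_burden_table(pat, pop, dm, "ROI")
  # two distinct missense positions (3, 7); the stop-gain is excluded
  expect_identical(bt$a_in, 2L)
  expect_identical(bt$a_out, 0L)
  expect_identical(bt$b_in, 3L)
  expect_identical(bt$b_out, 0L)

  expect_identical(build_burden_table(list(), pop, dm, "ROI")$a_in, 0L)

  set.seed(19)
  for (rep in 1:10) {
    L <- 60L
    dm2 <- domain_map("R", 15, 40, L)
    pop_pos <- sample(L, 25)
    pat_pos <- sample(L, 8)
    pat2 <- lapply(pat_pos, function(p) parse_hgvs_p(sprintf("p.Ala%dVal", p), "G"))
    bt2 <- build_burden_table(pat2, position_set(pop_pos, L), dm2, "R")
    in_r <- function(p) p >= 15 & p <= 40
    expect_identical(bt2$a_in, sum(in_r(unique(pat_pos))))
    expect_identical(bt2$a_out, sum(!in_r(unique(pat_pos))))
    expect_identical(bt2$b_in, sum(in_r(unique(pop_pos))))
    expect_identical(bt2$b_out, sum(!in_r(unique(pop_pos))))
  }

  expect_error(build_burden_table(pat, pop, dm, "missing_region"),
               class = "parazburden_config_error")
})

test_that("Fisher exact p matches hand values, the enumeration oracle and fisher.test", {
  # identical proportions: no association
  expect_equal(fisher_exact_2x2(list(a_in = 1, a_out = 9, b_in = 10, b_out = 90))$p_exact, 1)
  # maximally separated 5/0 vs 0/5: 2 of the 252 equally-likely tables
  r <- fisher_exact_2x2(list(a_in = 5, a_out = 0, b_in = 0, b_out = 5))
  expect_equal(r$p_exact, 2 / 252)
  expect_identical(r$odds_ratio, Inf)

  set.seed(23)
  for (rep in 1:200) {
    t <- list(a_in = sample(0:15, 1), a_out = sample(0:15, 1),
              b_in = sample(0:15, 1), b_out = sample(0:15, 1))
    mine <- fisher_exact_2x2(t)
    expect_equal(mine$p_exact,
                 oracle_fisher_p(t$a_in, t$a_out, t$b_in, t$b_out),
                 tolerance = 1e-12)
    if (!mine$degenerate) {
      ref <- stats::fisher.test(matrix(unlist(t), 2, byrow = TRUE))$p.value
      expect_equal(mine$p_exact, min(1, ref), tolerance = 1e-9)
    }
  }
})

test_that("degenerate margins give p = 1 with a flag, and the sample odds ratio is as defined", {
  r <- fisher_exact_2x2(list(a_in = 0, a_out = 0, b_in = 3, b_out = 7))
  expect_identical(r$p_exact, 1)
  expect_true(r$degenerate)

  r2 <- fisher_exact_2x2(list(a_in = 6, a_out = 2, b_in = 3, b_out = 9))
  expect_equal(r2$odds_ratio, (6 * 9) / (2 * 3))
  expect_true(is.nan(fisher_exact_2x2(list(a_in = 0, a_out = 2, b_in = 0, b_out = 9))$odds_ratio))
})

test_that("swapping cohort labels inverts the odds ratio and preserves p", {
  set.seed(29)
  for (rep in 1:20) {
    t <- list(a_in = sample(1:12, 1), a_out = sample(1:12, 1),
              b_in = sample(1:12, 1), b_out = sample(1:12, 1))
    fwd <- fisher_exact_2x2(t)
    rev <- fisher_exact_2x2(list(a_in = t$b_in, a_out = t$b_out,
                                 b_in = t$a_in, b_out = t$a_out))
    expect_equal(fwd$p_exact, rev$p_exact, tolerance = 1e-12)
    expect_equal(fwd$odds_ratio, 1 / rev$odds_ratio, tolerance = 1e-12)
  }
})

test_that("permutation p-values hit their boundary cases and reproduce under a seed", {
  dm <- domain_map("whole", 1, 50, 50)
  r <- permutation_enrichment(6, 6, dm, "whole", n_perm = 99, seed = 4)
  expect_identical(r$p_perm, 1)   # region = whole protein

  dm2 <- domain_map("R", 10, 20, 50)
  expect_identical(
    permutation_enrichment(0, 6, dm2, "R", n_perm = 99, seed = 4)$p_perm, 1
  )

  a <- permutation_enrichment(4, 6, dm2, "R", n_perm = 999, seed = 42)
  b <- permutation_enrichment(4, 6, dm2, "R", n_perm = 999, seed = 42)
  expect_identical(a$p_perm, b$p_perm)
  expect_gte(a$p_perm, 1 / 1000)

  expect_error(permutation_enrichment(1, 51, dm2, "R", n_perm = 99, seed = 1),
               class = "parazburden_param_error")
  expect_error(permutation_enrichment(1, 5, dm2, "R", n_perm = 50, seed = 1),
               class = "parazburden_param_error")
})

test_that("permutation p converges to the exhaustive hypergeometric null", {
  # fixed instance: 6 draws from 50 positions, region of 10, observed 3
  dm <- domain_map("R", 1, 10, 50)
  p_true <- stats::phyper(2, 10, 40, 6, lower.tail = FALSE)
  for (cfg in list(c(99, 0.15), c(999, 0.05), c(9999, 0.015))) {
    p_hat <- permutation_enrichment(3, 6, dm, "R", n_perm = cfg[1], seed = 7)$p_perm
    expect_lt(abs(p_hat - p_true), cfg[2])
  }
})

test_that("rank-sum comparison: identical samples, the 2v2 extreme and branch agreement", {
  same <- c(0.1, 0.5, 0.9)
  expect_equal(compare_z_distributions(same, same)$p, 1)

  r <- compare_z_distributions(c(1, 2), c(3, 4))
  expect_identical(r$method, "exact")
  expect_equal(r$p, 2 / 6)

  expect_error(compare_z_distributions(numeric(0), c(1)),
               class = "parazburden_param_error")

  # exact vs normal approximation within 0.02 on balanced samples of 6
  set.seed(37)
  for (rep in 1:10) {
    x <- rnorm(6)
    y <- rnorm(6, mean = 0.5)
    pe <- compare_z_distributions(x, y, method = "exact")$p
    pn <- compare_z_distributions(x, y, method = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("rank-sum comparison agrees with wilcox.test on tie-free data", {
  set.seed(41)
  for (rep in 1:10) {
    x <- rnorm(8)
    y <- rnorm(15, mean = 0.3)
    mine <- compare_z_distributions(x, y, method = "normal")$p
    ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
  # and the exact branch against wilcox.test's exact branch (no ties, small n)
  for (rep in 1:10) {
    x <- rnorm(5)
    y <- rnorm(6)
    mine <- compare_z_distributions(x, y, method = "exact")$p
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("the combined enrichment test wires the pieces together", {
  ch <- gen_cohort(cohort_spec(seed = 3))
  dm <- domain_map("ROI", 180, 251, 288)
  pat <- lapply(ch$patient_positions,
                function(p) parse_hgvs_p(sprintf("p.Ala%dVal", p), "G"))
  res <- enrichment_test(pat, ch$population, dm, "ROI", n_perm = 199, seed = 5)
  expect_s3_class(res, "enrichment_result")
  expect_identical(res$table$a_in + res$table$a_out, 8L)
  expect_identical(res$table$b_in + res$table$b_out, 120L)
  expect_true(res$p_exact > 0 && res$p_exact <= 1)
  expect_true(res$p_perm >= 1 / 200 && res$p_perm <= 1)

  expect_error(enrichment_test(list(), ch$population, dm, "ROI"),
               class = "parazburden_param_error")
})
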