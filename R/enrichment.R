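#' Build a 2x2 regional burden table
#'
#' Partitions distinct missense residue positions of a patient cohort and
#' of a population background by membership in a named region. Only
#' missense variants enter the comparison: truncating variants and
#' whole-gene deletions act gene-wide (or have no residue coordinate) and
#' are excluded from both sides. Each distinct residue position counts
#' once per cohort, regardless of how many carriers or alleles hit it.
#'
#' @param patient List of `protein_variant` objects (non-missense entries
#'   are dropped automatically).
#' @param population A [position_set()] in residue space.
#' @param dm A [domain_map()] whose protein length matches `population$length`.
#' @param region Region name in `dm` (or `"other"`).
#' @return A `burden_table`: list with counts `a_in`, `a_out` (patient
#'   in/out of region) and `b_in`, `b_out` (population in/out), plus
#'   `region` and the distinct position vectors.
#' @export
build_burden_table <- function(patient, population, dm, region) {
  stopifnot(is.list(patient), inherits(population, "position_set"),
            inherits(dm, "domain_map"))
  L <- attr(dm, "protein_length")
  if (population$length != L) {
    stop_param_error("population position-set length does not match domain map")
  }
  region_idx <- region_residues(dm, region)  # errors for unknown region

  keep <- vapply(patient, function(v) {
    stopifnot(inherits(v, "protein_variant"))
    v$vclass == "missense"
  }, logical(1))
  pat_pos <- sort(unique(vapply(patient[keep], `[[`, integer(1), "position")))
  if (length(pat_pos) && (min(pat_pos) < 1L || max(pat_pos) > L)) {
    stop_param_error("patient residue position outside protein length")
  }
  pop_pos <- population$positions

  structure(
    list(
      a_in = sum(pat_pos %in% region_idx),
      a_out = sum(!pat_pos %in% region_idx),
      b_in = sum(pop_pos %in% region_idx),
      b_out = sum(!pop_pos %in% region_idx),
      region = region,
      patient_positions = pat_pos,
      population_positions = pop_pos
    ),
    class = "burden_table"
  )
}

#' @export
print.burden_table <- function(x, ...) {
  cat(sprintf("Burden table (region %s):\n", x$region))
  m <- matrix(c(x$a_in, x$a_out, x$b_in, x$b_out), nrow = 2, byrow = TRUE,
              dimnames = list(c("patient", "population"), c("in", "out")))
  print(m)
  invisible(x)
}

#' Fisher's exact test on a 2x2 burden table
#'
#' Two-sided p-value by probability ordering: conditioning on both
#' margins, the hypergeometric probabilities of all tables as or less
#' probable than the observed one are summed (the classic two-sided
#' convention for 2x2 tables). The odds ratio is the sample odds ratio
#' `(a_in * b_out) / (a_out * b_in)` — `Inf` when the denominator is 0 —
#' not the conditional maximum-likelihood estimate.
#'
#' @param t A [build_burden_table()] result, or any list with fields
#'   `a_in`, `a_out`, `b_in`, `b_out`.
#' @return List with `odds_ratio`, `p_exact` and `degenerate` (`TRUE`
#'   when a margin is zero, in which case `p_exact = 1` by convention).
#' @export
fisher_exact_2x2 <- function(t) {
  a <- as.integer(t$a_in); b <- as.integer(t$a_out)
  c_ <- as.integer(t$b_in); d <- as.integer(t$b_out)
  if (any(c(a, b, c_, d) < 0L)) {
    stop_param_error("burden table counts must be non-negative")
  }
  or <- if (b * c_ == 0L) {
    if (a * d == 0L) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }

  m <- a + b          # patient margin
  n <- c_ + d         # population margin
  k <- a + c_         # in-region margin
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) {
    return(list(odds_ratio = or, p_exact = 1, degenerate = TRUE))
  }
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p_exact = min(1, p), degenerate = FALSE)
}

#' Permutation test of regional enrichment
#'
#' Null model: the patient's distinct missense positions are an
#' unordered uniform draw (without replacement) from all residue
#' positions `1..L`. The statistic is the number of patient positions
#' inside the region; the p-value uses the add-one estimator
#' `(1 + #[null >= observed]) / (n_perm + 1)`, so it can never be 0 and
#' is never smaller than `1 / (n_perm + 1)`.
#'
#' All replicates are drawn from R's Mersenne-Twister stream seeded once
#' with `seed`, so a run is exactly reproducible from (seed, n_perm).
#'
#' @param observed_in Observed count of patient positions inside the region.
#' @param patient_n Number of distinct patient positions.
#' @param dm A [domain_map()] providing the protein length.
#' @param region Region name in `dm` (or `"other"`).
#' @param n_perm Number of permutation replicates (>= 99).
#' @param seed Integer seed.
#' @return List with `p_perm`, `observed_in`, `n_perm`, `seed`.
#' @export
permutation_enrichment <- function(observed_in, patient_n, dm, region,
                                   n_perm = 999L, seed = 1L) {
  stopifnot(inherits(dm, "domain_map"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) {
    stop_param_error("n_perm must be at least 99")
  }
  L <- attr(dm, "protein_length")
  if (patient_n > L) {
    stop_param_error("patient_n exceeds protein length")
  }
  if (observed_in > patient_n) {
    stop_param_error("observed_in cannot exceed patient_n")
  }
  region_idx <- region_residues(dm, region)
  in_region <- logical(L)
  in_region[region_idx] <- TRUE

  null_stat <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      sum(in_region[sample.int(L, patient_n)])
    }, numeric(1))
  })
  list(
    p_perm = (1 + sum(null_stat >= observed_in)) / (n_perm + 1),
    observed_in = observed_in,
    n_perm = n_perm,
    seed = as.integer(seed)
  )
}

#' Compare para_zscore distributions between two variant sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with midrank handling
#' of ties. For small problems (`n_patient + n_population <= 12`) the
#' null distribution of the rank-sum is enumerated exactly over all
#' assignments of the pooled midranks; otherwise the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction is used.
#' The two-sided p is the null probability of a rank-sum at least as far
#' from its expectation as the observed one.
#'
#' @param patient_z Numeric vector of para_zscores at patient variant
#'   positions.
#' @param population_z Numeric vector of para_zscores at population
#'   variant positions.
#' @param method `"auto"` (size-based branch selection, the default),
#'   `"exact"` or `"normal"`.
#' @return A `z_comparison` list: `statistic` (patient rank-sum `W`),
#'   `p` (two-sided), `n_patient`, `n_population`, `method`.
#' @export
compare_z_distributions <- function(patient_z, population_z,
                                    method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  patient_z <- as.numeric(patient_z)
  population_z <- as.numeric(population_z)
  n1 <- length(patient_z)
  n2 <- length(population_z)
  if (n1 == 0L || n2 == 0L) {
    stop_param_error("both samples must be non-empty")
  }
  pooled <- c(patient_z, population_z)
  r <- rank(pooled)            # midranks for ties
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2

  if (method == "auto") {
    method <- if (n1 + n2 <= 12L) "exact" else "normal"
  }
  if (method == "exact") {
    combs <- utils::combn(n1 + n2, n1)
    w_null <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(w_null - mu) >= abs(w - mu) - 1e-12)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
      sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      p <- 1   # every pooled value tied: no evidence either way
    } else {
      zstat <- (abs(w - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(zstat, 0)))
    }
  }
  structure(
    list(statistic = w, p = p, n_patient = n1, n_population = n2, method = method),
    class = "z_comparison"
  )
}

#' @export
print.z_comparison <- function(x, ...) {
  cat(sprintf("Rank-sum comparison (%s): W = %g, p = %.4g (n = %d vs %d)\n",
              x$method, x$statistic, x$p, x$n_patient, x$n_population))
  invisible(x)
}

#' Full regional enrichment analysis
#'
#' Convenience wrapper running [build_burden_table()],
#' [fisher_exact_2x2()] and [permutation_enrichment()] on one cohort.
#'
#' @inheritParams build_burden_table
#' @param n_perm Permutation replicates.
#' @param seed Integer seed for the permutation stream.
#' @return An `enrichment_result`: list with `table`, `odds_ratio`,
#'   `p_exact`, `p_perm`, `n_perm`, `seed`, `region`.
#' @export
enrichment_test <- function(patient, population, dm, region,
                            n_perm = 999L, seed = 1L) {
  bt <- build_burden_table(patient, population, dm, region)
  if (bt$a_in + bt$a_out < 1L || bt$b_in + bt$b_out < 1L) {
    stop_param_error("both cohorts need at least one distinct missense position")
  }
  fe <- fisher_exact_2x2(bt)
  pe <- permutation_enrichment(bt$a_in, bt$a_in + bt$a_out, dm, region,
                               n_perm = n_perm, seed = seed)
  structure(
    list(
      table = bt,
      odds_ratio = fe$odds_ratio,
      p_exact = fe$p_exact,
      degenerate = fe$degenerate,
      p_perm = pe$p_perm,
      n_perm = pe$n_perm,
      seed = pe$seed,
      region = region
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment in %s: patient %d/%d in-region vs population %d/%d\n  OR = %.3g, Fisher p = %.4g, permutation p = %.4g (n_perm = %d, seed = %d)\n",
    x$region, x$table$a_in, x$table$a_in + x$table$a_out,
    x$table$b_in, x$table$b_in + x$table$b_out,
    x$odds_ratio, x$p_exact, x$p_perm, x$n_perm, x$seed
  ))
  invisible(x)
}
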