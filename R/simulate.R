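# Synthetic-data generators. These define the study conditions under
# which the pipeline is validated: a paralog family with a planted
# high-conservation block (emulating a 7-member syntaxin-like family with
# a SNARE-motif-like constrained region) and a patient/population variant
# cohort with a planted regional enrichment.

#' Specification of a synthetic paralog family
#'
#' @param n_members Number of family members (>= 2; default 7, the size
#'   of the human syntaxin family used as the template).
#' @param length Protein length in residues (default 288, syntaxin-1B).
#' @param conserved_block Two-element vector `(start, end)` of the planted
#'   high-conservation block (default 180-250, a SNARE-motif-like block).
#' @param p_sub_conserved Per-column substitution probability inside the
#'   block (default 0.05).
#' @param p_sub_background Substitution probability outside the block
#'   (default 0.5); must exceed `p_sub_conserved`.
#' @param gap_rate Per-position gap probability outside the block
#'   (default 0.05; must be <= 0.3). Gaps are never placed inside the
#'   block, so block columns always map to focal-protein residues.
#' @param seed Integer seed.
#' @return A validated `family_spec` list.
#' @export
family_spec <- function(n_members = 7L, length = 288L,
                        conserved_block = c(180L, 250L),
                        p_sub_conserved = 0.05, p_sub_background = 0.5,
                        gap_rate = 0.05, seed = 1L) {
  spec <- list(
    n_members = as.integer(n_members), length = as.integer(length),
    conserved_block = as.integer(conserved_block),
    p_sub_conserved = p_sub_conserved, p_sub_background = p_sub_background,
    gap_rate = gap_rate, seed = as.integer(seed)
  )
  if (spec$n_members < 2L) {
    stop_param_error("n_members must be >= 2")
  }
  if (length(spec$conserved_block) != 2L ||
      spec$conserved_block[1] < 1L ||
      spec$conserved_block[2] > spec$length ||
      spec$conserved_block[1] > spec$conserved_block[2]) {
    stop_param_error("conserved_block must lie within [1, length]")
  }
  if (!(0 <= p_sub_conserved && p_sub_conserved < p_sub_background &&
        p_sub_background <= 1)) {
    stop_param_error("need 0 <= p_sub_conserved < p_sub_background <= 1")
  }
  if (gap_rate < 0 || gap_rate > 0.3) {
    stop_param_error("gap_rate must be in [0, 0.3]")
  }
  structure(spec, class = "family_spec")
}

#' Generate a synthetic paralog family
#'
#' Draws an ancestor sequence uniformly over the 20 amino acids, then
#' derives each member independently: every column mutates to a uniform
#' choice among the 19 alternative residues with the block-dependent
#' substitution probability, and positions outside the conserved block
#' are additionally gapped with probability `gap_rate`. Columns that
#' would become all-gap keep one member ungapped. The alignment is
#' deterministic given `spec$seed`.
#'
#' @param spec A [family_spec()].
#' @return A [paralog_alignment()] with members `P1..Pn`; `P1` is the
#'   conventional focal protein.
#' @export
gen_paralog_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  aa <- names(AA_CLASS)
  L <- spec$length
  block <- seq.int(spec$conserved_block[1], spec$conserved_block[2])
  p_sub <- rep(spec$p_sub_background, L)
  p_sub[block] <- spec$p_sub_conserved
  gap_ok <- rep(TRUE, L)
  gap_ok[block] <- FALSE

  mat <- withr::with_seed(spec$seed, {
    ancestor <- sample(aa, L, replace = TRUE)
    m <- matrix("", nrow = spec$n_members, ncol = L)
    for (i in seq_len(spec$n_members)) {
      s <- ancestor
      mut <- stats::runif(L) < p_sub
      if (any(mut)) {
        # uniform over the 19 non-ancestral residues
        s[mut] <- vapply(s[mut], function(x) sample(setdiff(aa, x), 1L), character(1))
      }
      gap <- gap_ok & stats::runif(L) < spec$gap_rate
      s[gap] <- "-"
      m[i, ] <- s
    }
    all_gap <- colSums(m != "-") == 0L
    for (j in which(all_gap)) {
      m[sample.int(spec$n_members, 1L), j] <- ancestor[j]
    }
    m
  })
  paralog_alignment(paste0("P", seq_len(spec$n_members)), apply(mat, 1L, paste, collapse = ""))
}

#' Specification of a synthetic variant cohort
#'
#' Defaults emulate the study conditions of a constrained ~300-residue
#' neuronal protein: 8 distinct patient missense positions, 120 distinct
#' population missense positions (the order of magnitude of per-gene
#' distinct missense positions in large population databases), and a
#' region of interest covering 25% of the protein in which patient
#' variants arise at 5x the per-residue rate.
#'
#' @param n_patient Number of distinct patient positions (default 8).
#' @param n_population Number of distinct population positions (default
#'   120; must be <= `protein_length`).
#' @param protein_length Protein length in residues (default 288).
#' @param region Two-element `(start, end)` region of interest (default
#'   180-251, i.e. 72/288 = 25% of the protein).
#' @param rate_ratio Relative per-residue patient variant rate inside the
#'   region (>= 1; default 5).
#' @param seed Integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patient = 8L, n_population = 120L,
                        protein_length = 288L, region = c(180L, 251L),
                        rate_ratio = 5, seed = 1L) {
  spec <- list(
    n_patient = as.integer(n_patient), n_population = as.integer(n_population),
    protein_length = as.integer(protein_length), region = as.integer(region),
    rate_ratio = rate_ratio, seed = as.integer(seed)
  )
  if (spec$n_patient < 1L || spec$n_patient > spec$protein_length) {
    stop_param_error("n_patient must be in [1, protein_length]")
  }
  if (spec$n_population < 1L || spec$n_population > spec$protein_length) {
    stop_param_error("n_population must be in [1, protein_length]")
  }
  if (length(spec$region) != 2L || spec$region[1] < 1L ||
      spec$region[2] > spec$protein_length || spec$region[1] > spec$region[2]) {
    stop_param_error("region must lie within [1, protein_length]")
  }
  if (is.na(rate_ratio) || (is.finite(rate_ratio) && rate_ratio < 1) ||
      rate_ratio < 0) {
    stop_param_error("rate_ratio must be >= 1 (or Inf)")
  }
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic patient/population variant cohort
#'
#' Population positions are a uniform draw without replacement from
#' `1..protein_length`. Patient positions are drawn without replacement
#' with per-residue weight `rate_ratio` inside the region and 1 outside
#' (`rate_ratio = Inf` puts every patient position inside the region).
#' Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `patient_positions` (sorted integer vector),
#'   `population` (a residue-space [position_set()]) and `region`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec$protein_length
  in_region <- seq_len(L) >= spec$region[1] & seq_len(L) <= spec$region[2]
  w <- rep(1, L)
  if (is.finite(spec$rate_ratio)) {
    w[in_region] <- spec$rate_ratio
  } else {
    w[] <- 0
    w[in_region] <- 1
    if (sum(in_region) < spec$n_patient) {
      stop_param_error("region too small to hold all patient positions at rate_ratio = Inf")
    }
  }
  withr::with_seed(spec$seed, {
    patient <- sort(sample.int(L, spec$n_patient, prob = w))
    population <- sort(sample.int(L, spec$n_population))
    list(
      patient_positions = patient,
      population = position_set(population, L),
      region = spec$region
    )
  })
}

#' Write a synthetic cohort as TSV files
#'
#' @param cohort A [gen_cohort()] result.
#' @param patient_path,population_path Output paths. Each file has a
#'   single `position` column (1-based residues).
#' @export
write_cohort_tsv <- function(cohort, patient_path, population_path) {
  utils::write.table(data.frame(position = cohort$patient_positions),
                     patient_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(position = cohort$population$positions),
                     population_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(patient_path, population_path))
}
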