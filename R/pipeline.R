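#' Assemble a pipeline run configuration
#'
#' @param variants_tsv Cohort TSV (see [read_cohort_tsv()]).
#' @param alignment_fasta Aligned FASTA of the paralog family.
#' @param population_tsv TSV of population variant positions with a
#'   `position` column.
#' @param domains_yaml Domain-map YAML (see [read_domain_map()]).
#' @param focal_protein Member id of the protein of interest in the
#'   alignment.
#' @param population_space `"residue"` (default) or `"nucleotide"`; in
#'   nucleotide space the positions are interpreted on the coding
#'   sequence (length `3 * protein_length`) and drive the density
#'   profile, then collapse to distinct residues for the burden test. In
#'   residue space the density profile is computed on the residue grid
#'   directly (window in residue units).
#' @param window Sliding-window length for the density profile (default
#'   10 nucleotides).
#' @param scorer Conservation scorer name (see [column_conservation()]).
#' @param region Region of interest for the enrichment test.
#' @param n_perm Permutation replicates (default 999).
#' @param seed Integer seed (default 1).
#' @param out_dir Output directory; created if missing.
#' @return A validated `run_config` list.
#' @export
run_config <- function(variants_tsv, alignment_fasta, population_tsv,
                       domains_yaml, focal_protein,
                       population_space = c("residue", "nucleotide"),
                       window = 10L, scorer = "identity_fraction",
                       region = "SNARE", n_perm = 999L, seed = 1L,
                       out_dir = tempfile("parazburden_run_")) {
  population_space <- match.arg(population_space)
  for (p in c(variants_tsv, alignment_fasta, population_tsv, domains_yaml)) {
    if (!file.exists(p)) {
      stop_config_error(sprintf("input file does not exist: %s", p))
    }
  }
  structure(
    list(
      variants_tsv = variants_tsv, alignment_fasta = alignment_fasta,
      population_tsv = population_tsv, domains_yaml = domains_yaml,
      focal_protein = focal_protein, population_space = population_space,
      window = as.integer(window), scorer = scorer, region = region,
      n_perm = as.integer(n_perm), seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|~)", p)) file.path(base, p) else p
  }
  run_config(
    variants_tsv = resolve(cfg$variants_tsv),
    alignment_fasta = resolve(cfg$alignment_fasta),
    population_tsv = resolve(cfg$population_tsv),
    domains_yaml = resolve(cfg$domains_yaml),
    focal_protein = cfg$focal_protein,
    population_space = cfg$population_space %||% "residue",
    window = cfg$window %||% 10L,
    scorer = cfg$scorer %||% "identity_fraction",
    region = cfg$region %||% "SNARE",
    n_perm = cfg$n_perm %||% 999L,
    seed = cfg$seed %||% 1L,
    out_dir = resolve(cfg$out_dir) %||% tempfile("parazburden_run_")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full variant-to-enrichment pipeline
#'
#' Executes the stages in dependency order: parse and classify the
#' cohort variants; sliding-window density of the population positions
#' (projected to residues when the input is in nucleotide space); paralog
#' conservation and para_zscores for the focal protein; regional burden
#' (Fisher exact + permutation) of patient vs population missense
#' positions; rank-sum comparison of para_zscores at patient vs
#' population variant sites. Writes TSV outputs and a plain-text report
#' to `cfg$out_dir`; identical config and seed reproduce the report
#' byte-for-byte.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` list (invisibly): `class_counts`,
#'   `region_density`, `region_z`, `enrichment`, `z_comparison`,
#'   `crosstab`, `config`, `version`, and `paths` of the written files.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[1/5] variants: %s", cfg$variants_tsv)
  cohort <- read_cohort_tsv(cfg$variants_tsv)
  variants <- cohort_variants(cohort)
  counts <- classify_counts(variants)
  dm <- read_domain_map(cfg$domains_yaml)
  L <- attr(dm, "protein_length")

  say("[2/5] density: %s (%s space, window %d)",
      cfg$population_tsv, cfg$population_space, cfg$window)
  if (cfg$population_space == "nucleotide") {
    ps_nt <- read_position_set(cfg$population_tsv, 3L * L)
    dp_res <- project_to_residues(sliding_density(ps_nt, cfg$window))
    pop_res <- positions_to_residues(ps_nt)
  } else {
    pop_res <- read_position_set(cfg$population_tsv, L)
    dp_res <- sliding_density(pop_res, cfg$window)
    attr(dp_res, "space") <- "residue"
  }
  region_names <- c(dm$name, "other")
  region_density <- vapply(region_names, function(r) {
    region_mean_density(dp_res, dm, r)
  }, numeric(1))

  say("[3/5] para_zscore: %s (focal %s, scorer %s)",
      cfg$alignment_fasta, cfg$focal_protein, cfg$scorer)
  aln <- read_paralog_alignment(cfg$alignment_fasta)
  cp <- column_conservation(aln, cfg$scorer)
  pz <- para_zscore(cp, aln, cfg$focal_protein)
  if (length(pz$z) != L) {
    stop_config_error(sprintf(
      "focal protein has %d residues but domain map declares %d",
      length(pz$z), L
    ))
  }
  region_z <- t(vapply(region_names, function(r) {
    region_z_summary(pz, dm, r)
  }, numeric(5)))

  say("[4/5] enrichment: region %s, n_perm %d, seed %d",
      cfg$region, cfg$n_perm, cfg$seed)
  enr <- enrichment_test(variants, pop_res, dm, cfg$region,
                         n_perm = cfg$n_perm, seed = cfg$seed)

  say("[5/5] para_zscore comparison at variant sites")
  pat_pos <- enr$table$patient_positions
  zcmp <- compare_z_distributions(pz$z[pat_pos], pz$z[pop_res$positions])
  crosstab <- crosstab_genotype_phenotype(cohort, dm, cfg$region)

  report <- structure(
    list(
      class_counts = counts,
      region_density = region_density,
      region_z = region_z,
      enrichment = enr,
      z_comparison = zcmp,
      crosstab = crosstab,
      config = cfg,
      version = as.character(utils::packageVersion("parazburden"))
    ),
    class = "run_report"
  )
  report$paths <- write_run_outputs(report, pz, aln, dp_res)
  invisible(report)
}

write_run_outputs <- function(report, pz, aln, dp_res) {
  out <- report$config$out_dir
  paths <- c(
    density = file.path(out, "density_residue.tsv"),
    para_z = file.path(out, "para_z.tsv"),
    report = file.path(out, "report.txt")
  )
  write_density_tsv(dp_res, paths["density"])
  utils::write.table(para_z_table(pz, aln), paths["para_z"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(format_run_report(report), paths["report"])
  paths
}

#' Render a run report as text lines
#'
#' The body is a deterministic function of the inputs, configuration and
#' seed — two runs with the same config produce identical lines.
#'
#' @param report A [run_all()] result.
#' @return Character vector of report lines.
#' @export
format_run_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  cfg <- report$config
  enr <- report$enrichment
  num <- function(x) formatC(x, digits = 6, format = "g")
  c(
    sprintf("parazburden run report (package version %s)", report$version),
    "",
    "[config]",
    sprintf("  variants:   %s", basename(cfg$variants_tsv)),
    sprintf("  alignment:  %s (focal %s)", basename(cfg$alignment_fasta), cfg$focal_protein),
    sprintf("  population: %s (%s space)", basename(cfg$population_tsv), cfg$population_space),
    sprintf("  domains:    %s", basename(cfg$domains_yaml)),
    sprintf("  window=%d scorer=%s region=%s n_perm=%d seed=%d",
            cfg$window, cfg$scorer, cfg$region, cfg$n_perm, cfg$seed),
    "",
    "[variant classes]",
    sprintf("  %s: %d", names(report$class_counts), report$class_counts),
    "",
    "[region mean density]",
    sprintf("  %s: %s", names(report$region_density), num(report$region_density)),
    "",
    "[region para_zscore mean (q25/median/q75, n)]",
    sprintf("  %s: %s (%s/%s/%s, n=%d)",
            rownames(report$region_z), num(report$region_z[, "mean"]),
            num(report$region_z[, "q25"]), num(report$region_z[, "median"]),
            num(report$region_z[, "q75"]), as.integer(report$region_z[, "n"])),
    "",
    sprintf("[enrichment in %s]", enr$region),
    sprintf("  patient in/out: %d/%d; population in/out: %d/%d",
            enr$table$a_in, enr$table$a_out, enr$table$b_in, enr$table$b_out),
    sprintf("  odds_ratio=%s p_exact=%s p_perm=%s (n_perm=%d, seed=%d)",
            num(enr$odds_ratio), num(enr$p_exact), num(enr$p_perm),
            enr$n_perm, enr$seed),
    "",
    "[para_zscore comparison at variant sites]",
    sprintf("  W=%s p=%s (%s; n=%d vs %d)",
            num(report$z_comparison$statistic), num(report$z_comparison$p),
            report$z_comparison$method, report$z_comparison$n_patient,
            report$z_comparison$n_population),
    "",
    "[genotype-phenotype crosstab]",
    sprintf("  %-6s %s", "", paste(sprintf("%-20s", colnames(report$crosstab)), collapse = " ")),
    sprintf("  %-6s %s", rownames(report$crosstab),
            apply(report$crosstab, 1L, function(r) paste(sprintf("%-20d", r), collapse = " ")))
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_run_report(x), sep = "\n")
  invisible(x)
}
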