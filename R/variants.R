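#' Parse a protein-level variant in HGVS p. notation
#'
#' Supports the three protein-level consequence classes that occur in
#' monogenic epilepsy variant inventories — missense (`p.Val88Phe`),
#' stop-gain (`p.Lys93*`, also `p.Lys93Ter`) and frameshift
#' (`p.Ser10Alafs*7`) — plus a whole-gene deletion token for structural
#' deletions that remove the entire coding sequence and therefore have no
#' residue coordinate. Both one-letter (`p.V88F`) and three-letter residue
#' codes are accepted; the canonical form produced by [format_hgvs_p()]
#' always uses three-letter codes.
#'
#' @param s The variant string. Either an HGVS p. expression starting with
#'   `"p."` or one of the whole-gene-deletion tokens
#'   `"whole_gene_deletion"` / `"deletion"` (case-insensitive).
#' @param gene Gene symbol the variant belongs to, e.g. `"STX1B"`.
#' @return A `protein_variant` object: a list with fields `gene`, `hgvs_p`
#'   (the input as written), `position` (1-based residue index, `NA` for
#'   whole-gene deletion), `ref_aa`, `alt_aa` (three-letter; `"Ter"` for a
#'   stop), `vclass` (one of `missense`, `stop_gain`, `frameshift`,
#'   `whole_gene_deletion`) and `fs_ter_offset` (frameshift only: distance
#'   in codons to the new termination codon).
#' @examples
#' parse_hgvs_p("p.Val88Phe", "STX1B")
#' parse_hgvs_p("p.K93*", "STX1B")
#' parse_hgvs_p("p.Ser10Alafs*7", "STX1B")
#' @seealso [format_hgvs_p()], [classify_counts()], [assign_domain()]
#' @export
parse_hgvs_p <- function(s, gene) {
  stopifnot(is.character(s), length(s) == 1L, is.character(gene), length(gene) == 1L)
  raw <- trimws(s)

  if (tolower(raw) %in% c("whole_gene_deletion", "deletion")) {
    return(new_protein_variant(
      gene = gene, hgvs_p = raw, position = NA_integer_,
      ref_aa = NA_character_, alt_aa = NA_character_,
      vclass = "whole_gene_deletion", fs_ter_offset = NA_integer_
    ))
  }
  if (!startsWith(raw, "p.")) {
    stop_parse_error(sprintf(
      "'%s' does not start with 'p.' and is not a whole-gene-deletion token", raw
    ))
  }
  body <- substr(raw, 3L, nchar(raw))
  aa_tok <- "(\\*|Ter|[A-Za-z]{3}|[A-Za-z])"

  m <- regmatches(body, regexec(paste0("^", aa_tok, "([0-9]+)", aa_tok, "fs\\*([0-9]+)$"), body))[[1]]
  if (length(m)) {
    ref <- normalize_aa(m[2], "reference residue")
    alt <- normalize_aa(m[4], "frameshift first residue")
    if (identical(ref, TER_THREE)) {
      stop_parse_error(sprintf("'%s': frameshift reference residue cannot be a stop", raw))
    }
    return(new_protein_variant(
      gene = gene, hgvs_p = raw, position = as.integer(m[3]),
      ref_aa = ref, alt_aa = alt, vclass = "frameshift",
      fs_ter_offset = as.integer(m[5])
    ))
  }

  m <- regmatches(body, regexec(paste0("^", aa_tok, "([0-9]+)(\\*|Ter)$"), body))[[1]]
  if (length(m)) {
    ref <- normalize_aa(m[2], "reference residue")
    if (identical(ref, TER_THREE)) {
      stop_parse_error(sprintf("'%s': reference residue cannot be a stop", raw))
    }
    return(new_protein_variant(
      gene = gene, hgvs_p = raw, position = as.integer(m[3]),
      ref_aa = ref, alt_aa = TER_THREE, vclass = "stop_gain",
      fs_ter_offset = NA_integer_
    ))
  }

  m <- regmatches(body, regexec(paste0("^", aa_tok, "([0-9]+)", aa_tok, "$"), body))[[1]]
  if (length(m)) {
    ref <- normalize_aa(m[2], "reference residue")
    alt <- normalize_aa(m[4], "alternate residue")
    if (identical(ref, TER_THREE)) {
      stop_parse_error(sprintf("'%s': reference residue cannot be a stop", raw))
    }
    if (identical(alt, TER_THREE)) {
      # caught above by the stop-gain branch; defensive
      stop_parse_error(sprintf("'%s': unexpected stop alternate", raw))
    }
    if (identical(ref, alt)) {
      stop_parse_error(sprintf(
        "'%s': reference and alternate residue are identical (synonymous changes are not modelled)", raw
      ))
    }
    return(new_protein_variant(
      gene = gene, hgvs_p = raw, position = as.integer(m[3]),
      ref_aa = ref, alt_aa = alt, vclass = "missense",
      fs_ter_offset = NA_integer_
    ))
  }

  stop_parse_error(sprintf("cannot parse HGVS p. expression '%s'", raw))
}

new_protein_variant <- function(gene, hgvs_p, position, ref_aa, alt_aa, vclass, fs_ter_offset) {
  if (vclass != "whole_gene_deletion" && (is.na(position) || position < 1L)) {
    stop_parse_error(sprintf("'%s': residue position must be >= 1", hgvs_p))
  }
  structure(
    list(
      gene = gene, hgvs_p = hgvs_p, position = position,
      ref_aa = ref_aa, alt_aa = alt_aa, vclass = vclass,
      fs_ter_offset = fs_ter_offset
    ),
    class = "protein_variant"
  )
}

VCLASSES <- c("missense", "stop_gain", "frameshift", "whole_gene_deletion")

#' Canonical HGVS p. form of a parsed variant
#'
#' Renders three-letter residue codes and `*` for the stop, so
#' `format_hgvs_p(parse_hgvs_p(s))` is the identity on canonical input and
#' canonicalises one-letter input (`p.V88F` becomes `p.Val88Phe`).
#'
#' @param v A [parse_hgvs_p()] result.
#' @return A single string; `"whole_gene_deletion"` for a gene deletion.
#' @export
format_hgvs_p <- function(v) {
  stopifnot(inherits(v, "protein_variant"))
  switch(v$vclass,
    whole_gene_deletion = "whole_gene_deletion",
    missense = sprintf("p.%s%d%s", v$ref_aa, v$position, v$alt_aa),
    stop_gain = sprintf("p.%s%d*", v$ref_aa, v$position),
    frameshift = sprintf("p.%s%d%sfs*%d", v$ref_aa, v$position, v$alt_aa, v$fs_ter_offset)
  )
}

#' @export
format.protein_variant <- function(x, ...) {
  sprintf("<%s %s (%s)>", x$gene, format_hgvs_p(x), x$vclass)
}

#' @export
print.protein_variant <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Tabulate variants by consequence class
#'
#' @param variants A list of `protein_variant` objects.
#' @return Named integer vector over the four consequence classes
#'   (`missense`, `stop_gain`, `frameshift`, `whole_gene_deletion`);
#'   classes absent from the input count 0 and the counts sum to
#'   `length(variants)`.
#' @examples
#' vs <- lapply(c("p.Val88Phe", "p.Lys93*"), parse_hgvs_p, gene = "STX1B")
#' classify_counts(vs)
#' @export
classify_counts <- function(variants) {
  stopifnot(is.list(variants))
  classes <- vapply(variants, function(v) {
    stopifnot(inherits(v, "protein_variant"))
    v$vclass
  }, character(1))
  counts <- table(factor(classes, levels = VCLASSES))
  out <- as.integer(counts)
  names(out) <- VCLASSES
  out
}

#' Locate a variant on a protein domain map
#'
#' @param v A `protein_variant`.
#' @param dm A [domain_map()].
#' @return The name of the interval containing the variant's residue
#'   position; `"other"` for residues not covered by any named interval;
#'   `"all"` for a whole-gene deletion.
#' @export
assign_domain <- function(v, dm) {
  stopifnot(inherits(v, "protein_variant"), inherits(dm, "domain_map"))
  if (v$vclass == "whole_gene_deletion") {
    return("all")
  }
  region_at_position(v$position, dm)
}

region_at_position <- function(position, dm) {
  L <- attr(dm, "protein_length")
  if (position < 1L || position > L) {
    stop_param_error(sprintf(
      "residue position %d outside protein length %d", position, L
    ))
  }
  hit <- which(dm$start <= position & position <= dm$end)
  if (length(hit)) dm$name[hit[1]] else "other"
}

#' Genotype-phenotype crosstab of a cohort
#'
#' Counts each family once, cross-classified by phenotype group and a
#' four-way genotype category: missense inside the region of interest,
#' missense elsewhere, truncating (frameshift and stop-gain pooled, both
#' predicting nonsense-mediated decay), and whole-gene deletion.
#'
#' @param cohort A cohort data frame as returned by [read_cohort_tsv()] or
#'   [stx1b_variants()]: columns `family_id`, `gene`, `hgvs_p`,
#'   `phenotype_group`, `inheritance`.
#' @param dm A [domain_map()].
#' @param region Name of the region of interest; must exist in `dm`.
#' @return An integer matrix, rows the four phenotype groups, columns
#'   `missense_in_<region>`, `missense_elsewhere`, `truncating`,
#'   `deletion`.
#' @export
crosstab_genotype_phenotype <- function(cohort, dm, region) {
  check_cohort(cohort)
  stopifnot(inherits(dm, "domain_map"))
  if (!region %in% dm$name) {
    stop_config_error(sprintf("region '%s' not in domain map", region))
  }
  cols <- c(paste0("missense_in_", region), "missense_elsewhere", "truncating", "deletion")
  tab <- matrix(0L, nrow = length(PHENOTYPE_GROUPS), ncol = length(cols),
                dimnames = list(PHENOTYPE_GROUPS, cols))
  if (!nrow(cohort)) {
    return(tab)
  }
  if (anyDuplicated(cohort$family_id)) {
    stop_config_error("family_id must be unique per cohort record")
  }
  for (i in seq_len(nrow(cohort))) {
    v <- parse_hgvs_p(cohort$hgvs_p[i], cohort$gene[i])
    cat_i <- switch(v$vclass,
      missense = if (assign_domain(v, dm) == region) cols[1] else cols[2],
      stop_gain = "truncating",
      frameshift = "truncating",
      whole_gene_deletion = "deletion"
    )
    tab[cohort$phenotype_group[i], cat_i] <- tab[cohort$phenotype_group[i], cat_i] + 1L
  }
  tab
}

PHENOTYPE_GROUPS <- c("GEFS+", "GGE", "DEE", "FE")
INHERITANCE_MODES <- c("de_novo", "inherited", "unknown")

check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("family_id", "gene", "hgvs_p", "phenotype_group", "inheritance")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop_config_error(paste("cohort table lacks columns:", paste(missing, collapse = ", ")))
  }
  bad_pg <- setdiff(unique(cohort$phenotype_group), PHENOTYPE_GROUPS)
  if (length(bad_pg)) {
    stop_config_error(paste("unknown phenotype group(s):", paste(bad_pg, collapse = ", ")))
  }
  bad_inh <- setdiff(unique(cohort$inheritance), INHERITANCE_MODES)
  if (length(bad_inh)) {
    stop_config_error(paste("unknown inheritance mode(s):", paste(bad_inh, collapse = ", ")))
  }
  invisible(cohort)
}

#' Read a cohort variant table
#'
#' @param path TSV with columns `gene`, `hgvs_p`, `family_id`,
#'   `phenotype_group` (GEFS+/GGE/DEE/FE) and `inheritance`
#'   (de_novo/inherited/unknown). All HGVS strings are parsed eagerly so a
#'   malformed row fails at load time.
#' @return The validated data frame.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  check_cohort(df)
  for (i in seq_len(nrow(df))) {
    parse_hgvs_p(df$hgvs_p[i], df$gene[i])
  }
  df
}

#' Read a plain list of HGVS p. strings
#'
#' @param path Text file, one HGVS p. expression per line; blank lines and
#'   lines starting with `#` are skipped.
#' @param gene Gene symbol applied to every variant.
#' @return A list of `protein_variant` objects.
#' @export
read_variant_lines <- function(path, gene) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_hgvs_p, gene = gene)
}

#' Parsed variants from a cohort table
#'
#' @param cohort A cohort data frame (see [read_cohort_tsv()]).
#' @return List of `protein_variant` objects, one per row.
#' @export
cohort_variants <- function(cohort) {
  check_cohort(cohort)
  lapply(seq_len(nrow(cohort)), function(i) parse_hgvs_p(cohort$hgvs_p[i], cohort$gene[i]))
}

#' The 17-variant STX1B study cohort
#'
#' The newly identified STX1B variants of the epilepsy genotype-phenotype
#' study shipped as a fixture: 8 missense, 5 frameshift, 3 stop-gain and 1
#' whole-gene deletion across 17 families, with phenotype-group
#' (GEFS+/GGE/DEE/FE) and inheritance annotations. Three family-to-variant
#' pairings not stated explicitly in the source are inferred from group
#' constraints and flagged in the file's comment header.
#'
#' @return Cohort data frame (see [read_cohort_tsv()]).
#' @export
stx1b_variants <- function() {
  read_cohort_tsv(system.file("extdata", "stx1b_variants.tsv", package = "parazburden"))
}
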