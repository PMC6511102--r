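#' Paralog-family multiple sequence alignment
#'
#' A gapped protein alignment of a paralog family (e.g. the 7-member
#' human syntaxin family). All members must have equal aligned length, the
#' gap character is `-`, and no retained column may be all-gap.
#'
#' @param ids Character vector of member identifiers (unique).
#' @param seqs Character vector of aligned sequences (upper-case amino
#'   acids and `-`), same order as `ids`.
#' @return A `paralog_alignment` object with fields `ids`, `seqs` (named
#'   by id), `n_columns` and `mat` (character matrix, members x columns).
#' @export
paralog_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) {
    stop_param_error("a paralog alignment needs at least 2 members")
  }
  if (anyDuplicated(ids)) {
    stop_param_error("member ids must be unique")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop_param_error("aligned sequences must all have the same length")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- !(mat %in% c(names(AA_CLASS), "-"))
  if (any(bad)) {
    stop_aa_error(paste(unique(mat[bad]), collapse = ","), "alignment symbol")
  }
  if (any(colSums(mat != "-") == 0L)) {
    stop_param_error("alignment contains an all-gap column")
  }
  structure(
    list(ids = ids, seqs = setNames(seqs, ids), n_columns = ncol(mat), mat = mat),
    class = "paralog_alignment"
  )
}

#' @export
print.paralog_alignment <- function(x, ...) {
  cat(sprintf("Paralog alignment: %d members x %d columns\n",
              length(x$ids), x$n_columns))
  invisible(x)
}

#' Read an aligned FASTA paralog family
#'
#' @param path Aligned FASTA (gap character `-`). Alignment construction
#'   is out of scope: this package consumes alignments produced by an
#'   external aligner.
#' @return A [paralog_alignment()].
#' @export
read_paralog_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  paralog_alignment(names(aa), as.character(aa))
}

#' Write a paralog alignment as aligned FASTA
#'
#' @param aln A [paralog_alignment()].
#' @param path Output path.
#' @export
write_paralog_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "paralog_alignment"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$seqs), path)
  invisible(path)
}

CONSERVATION_SCORERS <- c("identity_fraction", "property_class")

#' Per-column conservation of a paralog alignment
#'
#' Two documented column metrics are available, both on \[0, 1\] and both
#' gap-aware (gaps enter neither the modal count nor the denominator):
#'
#' * `identity_fraction` (default): fraction of non-gap residues equal to
#'   the column's modal residue.
#' * `property_class`: fraction of non-gap residues in the column's modal
#'   physicochemical class (hydrophobic, polar, positive, negative, or
#'   special = G/P/C).
#'
#' These are deliberate, reproducible approximations of interactive
#' alignment-viewer conservation scores; the scorer name travels with the
#' profile for provenance.
#'
#' @param aln A [paralog_alignment()].
#' @param scorer `"identity_fraction"` or `"property_class"`.
#' @return A `conservation_profile`: numeric vector of length
#'   `aln$n_columns` with attribute `scorer_name`.
#' @export
column_conservation <- function(aln, scorer = c("identity_fraction", "property_class")) {
  stopifnot(inherits(aln, "paralog_alignment"))
  if (is.character(scorer) && length(scorer) == 1L && !scorer %in% CONSERVATION_SCORERS) {
    stop_config_error(sprintf(
      "unknown conservation scorer '%s' (available: %s)",
      scorer, paste(CONSERVATION_SCORERS, collapse = ", ")
    ))
  }
  scorer <- match.arg(scorer)
  scores <- apply(aln$mat, 2L, function(col) {
    res <- col[col != "-"]
    if (scorer == "property_class") {
      res <- AA_CLASS[res]
    }
    max(table(res)) / length(res)
  })
  structure(as.numeric(scores), scorer_name = scorer, class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile (%s): %d columns, mean %.3f\n",
              attr(x, "scorer_name"), length(x), mean(x)))
  invisible(x)
}

#' Residue-to-column map for one alignment member
#'
#' @param aln A [paralog_alignment()].
#' @param protein_id A member id.
#' @return Integer vector: element `i` is the alignment column holding
#'   residue `i` (1-based, ungapped) of that member; strictly increasing.
#' @export
residue_map <- function(aln, protein_id) {
  stopifnot(inherits(aln, "paralog_alignment"))
  i <- match(protein_id, aln$ids)
  if (is.na(i)) {
    stop_config_error(sprintf("unknown protein id '%s'", protein_id))
  }
  which(aln$mat[i, ] != "-")
}

#' Per-residue paralog conservation z-scores (para_zscore)
#'
#' Standardises the column conservation scores of one focal protein
#' against that protein's own mean and standard deviation: for residue
#' `i` mapped to alignment column `k`,
#' `z_i = (score_k - mean_p) / sd_p`, with `mean_p` and `sd_p` computed
#' over exactly the focal protein's non-gap columns (columns where the
#' focal protein is gapped map to no residue and are excluded). The
#' standard deviation uses the n-1 denominator. Normalisation is per
#' protein, not pooled across the family, so each member's profile has
#' mean 0 and sd 1 over its own residues. Residues with `z > 0` are
#' called paralog-conserved (see [conserved_mask()]).
#'
#' @param cp A [column_conservation()] profile of `aln`.
#' @param aln A [paralog_alignment()].
#' @param protein_id Focal member id.
#' @return A `para_z_profile`: list with `protein_id`, `z` (one value per
#'   ungapped residue), `residue_columns` (the residue -> column map),
#'   `conservation` (per-residue raw scores), `mean_c`, `sd_c` and
#'   `scorer_name`.
#' @export
para_zscore <- function(cp, aln, protein_id) {
  stopifnot(inherits(cp, "conservation_profile"), inherits(aln, "paralog_alignment"))
  if (length(cp) != aln$n_columns) {
    stop_param_error("conservation profile length does not match alignment columns")
  }
  cols <- residue_map(aln, protein_id)
  scores <- as.numeric(cp)[cols]
  m <- mean(scores)
  s <- stats::sd(scores)  # n - 1 denominator
  if (!is.finite(s) || s == 0) {
    stop(errorCondition(
      sprintf("degenerate conservation profile for '%s': all residues equally conserved", protein_id),
      class = c("parazburden_degenerate_error", "parazburden_error")
    ))
  }
  structure(
    list(
      protein_id = protein_id,
      z = (scores - m) / s,
      residue_columns = cols,
      conservation = scores,
      mean_c = m,
      sd_c = s,
      scorer_name = attr(cp, "scorer_name")
    ),
    class = "para_z_profile"
  )
}

#' @export
print.para_z_profile <- function(x, ...) {
  cat(sprintf("para_zscore profile for %s: %d residues (scorer %s, mean_c %.3f, sd_c %.3f)\n",
              x$protein_id, length(x$z), x$scorer_name, x$mean_c, x$sd_c))
  invisible(x)
}

#' Paralog-conserved residue mask
#'
#' A residue counts as paralog-conserved when its para_zscore is strictly
#' greater than zero, i.e. more conserved than the focal protein's own
#' average residue.
#'
#' @param pz A [para_zscore()] profile.
#' @return Logical vector, one flag per residue; `z == 0` is `FALSE`.
#' @export
conserved_mask <- function(pz) {
  stopifnot(inherits(pz, "para_z_profile"))
  pz$z > 0
}

#' Summary of para_zscores inside a region
#'
#' @param pz A [para_zscore()] profile.
#' @param dm A [domain_map()] with protein length `length(pz$z)`.
#' @param region Region name (or `"other"`).
#' @return Named numeric vector: `mean`, `q25`, `median`, `q75`, `n`.
#' @export
region_z_summary <- function(pz, dm, region) {
  stopifnot(inherits(pz, "para_z_profile"), inherits(dm, "domain_map"))
  if (length(pz$z) != attr(dm, "protein_length")) {
    stop_param_error("z profile length does not match domain-map protein length")
  }
  idx <- region_residues(dm, region)
  if (!length(idx)) {
    stop_param_error(sprintf("region '%s' covers no residues", region))
  }
  zr <- pz$z[idx]
  q <- stats::quantile(zr, c(0.25, 0.5, 0.75), names = FALSE)
  c(mean = mean(zr), q25 = q[1], median = q[2], q75 = q[3], n = length(zr))
}

#' Per-residue conservation table for one protein
#'
#' @param pz A [para_zscore()] profile.
#' @param aln The [paralog_alignment()] the profile came from.
#' @return Data frame with columns `protein_id`, `residue`, `ref_aa`,
#'   `column`, `conservation`, `z`, `conserved` — the TSV-ready export of
#'   a para_zscore analysis.
#' @export
para_z_table <- function(pz, aln) {
  stopifnot(inherits(pz, "para_z_profile"), inherits(aln, "paralog_alignment"))
  i <- match(pz$protein_id, aln$ids)
  data.frame(
    protein_id = pz$protein_id,
    residue = seq_along(pz$z),
    ref_aa = aln$mat[i, pz$residue_columns],
    column = pz$residue_columns,
    conservation = pz$conservation,
    z = pz$z,
    conserved = conserved_mask(pz),
    stringsAsFactors = FALSE
  )
}
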