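#' Population variant position set
#'
#' The set of distinct 1-based coding-nucleotide positions at which at
#' least one population variant has been observed. Allele counts are
#' deliberately ignored: a position either carries a variant or it does
#' not, which is the counting unit behind the mutational-density profile.
#'
#' @param positions Integer vector of variant positions (duplicates are
#'   collapsed).
#' @param length Coding-sequence length in nucleotides.
#' @return A `position_set` object.
#' @export
position_set <- function(positions, length) {
  length <- as.integer(length)
  positions <- sort(unique(as.integer(positions)))
  stopifnot(length >= 1L)
  if (any(positions < 1L) || any(positions > length)) {
    stop_param_error("variant positions must lie in [1, length]")
  }
  structure(list(positions = positions, length = length), class = "position_set")
}

#' @export
print.position_set <- function(x, ...) {
  cat(sprintf("Position set: %d variant position(s) over %d nt\n",
              length(x$positions), x$length))
  invisible(x)
}

#' Read a position set from a TSV file
#'
#' @param path TSV with a `position` column of 1-based coding-nucleotide
#'   coordinates (duplicate rows, e.g. multi-allelic sites, collapse to
#'   one position).
#' @param length Coding-sequence length in nucleotides.
#' @return A [position_set()].
#' @export
read_position_set <- function(path, length) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#")
  if (!"position" %in% names(df)) {
    stop_config_error("position table needs a 'position' column")
  }
  position_set(df$position, length)
}

#' Sliding-window mutational density over a coding sequence
#'
#' For every nucleotide position the fraction of positions inside its
#' window that carry a population variant. The window is centred — for the
#' default length 10 it covers positions `[i - 5, i + 4]` — and truncated
#' at the sequence edges, with the *actual* (truncated) window size as the
#' divisor so edge densities stay on the same 0-1 scale as interior ones.
#'
#' @param ps A [position_set()].
#' @param window Window length in nucleotides (default 10).
#' @return A `density_profile`: numeric vector of length `ps$length`, one
#'   value in \[0, 1\] per nucleotide, with attributes `window` and
#'   `space = "nucleotide"`.
#' @export
sliding_density <- function(ps, window = 10L) {
  stopifnot(inherits(ps, "position_set"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window > ps$length) {
    stop_param_error(sprintf(
      "window must be an integer in [1, %d], got %s", ps$length, deparse(window)
    ))
  }
  L <- ps$length
  is_var <- integer(L)
  is_var[ps$positions] <- 1L
  half <- window %/% 2L
  # cumulative-sum window counts; window for position i is
  # [i - half, i + window - half - 1] intersected with [1, L]
  cs <- c(0L, cumsum(is_var))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + (window - half - 1L), L)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new_density_profile(vals, window = window, space = "nucleotide")
}

new_density_profile <- function(values, window, space) {
  structure(as.numeric(values), window = as.integer(window),
            space = space, class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile: %d %s positions, window %d nt, range [%.3g, %.3g]\n",
              length(x), attr(x, "space"), attr(x, "window"),
              min(x), max(x)))
  invisible(x)
}

#' Project a nucleotide density profile onto residues
#'
#' Each residue receives the mean of the three nucleotide densities of its
#' codon. The mean (rather than the maximum) gives a smooth per-amino-acid
#' profile suitable for plotting against a protein domain map.
#'
#' @param dp A nucleotide-space `density_profile` whose length is a
#'   multiple of 3.
#' @return A residue-space `density_profile` of length `length(dp) / 3`.
#' @export
project_to_residues <- function(dp) {
  stopifnot(inherits(dp, "density_profile"))
  if (!identical(attr(dp, "space"), "nucleotide")) {
    stop_param_error("profile is not in nucleotide space")
  }
  n <- length(dp)
  if (n %% 3L != 0L) {
    stop_param_error(sprintf("nucleotide length %d is not divisible by 3", n))
  }
  vals <- colMeans(matrix(as.numeric(dp), nrow = 3L))
  new_density_profile(vals, window = attr(dp, "window"), space = "residue")
}

#' Mean density of a domain-map region
#'
#' @param dp A residue-space `density_profile`.
#' @param dm A [domain_map()] whose protein length equals `length(dp)`.
#' @param region Region name in `dm` (or `"other"`).
#' @return Arithmetic mean of the residue densities inside the region.
#' @export
region_mean_density <- function(dp, dm, region) {
  stopifnot(inherits(dp, "density_profile"), inherits(dm, "domain_map"))
  if (!identical(attr(dp, "space"), "residue")) {
    stop_param_error("profile is not in residue space")
  }
  if (length(dp) != attr(dm, "protein_length")) {
    stop_param_error("profile length does not match domain-map protein length")
  }
  idx <- region_residues(dm, region)
  if (!length(idx)) {
    stop_param_error(sprintf("region '%s' covers no residues", region))
  }
  mean(as.numeric(dp)[idx])
}

#' Distinct residue positions touched by nucleotide variant positions
#'
#' Maps coding-nucleotide positions to residue (codon) indices,
#' collapsing to distinct residues — the residue-space population
#' position set used by the burden test.
#'
#' @param ps A [position_set()] in nucleotide space (length divisible by 3).
#' @return A [position_set()] over residues.
#' @export
positions_to_residues <- function(ps) {
  stopifnot(inherits(ps, "position_set"))
  if (ps$length %% 3L != 0L) {
    stop_param_error("coding length not divisible by 3")
  }
  position_set((ps$positions + 2L) %/% 3L, ps$length %/% 3L)
}

#' Write a density profile as TSV
#'
#' @param dp A `density_profile`.
#' @param path Output path; columns `position` and `density`.
#' @export
write_density_tsv <- function(dp, path) {
  stopifnot(inherits(dp, "density_profile"))
  utils::write.table(
    data.frame(position = seq_along(dp), density = as.numeric(dp)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
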