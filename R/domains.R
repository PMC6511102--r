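#' Protein domain map
#'
#' An ordered set of named, non-overlapping residue intervals (1-based,
#' inclusive) over a protein of known length. Residues not covered by any
#' named interval belong to the implicit region `"other"`.
#'
#' @param name Character vector of region names.
#' @param start,end Integer vectors of interval bounds, 1-based inclusive.
#' @param protein_length Total protein length in residues.
#' @return A `domain_map`: a data frame with columns `name`, `start`,
#'   `end` and attribute `protein_length`.
#' @examples
#' domain_map(c("Habc", "SNARE", "TMR"), c(28, 192, 266), c(144, 254, 288), 288)
#' @export
domain_map <- function(name, start, end, protein_length) {
  start <- as.integer(start)
  end <- as.integer(end)
  protein_length <- as.integer(protein_length)
  stopifnot(length(name) == length(start), length(start) == length(end),
            length(protein_length) == 1L, protein_length >= 1L)
  if (anyDuplicated(name)) {
    stop_config_error("domain names must be unique")
  }
  if (any(start < 1L) || any(end > protein_length) || any(start > end)) {
    stop_config_error("domain intervals must satisfy 1 <= start <= end <= protein_length")
  }
  if (length(start) > 1L) {
    o <- order(start)
    if (any(start[o][-1] <= end[o][-length(o)])) {
      stop_config_error("domain intervals must not overlap")
    }
  }
  dm <- data.frame(name = as.character(name), start = start, end = end,
                   stringsAsFactors = FALSE)
  dm <- dm[order(dm$start), , drop = FALSE]
  rownames(dm) <- NULL
  attr(dm, "protein_length") <- protein_length
  class(dm) <- c("domain_map", "data.frame")
  dm
}

#' @export
print.domain_map <- function(x, ...) {
  cat(sprintf("Domain map over %d residues:\n", attr(x, "protein_length")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Residue indices covered by a region
#'
#' @param dm A [domain_map()].
#' @param region A named interval of `dm`, or `"other"` for all residues
#'   not covered by any named interval.
#' @return Integer vector of 1-based residue positions.
#' @export
region_residues <- function(dm, region) {
  stopifnot(inherits(dm, "domain_map"))
  L <- attr(dm, "protein_length")
  if (region == "other") {
    covered <- unlist(Map(seq.int, dm$start, dm$end))
    return(setdiff(seq_len(L), covered))
  }
  i <- match(region, dm$name)
  if (is.na(i)) {
    stop_config_error(sprintf("region '%s' not in domain map", region))
  }
  seq.int(dm$start[i], dm$end[i])
}

#' Read a domain map from a YAML config file
#'
#' Expected layout:
#' ```yaml
#' protein_length: 288
#' domains:
#'   - {name: SNARE, start: 192, end: 254}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$protein_length) || is.null(cfg$domains)) {
    stop_config_error("domain config needs 'protein_length' and 'domains'")
  }
  domain_map(
    name = vapply(cfg$domains, `[[`, character(1), "name"),
    start = vapply(cfg$domains, function(d) as.integer(d$start), integer(1)),
    end = vapply(cfg$domains, function(d) as.integer(d$end), integer(1)),
    protein_length = cfg$protein_length
  )
}

#' Default syntaxin-1B domain map
#'
#' Domain boundaries for human syntaxin-1B (288 residues): the N-terminal
#' Habc three-helix bundle (Ha, Hb, Hc), the linker, the SNARE motif and
#' the C-terminal transmembrane region (TMR). The source study shows the
#' domain architecture only schematically, so these boundaries are taken
#' from standard protein annotation (UniProt P61266 and the homologous
#' syntaxin-1A structure) and are deliberately user-replaceable: every
#' region-dependent result should cite the domain map actually used.
#'
#' @return A [domain_map()] with regions `Ha`, `Hb`, `Hc`, `linker`,
#'   `SNARE`, `TMR` over 288 residues.
#' @export
stx1b_domain_map <- function() {
  read_domain_map(system.file("extdata", "stx1b_domains.yaml", package = "parazburden"))
}
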