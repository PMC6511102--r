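# Amino-acid code tables shared by the parser and the alignment scorers.

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)
AA_ONE <- setNames(names(AA_THREE), AA_THREE)

# Physicochemical classes used by the "property_class" conservation scorer.
# G, P and C get their own class: glycine and proline break secondary
# structure, cysteine forms disulfides, so none substitutes conservatively.
AA_CLASS <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  G = "special", P = "special", C = "special"
)

TER_THREE <- "Ter"
TER_SYMBOL <- "*"

# Normalise an amino-acid token (one- or three-letter) to its three-letter
# form; "*" and "Ter" map to "Ter". Unknown codes raise a dedicated condition
# so callers can distinguish bad residue codes from malformed syntax.
normalize_aa <- function(token, what = "residue") {
  if (identical(token, TER_SYMBOL) || identical(token, TER_THREE)) {
    return(TER_THREE)
  }
  if (nchar(token) == 3L) {
    cased <- paste0(toupper(substr(token, 1L, 1L)), tolower(substr(token, 2L, 3L)))
    if (cased %in% AA_THREE) {
      return(cased)
    }
    stop_aa_error(token, what)
  }
  if (nchar(token) == 1L) {
    up <- toupper(token)
    if (up %in% names(AA_THREE)) {
      return(unname(AA_THREE[up]))
    }
  }
  stop_aa_error(token, what)
}

aa_three_to_one <- function(three) {
  if (identical(three, TER_THREE)) {
    return(TER_SYMBOL)
  }
  unname(AA_ONE[three])
}

stop_aa_error <- function(token, what) {
  stop(errorCondition(
    sprintf("unknown amino-acid code '%s' (%s)", token, what),
    class = c("parazburden_aa_error", "parazburden_error")
  ))
}

stop_parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("parazburden_parse_error", "parazburden_error")))
}

stop_config_error <- function(msg) {
  stop(errorCondition(msg, class = c("parazburden_config_error", "parazburden_error")))
}

stop_param_error <- function(msg) {
  stop(errorCondition(msg, class = c("parazburden_param_error", "parazburden_error")))
}
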