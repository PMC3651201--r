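#' Standard amino-acid three-letter codes
#'
#' The 20 standard residue codes, in alphabetical order. This is the symbol
#' set over which substitution matrices are defined.
#'
#' @return Character vector of length 20.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' Default ion identity list
#'
#' Ion codes that participate in the ion wildcard: during candidate pooling
#' any ion in this list may substitute for any other. The list is data, not
#' code; pass a modified vector to the pooling functions to change it.
#'
#' @param file Optional path to a one-column TSV (`ion_code`) overriding the
#'   shipped default of 22 common catalytic/crystallographic ions.
#' @return Character vector of ion codes.
#' @export
default_ions <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "ions.tsv", package = "sitematch")
  }
  readr::read_tsv(file, show_col_types = FALSE)$ion_code
}

#' Centroid assignment rules
#'
#' Reads the editable rules table mapping nonstandard residue and cofactor
#' HET codes to an equivalent standard code and the atom used as the residue
#' centroid. Standard residues always use the C-alpha atom and need no rule;
#' ions use their single atom and are governed by [default_ions()].
#'
#' @param file Optional path to a TSV with columns `het_code`,
#'   `equivalent_code`, `centroid_atom`, `category`; defaults to the shipped
#'   rules file.
#' @return A tibble of rules (one row per HET code).
#' @export
centroid_rules <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "centroid_rules.tsv", package = "sitematch")
  }
  rules <- readr::read_tsv(file, show_col_types = FALSE)
  stopifnot(all(c("het_code", "equivalent_code", "centroid_atom", "category")
                %in% names(rules)))
  if (anyDuplicated(rules$het_code)) {
    stop("centroid rules must be a function: duplicated het_code entries")
  }
  rules
}

# Euclidean distance matrix for an n x 3 coordinate matrix.
coord_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

# Deterministic residue key used in tie-breaks and injectivity checks.
residue_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, insert)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
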