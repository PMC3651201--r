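#' @title Catalytic-site templates
#' @description A `site_template` is the reduced representation of one
#'   annotated catalytic site: one centroid coordinate per critical residue,
#'   ion or cofactor, the symmetric matrix of their pairwise centroid
#'   distances, and the site's EC number. Residues are kept in canonical
#'   order: alphabetical by canonical code, then by residue number.
#' @param site_id Site identifier (parent PDB id plus site index, with an
#'   optional `cx`/chain/`mfm` suffix for split multimeric sites).
#' @param ec Four-field EC number string, retained verbatim.
#' @param residues Tibble with columns `raw_code`, `code` (canonical),
#'   `category` (`standard`, `nonstandard`, `ion`, `cofactor`, `unknown`),
#'   `chain`, `resno`, `insert`, `centroid_atom`, centroid `x`,`y`,`z` and
#'   backbone coordinates (`n_x`..`c_z`), which may be `NA` until resolved.
#' @return An object of class `site_template`.
#' @keywords internal
new_site_template <- function(site_id, ec, residues) {
  residues <- dplyr::arrange(residues, .data$code, .data$resno, .data$chain)
  n <- nrow(residues)
  resolved <- n > 0 && !anyNA(residues$x)
  dmat <- NULL
  if (resolved) {
    dmat <- coord_dist(as.matrix(residues[, c("x", "y", "z")]))
    dimnames(dmat) <- NULL
  }
  structure(
    list(site_id = site_id, ec = ec, residues = residues,
         dmat = dmat, n = n, searchable = n >= 2, resolved = resolved),
    class = "site_template"
  )
}

#' @export
print.site_template <- function(x, ...) {
  cat(sprintf("<site_template %s> EC %s, %d residue(s)%s%s\n",
              x$site_id, x$ec, x$n,
              if (x$searchable) "" else " [unsearchable]",
              if (x$resolved) "" else " [coordinates unresolved]"))
  print(dplyr::select(x$residues, "code", "raw_code", "category",
                      "chain", "resno"))
  invisible(x)
}

# Classify an annotated code and return canonical code, category and
# centroid atom (NA atom means C-alpha, resolved later).
classify_code <- function(raw_code, rules, ions) {
  raw_code <- toupper(raw_code)
  if (raw_code %in% standard_residues()) {
    return(list(code = raw_code, category = "standard", atom = "CA"))
  }
  if (raw_code %in% ions) {
    return(list(code = raw_code, category = "ion", atom = raw_code))
  }
  hit <- rules[rules$het_code == raw_code, ]
  if (nrow(hit) == 1) {
    return(list(code = hit$equivalent_code, category = hit$category,
                atom = hit$centroid_atom))
  }
  list(code = raw_code, category = "unknown", atom = NA_character_)
}

parse_residue_triplets <- function(txt) {
  if (is.na(txt) || !nzchar(trimws(txt))) return(NULL)
  parts <- stringr::str_split(txt, ";")[[1]]
  parts <- stringr::str_trim(parts)
  parts <- parts[parts != ""]
  if (length(parts) == 0) return(NULL)
  fields <- stringr::str_split(parts, "\\s+")
  bad <- lengths(fields) != 3
  if (any(bad)) {
    stop("malformed residue triplet(s): ",
         paste(parts[bad], collapse = ", "))
  }
  m <- do.call(rbind, fields)
  num <- m[, 3]
  insert <- stringr::str_extract(num, "[A-Za-z]$")
  insert[is.na(insert)] <- ""
  resno <- as.integer(stringr::str_remove(num, "[A-Za-z]$"))
  if (anyNA(resno)) stop("non-numeric residue number in: ", txt)
  tibble::tibble(raw_code = toupper(m[, 1]), chain = m[, 2],
                 resno = resno, insert = insert)
}

#' Parse a catalytic-site catalog table
#'
#' Reads the catalog dialect: one site per line, tab-separated columns
#' `site_id`, `ec` and `residues`, the latter a semicolon-separated list of
#' `CODE CHAIN NUMBER` triplets. Residue order within a row is irrelevant;
#' templates are canonicalized (alphabetical by canonical code, then residue
#' number). Coordinates are left unresolved; see [resolve_centroids()].
#'
#' Single-residue sites are retained but flagged unsearchable, since a
#' template needs at least two residues to have a distance matrix.
#'
#' @param file Path to the catalog TSV (or literal text with embedded
#'   newlines).
#' @param rules Centroid rules tibble, see [centroid_rules()].
#' @param ions Ion identity vector, see [default_ions()].
#' @return Tibble with one row per site: `site_id`, `ec`, `n_residues`,
#'   `searchable`, and a `template` list-column of [new_site_template()]
#'   objects with unresolved coordinates.
#' @export
parse_site_table <- function(file, rules = centroid_rules(),
                             ions = default_ions()) {
  tab <- readr::read_tsv(file, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("site_id", "ec", "residues")
  if (!all(required %in% names(tab))) {
    stop("catalog table needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id in catalog: ",
         paste(unique(tab$site_id[duplicated(tab$site_id)]), collapse = ", "))
  }
  templates <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    res <- tryCatch(parse_residue_triplets(row$residues), error = function(e) {
      stop(sprintf("catalog row %d (%s): %s", i, row$site_id,
                   conditionMessage(e)), call. = FALSE)
    })
    if (is.null(res)) {
      stop(sprintf("catalog row %d (%s): empty residue list", i, row$site_id),
           call. = FALSE)
    }
    cls <- purrr::map(res$raw_code, classify_code, rules = rules, ions = ions)
    res$code <- purrr::map_chr(cls, "code")
    res$category <- purrr::map_chr(cls, "category")
    res$centroid_atom <- purrr::map_chr(cls, "atom")
    res$x <- res$y <- res$z <- NA_real_
    res$n_x <- res$n_y <- res$n_z <- NA_real_
    res$ca_x <- res$ca_y <- res$ca_z <- NA_real_
    res$c_x <- res$c_y <- res$c_z <- NA_real_
    new_site_template(row$site_id, row$ec, res)
  })
  tibble::tibble(
    site_id = tab$site_id,
    ec = tab$ec,
    n_residues = purrr::map_int(templates, "n"),
    searchable = purrr::map_lgl(templates, "searchable"),
    template = templates
  )
}

#' Resolve template centroids against a structure
#'
#' Fills in centroid coordinates (and backbone N/CA/C coordinates for
#' standard and nonstandard residues) for every annotated residue of a
#' template, then builds the template distance matrix from all unique
#' centroid pairs. Standard and nonstandard residues use the C-alpha atom;
#' ions use their single atom; cofactors use the atom named by their
#' centroid rule.
#'
#' @param template A `site_template` (coordinates may be unresolved).
#' @param structure A `target_structure` from [load_structure()].
#' @param rules Centroid rules tibble (used to diagnose unknown HET codes).
#' @return The template with coordinates and `dmat` filled.
#' @export
resolve_centroids <- function(template, structure, rules = centroid_rules()) {
  stopifnot(inherits(template, "site_template"),
            inherits(structure, "target_structure"))
  res <- template$residues
  for (i in seq_len(nrow(res))) {
    cat_i <- res$category[i]
    if (cat_i == "unknown") {
      stop(sprintf("no centroid rule for HET code '%s' (site %s)",
                   res$raw_code[i], template$site_id))
    }
    if (cat_i %in% c("standard", "nonstandard")) {
      hit <- dplyr::filter(structure$residues,
                           .data$chain == res$chain[i],
                           .data$resno == res$resno[i],
                           .data$insert == res$insert[i])
      if (nrow(hit) != 1 || is.na(hit$ca_x)) {
        stop(sprintf("annotated residue %s %s%d%s absent from structure %s",
                     res$raw_code[i], res$chain[i], res$resno[i],
                     res$insert[i], structure$structure_id))
      }
      res$x[i] <- hit$ca_x; res$y[i] <- hit$ca_y; res$z[i] <- hit$ca_z
      res$n_x[i] <- hit$n_x; res$n_y[i] <- hit$n_y; res$n_z[i] <- hit$n_z
      res$ca_x[i] <- hit$ca_x; res$ca_y[i] <- hit$ca_y; res$ca_z[i] <- hit$ca_z
      res$c_x[i] <- hit$c_x; res$c_y[i] <- hit$c_y; res$c_z[i] <- hit$c_z
    } else {
      hit <- dplyr::filter(structure$het_atoms,
                           .data$resid == res$raw_code[i],
                           .data$chain == res$chain[i],
                           .data$resno == res$resno[i],
                           .data$elety == res$centroid_atom[i])
      if (nrow(hit) < 1) {
        stop(sprintf("atom %s of %s %s%d absent from structure %s",
                     res$centroid_atom[i], res$raw_code[i], res$chain[i],
                     res$resno[i], structure$structure_id))
      }
      hit <- hit[1, ]
      res$x[i] <- hit$x; res$y[i] <- hit$y; res$z[i] <- hit$z
    }
  }
  new_site_template(template$site_id, template$ec, res)
}

#' Split multichain and multi-site templates
#'
#' Sites whose residues span more than one chain are relabeled as the
#' original complex site (suffix `cx`) plus one per-chain site for every
#' chain holding at least two residues (suffix = chain id). Within a chain,
#' residue groups separated by more than `flag_distance` (single-linkage
#' clustering at that cut) are multi-site ("multifunctional monomer")
#' candidates: the chain site gets suffix `mfm` and each cluster with at
#' least two residues becomes its own site (suffix chain id plus index).
#' Compact single-chain sites are returned unchanged.
#'
#' @param template Resolved `site_template`.
#' @param flag_distance Distance flag in Angstrom (default 20).
#' @return List of `site_template`s (always at least one).
#' @export
split_multimeric <- function(template, flag_distance = .sm_defaults$flag_distance) {
  stopifnot(inherits(template, "site_template"), template$resolved)
  res <- template$residues
  chains <- unique(res$chain)

  split_chain <- function(chain_res, base_id) {
    # single-linkage partition of one chain's residues at the flag distance
    if (nrow(chain_res) < 2) return(NULL)
    d <- stats::dist(as.matrix(chain_res[, c("x", "y", "z")]))
    if (max(d) <= flag_distance) return(list(chain_res))
    cl <- stats::cutree(stats::hclust(d, method = "single"),
                        h = flag_distance)
    unname(split(chain_res, cl))
  }

  out <- list()
  if (length(chains) > 1) {
    out <- c(out, list(new_site_template(paste0(template$site_id, "cx"),
                                         template$ec, res)))
    for (ch in chains) {
      chain_res <- dplyr::filter(res, .data$chain == ch)
      if (nrow(chain_res) < 2) next
      pieces <- split_chain(chain_res, template$site_id)
      if (length(pieces) == 1) {
        out <- c(out, list(new_site_template(paste0(template$site_id, ch),
                                             template$ec, chain_res)))
      } else {
        for (j in seq_along(pieces)) {
          out <- c(out, list(new_site_template(
            paste0(template$site_id, ch, j), template$ec, pieces[[j]])))
        }
      }
    }
    return(out)
  }

  pieces <- split_chain(res, template$site_id)
  if (is.null(pieces) || length(pieces) == 1) return(list(template))
  out <- list(new_site_template(paste0(template$site_id, "mfm"),
                                template$ec, res))
  for (j in seq_along(pieces)) {
    if (nrow(pieces[[j]]) < 2) next
    out <- c(out, list(new_site_template(
      paste0(template$site_id, chains[1], j), template$ec, pieces[[j]])))
  }
  out
}

#' Parse a homolog site table
#'
#' Homolog entries mirror the catalog dialect with an extra
#' `parent_site_id` column: `member_id`, `parent_site_id`, `ec`, `residues`.
#' The residue triplets are listed in correspondence with the parent
#' template's canonical residue order, so position-wise comparison against
#' the parent is well defined even when a position is substituted.
#'
#' @param file Path to the homolog TSV.
#' @return Tibble with one row per homolog entry and a `residues`
#'   list-column.
#' @export
parse_homolog_table <- function(file) {
  tab <- readr::read_tsv(file, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("member_id", "parent_site_id", "ec", "residues")
  if (!all(required %in% names(tab))) {
    stop("homolog table needs columns: ", paste(required, collapse = ", "))
  }
  tab$residues <- purrr::map(tab$residues, parse_residue_triplets)
  tibble::as_tibble(tab)
}

#' Build a template-specific substitution matrix
#'
#' Derives the binary, symmetric residue-substitution allowance for one
#' template from its homolog site entries. A homolog is admitted only if
#' (1) its standard-residue count equals the parent's and (2) its four-field
#' EC number equals the parent's. For admitted homologs, position-wise code
#' differences against the parent's standard residues (in canonical order)
#' are recorded symmetrically. The diagonal is always 1, and the ion
#' wildcard is always on: any listed ion substitutes for any other.
#'
#' @param parent Parent `site_template`.
#' @param homologs Tibble as returned by [parse_homolog_table()] (rows for
#'   this parent; other rows are ignored).
#' @param ions Ion identity vector for the wildcard.
#' @return A `substitution_matrix`: binary symmetric 20 x 20 matrix over the
#'   standard codes with attributes `site_id`, `ion_wildcard`, `ion_codes`,
#'   `n_admitted`, `n_skipped` and `n_substitutions` (distinct substitution
#'   pairs observed).
#' @export
build_substitution_matrix <- function(parent, homologs = NULL,
                                      ions = default_ions()) {
  stopifnot(inherits(parent, "site_template"))
  codes <- standard_residues()
  m <- diag(20L)
  dimnames(m) <- list(codes, codes)
  parent_std <- dplyr::filter(parent$residues, .data$category %in%
                                c("standard", "nonstandard"))
  n_admitted <- 0L
  n_skipped <- 0L
  if (!is.null(homologs) && nrow(homologs) > 0) {
    rows <- homologs[homologs$parent_site_id == parent$site_id, ]
    for (i in seq_len(nrow(rows))) {
      hres <- rows$residues[[i]]
      hstd <- hres[toupper(hres$raw_code) %in% codes, , drop = FALSE]
      if (nrow(hstd) != nrow(parent_std) ||
          !identical(rows$ec[i], parent$ec)) {
        n_skipped <- n_skipped + 1L
        next
      }
      n_admitted <- n_admitted + 1L
      for (j in seq_len(nrow(parent_std))) {
        a <- parent_std$code[j]
        b <- toupper(hstd$raw_code[j])
        if (a != b) {
          m[a, b] <- 1L
          m[b, a] <- 1L
        }
      }
    }
  }
  n_subs <- (sum(m) - 20L) / 2L
  structure(m, class = c("substitution_matrix", class(m)),
            site_id = parent$site_id, ion_wildcard = TRUE,
            ion_codes = ions, n_admitted = n_admitted,
            n_skipped = n_skipped, n_substitutions = n_subs)
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("<substitution_matrix %s> %d substitution pair(s), %d homolog(s) admitted, %d skipped, ion wildcard %s\n",
              attr(x, "site_id"), attr(x, "n_substitutions"),
              attr(x, "n_admitted"), attr(x, "n_skipped"),
              if (isTRUE(attr(x, "ion_wildcard"))) "on" else "off"))
  invisible(x)
}

#' Summarize substitution matrices across a catalog
#'
#' Reporting utility: the element-wise OR of all per-template matrices (this
#' aggregate is never used in the search) and the distribution of observed
#' substitution counts per template.
#'
#' @param matrices List of `substitution_matrix` objects.
#' @return List with `aggregate` (binary 20 x 20 matrix), `counts` (tibble
#'   `site_id`, `n_substitutions`) and `histogram` (tibble
#'   `n_substitutions`, `n_templates`).
#' @export
summarize_substitutions <- function(matrices) {
  agg <- diag(20L)
  dimnames(agg) <- list(standard_residues(), standard_residues())
  for (m in matrices) agg <- pmax(agg, unclass(m))
  counts <- tibble::tibble(
    site_id = purrr::map_chr(matrices, ~ attr(.x, "site_id")),
    n_substitutions = purrr::map_int(matrices,
                                     ~ as.integer(attr(.x, "n_substitutions")))
  )
  histogram <- dplyr::count(counts, .data$n_substitutions,
                            name = "n_templates")
  list(aggregate = agg, counts = counts, histogram = histogram)
}
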