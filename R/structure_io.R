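#' Construct a target structure object
#'
#' Uniform coordinate model for a query structure: one row per residue (with
#' C-alpha and, where present, backbone N/C coordinates) plus a flat table
#' of HET-group atoms. Used both by the PDB reader and by the synthetic
#' benchmark generator.
#'
#' @param structure_id Identifier string.
#' @param residues Tibble: `chain`, `resno`, `insert`, `resid` (3-letter
#'   code), `ca_x/y/z`, `n_x/y/z`, `c_x/y/z` (`NA` when absent),
#'   `has_backbone`.
#' @param het_atoms Tibble: `resid`, `chain`, `resno`, `elety`, `x`, `y`,
#'   `z`.
#' @return A `target_structure`.
#' @export
new_target_structure <- function(structure_id, residues, het_atoms) {
  if (nrow(residues) == 0 && nrow(het_atoms) == 0) {
    stop("structure ", structure_id, " has no residues")
  }
  structure(list(structure_id = structure_id,
                 residues = tibble::as_tibble(residues),
                 het_atoms = tibble::as_tibble(het_atoms)),
            class = "target_structure")
}

#' @export
print.target_structure <- function(x, ...) {
  cat(sprintf("<target_structure %s> %d residue(s), %d HET atom(s)\n",
              x$structure_id, nrow(x$residues), nrow(x$het_atoms)))
  invisible(x)
}

#' Load a query structure from a PDB file
#'
#' Reads the first model of a PDB file into a [new_target_structure()].
#' Alternate locations are resolved to the highest-occupancy copy. A
#' residue is any (chain, number, insertion code) group carrying a C-alpha
#' atom; missing backbone N/C atoms are tolerated and flagged. All non-water
#' HETATM records are kept as HET atoms (waters configurable).
#'
#' @param file Path to a PDB file.
#' @param keep_water Keep water HET groups (default `FALSE`).
#' @return A `target_structure`.
#' @export
load_structure <- function(file, keep_water = FALSE) {
  if (!file.exists(file)) stop("cannot read PDB file: ", file)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE))
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) stop("no atoms in PDB file: ", file)
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: keep the highest-occupancy copy of each atom
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  bb <- at |>
    dplyr::filter(.data$elety %in% c("N", "CA", "C")) |>
    dplyr::select("chain", "resno", "insert", "resid", "elety",
                  "x", "y", "z") |>
    tidyr::pivot_wider(names_from = "elety",
                       values_from = c("x", "y", "z"),
                       names_glue = "{tolower(elety)}_{.value}",
                       values_fn = dplyr::first)
  for (col in c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
                "c_x", "c_y", "c_z")) {
    if (!col %in% names(bb)) bb[[col]] <- NA_real_
  }
  residues <- bb |>
    dplyr::filter(!is.na(.data$ca_x)) |>
    dplyr::mutate(has_backbone = !is.na(.data$n_x) & !is.na(.data$c_x)) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert)

  waters <- c("HOH", "WAT", "DOD")
  het <- at |>
    dplyr::filter(.data$type == "HETATM") |>
    dplyr::filter(keep_water | !(.data$resid %in% waters)) |>
    dplyr::select("resid", "chain", "resno", "elety", "x", "y", "z")

  if (nrow(residues) == 0 && nrow(het) == 0) {
    stop("zero residues parsed from ", file)
  }
  new_target_structure(
    structure_id = tools::file_path_sans_ext(basename(file)),
    residues = residues, het_atoms = het
  )
}

#' Write a target structure to a PDB file
#'
#' Emits backbone atoms (N, CA, C) for each residue as ATOM records and all
#' HET atoms as HETATM records, via the standard PDB writer. Structures from
#' the synthetic generator round-trip losslessly at the centroid level.
#'
#' @param structure A `target_structure`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_structure_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "target_structure"))
  res <- structure$residues
  rows <- list()
  for (i in seq_len(nrow(res))) {
    for (a in c("N", "CA", "C")) {
      xi <- res[[paste0(tolower(a), "_x")]][i]
      if (is.na(xi)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = "ATOM", elety = a, resid = res$resid[i], chain = res$chain[i],
        resno = res$resno[i], insert = res$insert[i],
        x = res[[paste0(tolower(a), "_x")]][i],
        y = res[[paste0(tolower(a), "_y")]][i],
        z = res[[paste0(tolower(a), "_z")]][i]
      )
    }
  }
  het <- structure$het_atoms
  if (nrow(het) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      type = "HETATM", elety = het$elety, resid = het$resid,
      chain = het$chain, resno = het$resno, insert = "",
      x = het$x, y = het$y, z = het$z
    )
  }
  tab <- dplyr::bind_rows(rows)
  ins <- ifelse(is.na(tab$insert) | tab$insert == "", "", tab$insert)
  bio3d::write.pdb(
    pdb = NULL, file = file,
    type = tab$type, eleno = seq_len(nrow(tab)), elety = tab$elety,
    resid = tab$resid, chain = tab$chain, resno = tab$resno, insert = ins,
    xyz = as.numeric(t(as.matrix(tab[, c("x", "y", "z")]))),
    o = rep(1, nrow(tab)), b = rep(0, nrow(tab))
  )
  invisible(file)
}

# Canonicalize a target residue code: standard codes map to themselves,
# known nonstandard codes to their standard equivalent, anything else NA.
canonical_target_code <- function(codes, rules) {
  out <- ifelse(codes %in% standard_residues(), codes, NA_character_)
  ns <- rules[rules$category == "nonstandard", ]
  hit <- match(codes, ns$het_code)
  out[!is.na(hit)] <- ns$equivalent_code[hit[!is.na(hit)]]
  out
}

#' Build the per-template candidate pool for a target
#'
#' For each template position, collects every target residue whose canonical
#' code equals the template code or is an allowed substitution. Ion
#' positions match any ion in the wildcard list; cofactor positions match
#' their exact HET code through the centroid rule's atom. The pool carries
#' the centroid distance matrix over all pooled residues, from which the
#' search reads edge lengths.
#'
#' @param target A `target_structure`.
#' @param template A resolved (or unresolved) `site_template`.
#' @param subs A `substitution_matrix` for this template; `NULL` means
#'   identity-only substitutions with the ion wildcard on.
#' @param rules Centroid rules tibble.
#' @param ions Ion identity vector (used when `subs` is `NULL`).
#' @return A `candidate_pool`: list with `template`, `candidates` (tibble of
#'   pooled residues with global index, ordered by chain/number), `cand_idx`
#'   (per-position integer vectors into `candidates`), and `D` (distance
#'   matrix over pooled centroids).
#' @export
build_candidate_pool <- function(target, template, subs = NULL,
                                 rules = centroid_rules(),
                                 ions = default_ions()) {
  stopifnot(inherits(target, "target_structure"),
            inherits(template, "site_template"))
  codes <- standard_residues()
  if (is.null(subs)) {
    subs <- diag(20L)
    dimnames(subs) <- list(codes, codes)
    attr(subs, "ion_wildcard") <- TRUE
    attr(subs, "ion_codes") <- ions
  }
  ion_codes <- attr(subs, "ion_codes") %||% ions
  wildcard <- isTRUE(attr(subs, "ion_wildcard"))

  tres <- target$residues
  tres$canonical <- canonical_target_code(tres$resid, rules)

  pos_candidates <- purrr::map(seq_len(template$n), function(i) {
    p <- template$residues[i, ]
    if (p$category %in% c("standard", "nonstandard")) {
      allowed <- codes[unclass(subs)[p$code, ] == 1]
      cand <- dplyr::filter(tres, .data$canonical %in% allowed)
      if (nrow(cand) == 0) return(NULL)
      tibble::tibble(code = cand$resid, canonical = cand$canonical,
                     category = "residue",
                     chain = cand$chain, resno = cand$resno,
                     insert = cand$insert,
                     x = cand$ca_x, y = cand$ca_y, z = cand$ca_z,
                     n_x = cand$n_x, n_y = cand$n_y, n_z = cand$n_z,
                     ca_x = cand$ca_x, ca_y = cand$ca_y, ca_z = cand$ca_z,
                     c_x = cand$c_x, c_y = cand$c_y, c_z = cand$c_z,
                     substitution = cand$canonical != p$code)
    } else if (p$category == "ion") {
      want <- if (wildcard) ion_codes else p$raw_code
      cand <- dplyr::filter(target$het_atoms, .data$resid %in% want,
                            .data$elety == .data$resid)
      if (nrow(cand) == 0) return(NULL)
      tibble::tibble(code = cand$resid, canonical = cand$resid,
                     category = "ion",
                     chain = cand$chain, resno = cand$resno, insert = "",
                     x = cand$x, y = cand$y, z = cand$z,
                     n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
                     ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
                     c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
                     substitution = cand$resid != p$raw_code)
    } else {
      cand <- dplyr::filter(target$het_atoms, .data$resid == p$raw_code,
                            .data$elety == p$centroid_atom)
      if (nrow(cand) == 0) return(NULL)
      tibble::tibble(code = cand$resid, canonical = cand$resid,
                     category = "cofactor",
                     chain = cand$chain, resno = cand$resno, insert = "",
                     x = cand$x, y = cand$y, z = cand$z,
                     n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
                     ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
                     c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
                     substitution = FALSE)
    }
  })

  all_cand <- dplyr::bind_rows(purrr::compact(purrr::map(pos_candidates,
    ~ if (is.null(.x)) NULL else dplyr::select(.x, -"substitution"))))
  if (nrow(all_cand) > 0) {
    all_cand <- dplyr::distinct(all_cand,
                                .data$chain, .data$resno, .data$insert,
                                .data$code, .keep_all = TRUE) |>
      dplyr::arrange(.data$chain, .data$resno, .data$insert, .data$code)
    all_cand$key <- residue_key(all_cand$chain, all_cand$resno,
                                all_cand$insert)
    all_cand$key <- paste0(all_cand$key, "/", all_cand$code)
    D <- coord_dist(as.matrix(all_cand[, c("x", "y", "z")]))
  } else {
    all_cand$key <- character(0)
    D <- matrix(0, 0, 0)
  }

  cand_idx <- purrr::map(pos_candidates, function(cc) {
    if (is.null(cc)) return(integer(0))
    k <- paste0(residue_key(cc$chain, cc$resno, cc$insert), "/", cc$code)
    sort(match(k, all_cand$key))
  })
  sub_flags <- purrr::map(pos_candidates, function(cc) {
    if (is.null(cc)) return(setNames(logical(0), character(0)))
    k <- paste0(residue_key(cc$chain, cc$resno, cc$insert), "/", cc$code)
    setNames(cc$substitution, k)[order(match(k, all_cand$key))]
  })

  structure(list(template = template, candidates = all_cand,
                 cand_idx = cand_idx, substitution = sub_flags, D = D,
                 target_id = target$structure_id),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("<candidate_pool %s ~ %s> position pool sizes: %s\n",
              x$target_id, x$template$site_id,
              paste(lengths(x$cand_idx), collapse = ", ")))
  invisible(x)
}

#' Drop template positions with empty candidate pools
#'
#' When an annotated residue type is entirely absent from the target, the
#' template is rebuilt without that position so the graph search still
#' works; the number of removed standard (amino-acid) residues is recorded
#' as a descriptor, with ions and cofactors not counted. Idempotent.
#'
#' @param template A `site_template`.
#' @param pool The matching `candidate_pool`.
#' @return List: `template` (reduced), `pool` (re-sliced), `n_removed`
#'   (removed standard residues), `removed` (tibble of dropped positions).
#' @export
reduce_template <- function(template, pool) {
  empty <- lengths(pool$cand_idx) == 0
  if (!any(empty)) {
    return(list(template = template, pool = pool, n_removed = 0L,
                removed = template$residues[0, ]))
  }
  removed <- template$residues[empty, ]
  n_removed <- sum(removed$category %in% c("standard", "nonstandard"))
  kept <- template$residues[!empty, , drop = FALSE]
  reduced <- new_site_template(template$site_id, template$ec, kept)
  pool2 <- pool
  pool2$template <- reduced
  pool2$cand_idx <- pool$cand_idx[!empty]
  pool2$substitution <- pool$substitution[!empty]
  list(template = reduced, pool = pool2, n_removed = as.integer(n_removed),
       removed = removed)
}
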