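#' Search configuration
#'
#' Bundles the tunable parameters of the template search. Defaults are the
#' published operating point: a 1.5 Angstrom edge screen during buildup, a
#' 0.5 Angstrom inclusion tolerance for the descriptor stage, and up to 100
#' retained partial paths per iteration.
#'
#' @param edge_threshold Edge screen in Angstrom: a path extension is kept
#'   only if every newly built edge deviates from the template edge by at
#'   most this much.
#' @param inclusion_threshold Inclusion tolerance in Angstrom used by the
#'   descriptor stage (distinct from `edge_threshold`).
#' @param p_max Maximum partial paths retained per buildup iteration
#'   (`Inf` disables pruning and recovers the exhaustive search).
#' @param max_hits Maximum complete matches returned (`Inf` = all).
#' @return A `search_config` list.
#' @export
search_config <- function(edge_threshold = .sm_defaults$edge_threshold,
                          inclusion_threshold = .sm_defaults$inclusion_threshold,
                          p_max = .sm_defaults$p_max,
                          max_hits = Inf) {
  stopifnot(edge_threshold > 0, inclusion_threshold > 0, p_max >= 1)
  structure(list(edge_threshold = edge_threshold,
                 inclusion_threshold = inclusion_threshold,
                 p_max = p_max, max_hits = max_hits),
            class = "search_config")
}

# Positions whose canonical code (and category) repeats the previous
# position share an identical candidate pool; requiring strictly
# increasing candidate indices across such runs removes permutation
# duplicates (the binomial-coefficient symmetry).
duplicate_run_flags <- function(template) {
  key <- paste(template$residues$code, template$residues$category)
  c(FALSE, key[-1] == key[-template$n])
}

empty_hits <- function(pool, searched, n_comparisons = 0) {
  out <- tibble::tibble(rank = integer(0), rmsddm = numeric(0),
                        mapping = list(), n_substitutions = integer(0),
                        substitutions = list())
  structure(out, class = c("site_hits", class(out)),
            searched = searched, n_comparisons = n_comparisons,
            site_id = pool$template$site_id, target_id = pool$target_id,
            template = pool$template)
}

finalize_hits <- function(pool, paths, ssq, n_comparisons, config) {
  template <- pool$template
  if (is.null(paths) || nrow(paths) == 0) {
    return(empty_hits(pool, TRUE, n_comparisons))
  }
  m_edges <- template$n * (template$n - 1) / 2
  rmsddm <- sqrt(ssq / m_edges)
  key <- apply(paths, 1, function(p) paste(sprintf("%06d", p), collapse = ""))
  ord <- order(rmsddm, key)
  paths <- paths[ord, , drop = FALSE]
  rmsddm <- rmsddm[ord]
  if (is.finite(config$max_hits) && nrow(paths) > config$max_hits) {
    paths <- paths[seq_len(config$max_hits), , drop = FALSE]
    rmsddm <- rmsddm[seq_len(config$max_hits)]
  }
  tcode <- template$residues$code
  mapping <- purrr::map(seq_len(nrow(paths)), function(i) {
    cand <- pool$candidates[paths[i, ], , drop = FALSE]
    tibble::tibble(position = seq_len(template$n),
                   template_code = tcode,
                   dplyr::select(cand, "code", "canonical", "category",
                                 "chain", "resno", "insert",
                                 "x", "y", "z",
                                 "n_x", "n_y", "n_z",
                                 "ca_x", "ca_y", "ca_z",
                                 "c_x", "c_y", "c_z"))
  })
  subs <- purrr::map(mapping, function(mp) {
    is_sub <- mp$canonical != mp$template_code
    if (!any(is_sub)) return(character(0))
    sprintf("%s->%s@%d", mp$template_code[is_sub], mp$canonical[is_sub],
            mp$position[is_sub])
  })
  out <- tibble::tibble(rank = seq_along(rmsddm), rmsddm = rmsddm,
                        mapping = mapping,
                        n_substitutions = lengths(subs),
                        substitutions = subs)
  structure(out, class = c("site_hits", class(out)),
            searched = TRUE, n_comparisons = n_comparisons,
            site_id = template$site_id, target_id = pool$target_id,
            template = template)
}

#' Pruned subgraph-isomorphism template search
#'
#' Iterative buildup of candidate residue paths over the template positions
#' in canonical order. At step k every retained (k-1)-path is extended by
#' each eligible pool candidate for position k whose k-1 new edges all
#' deviate from the template edges by at most `edge_threshold`; extensions
#' are scored by the running distance-matrix RMSD over built edges
#' (partial rmsddm) and only the best `p_max` paths survive to the next
#' step. The full first pair screen is never pruned, which makes the
#' comparison count quadratic in target size and linear in template size.
#' Mappings are injective, and positions of a repeated residue type are
#' filled in canonical order so no permutation duplicates arise.
#'
#' @param pool A `candidate_pool` built with the template's substitution
#'   matrix.
#' @param config A [search_config()].
#' @return A `site_hits` tibble of complete matches sorted ascending by
#'   rmsddm (ties broken by the mapped chain/number tuple), with attributes
#'   `searched`, `n_comparisons`, `site_id`, `target_id`. An unsearchable
#'   template yields `searched = FALSE`, distinct from "searched, zero
#'   hits".
#' @export
search_template <- function(pool, config = search_config()) {
  stopifnot(inherits(pool, "candidate_pool"))
  template <- pool$template
  if (!template$searchable) return(empty_hits(pool, FALSE))
  if (any(lengths(pool$cand_idx) == 0)) {
    # caller should reduce_template() first; an empty position can never
    # complete, so report a searched-but-empty result
    return(empty_hits(pool, TRUE))
  }
  d_T <- template$dmat
  D <- pool$D
  dup <- duplicate_run_flags(template)
  thr <- config$edge_threshold

  paths <- matrix(pool$cand_idx[[1]], ncol = 1)
  ssq <- numeric(nrow(paths))
  n_comparisons <- 0

  for (k in seq_len(template$n)[-1]) {
    cands <- pool$cand_idx[[k]]
    dk <- d_T[k, seq_len(k - 1)]
    new_paths <- vector("list", nrow(paths))
    new_ssq <- vector("list", nrow(paths))
    for (p in seq_len(nrow(paths))) {
      path <- paths[p, ]
      ok <- !(cands %in% path)
      if (dup[k]) ok <- ok & (cands > path[k - 1])
      cc <- cands[ok]
      if (length(cc) == 0) next
      n_comparisons <- n_comparisons + length(cc)
      dev <- abs(D[cc, path, drop = FALSE] -
                   matrix(dk, nrow = length(cc), ncol = k - 1, byrow = TRUE))
      pass <- rowSums(dev > thr) == 0
      if (!any(pass)) next
      cc <- cc[pass]
      add <- rowSums(dev[pass, , drop = FALSE]^2)
      new_paths[[p]] <- cbind(matrix(path, nrow = length(cc), ncol = k - 1,
                                     byrow = TRUE), cc)
      new_ssq[[p]] <- ssq[p] + add
    }
    keep <- !vapply(new_paths, is.null, logical(1))
    if (!any(keep)) return(empty_hits(pool, TRUE, n_comparisons))
    paths <- do.call(rbind, new_paths[keep])
    ssq <- unlist(new_ssq[keep], use.names = FALSE)
    # prune to the top p_max partial paths by partial rmsddm, with a
    # deterministic residue-tuple tie-break
    if (k < template$n && nrow(paths) > config$p_max) {
      key <- apply(paths, 1, function(p) paste(sprintf("%06d", p),
                                               collapse = ""))
      ord <- order(ssq, key)[seq_len(config$p_max)]
      paths <- paths[ord, , drop = FALSE]
      ssq <- ssq[ord]
    }
  }
  finalize_hits(pool, paths, ssq, n_comparisons, config)
}

#' Exhaustive match enumeration (ground-truth oracle)
#'
#' Evaluates every injective, canonical-order assignment of pool candidates
#' to template positions, applying the same edge screen as
#' [search_template()], and returns complete matches in the same sorted
#' order. Serves as the brute-force oracle for the pruned search.
#'
#' @param pool A `candidate_pool`.
#' @param config A [search_config()] (`p_max` ignored).
#' @param cap Safety cap on the number of candidate assignments.
#' @return A `site_hits` tibble.
#' @export
enumerate_matches_bruteforce <- function(pool, config = search_config(),
                                         cap = 1e6) {
  stopifnot(inherits(pool, "candidate_pool"))
  template <- pool$template
  if (!template$searchable) return(empty_hits(pool, FALSE))
  est <- predict_comparisons(template, pool, p_max = Inf)
  if (est$n_candidates > cap) {
    stop(sprintf("instance too large for brute force (%.3g candidate assignments > cap %g); shrink the instance",
                 est$n_candidates, cap))
  }
  d_T <- template$dmat
  D <- pool$D
  dup <- duplicate_run_flags(template)
  thr <- config$edge_threshold
  n <- template$n
  acc_paths <- list()
  acc_ssq <- list()

  recurse <- function(path, ssq) {
    k <- length(path) + 1L
    cands <- pool$cand_idx[[k]]
    cands <- cands[!(cands %in% path)]
    if (dup[k]) cands <- cands[cands > path[k - 1]]
    for (cc in cands) {
      if (k > 1) {
        dev <- abs(D[cc, path] - d_T[k, seq_len(k - 1)])
        if (any(dev > thr)) next
        s2 <- ssq + sum(dev^2)
      } else s2 <- 0
      if (k == n) {
        acc_paths[[length(acc_paths) + 1]] <<- c(path, cc)
        acc_ssq[[length(acc_ssq) + 1]] <<- s2
      } else {
        recurse(c(path, cc), s2)
      }
    }
  }
  for (c1 in pool$cand_idx[[1]]) recurse(c1, 0)
  if (length(acc_paths) == 0) return(empty_hits(pool, TRUE))
  finalize_hits(pool, do.call(rbind, acc_paths),
                unlist(acc_ssq), NA_real_, config)
}

#' Predict the comparison count of a search (scaling model)
#'
#' Closed-form accounting of the number of path-extension evaluations
#' ("distance matrix comparisons") the buildup performs, ignoring the edge
#' screen and assuming disjoint per-type pools. With `E_k` the number of
#' canonical partial assignments of the first `k` positions (products of
#' binomial coefficients over repeated types), the uncapped buildup
#' evaluates `full = sum(E_k, k = 2..n_T)` extensions, while the pruned
#' search evaluates `E_2` for the unpruned first pair screen plus
#' `min(E_(k-1), P_max) * f_k` at each later step, where
#' `f_k = E_k / E_(k-1)`. A flat enumeration of all `E_(n_T)` candidate
#' sites, costed at one comparison per template row, gives the naive
#' enumeration figure `enum_cost = n_T * E_(n_T)`. With `p_max = Inf` the
#' pruned count equals the full count, and for `n_T = 2` all buildup counts
#' coincide.
#'
#' @param template A `site_template`.
#' @param pool The `candidate_pool` (pool sizes are read from it).
#' @param p_max Retained paths per iteration.
#' @param observed Optional instrumented comparison count from a search run.
#' @return A `complexity_estimate` list: `n_T`, `pool_sizes`,
#'   `n_candidates`, `enum_cost`, `full_comparisons`, `pruned_comparisons`,
#'   `observed`.
#' @export
predict_comparisons <- function(template, pool, p_max = .sm_defaults$p_max,
                                observed = NA_real_) {
  n <- template$n
  sizes <- lengths(pool$cand_idx)
  key <- paste(template$residues$code, template$residues$category)
  used <- stats::setNames(rep(0, length(unique(key))), unique(key))
  E <- numeric(n)
  f <- numeric(n)
  for (k in seq_len(n)) {
    c_before <- used[key[k]]
    f[k] <- max(sizes[k] - c_before, 0) / (c_before + 1)
    E[k] <- if (k == 1) f[k] else E[k - 1] * f[k]
    used[key[k]] <- c_before + 1
  }
  full <- if (n >= 2) sum(E[2:n]) else 0
  pruned <- 0
  if (n >= 2) {
    pruned <- E[2]
    for (k in seq_len(n)[-(1:2)]) {
      pruned <- pruned + min(E[k - 1], p_max) * f[k]
    }
  }
  structure(list(n_T = n, pool_sizes = sizes, n_candidates = E[n],
                 enum_cost = n * E[n], full_comparisons = full,
                 pruned_comparisons = pruned, observed = observed),
            class = "complexity_estimate")
}

#' @export
print.complexity_estimate <- function(x, ...) {
  cat(sprintf("<complexity_estimate> n_T=%d, pools [%s]: %.3g candidates, enum cost %.3g, full %.3g, pruned %.3g, observed %s\n",
              x$n_T, paste(x$pool_sizes, collapse = ","), x$n_candidates,
              x$enum_cost, x$full_comparisons, x$pruned_comparisons,
              ifelse(is.na(x$observed), "-", format(x$observed))))
  invisible(x)
}

#' Flatten search hits to a plain table
#'
#' One row per hit with the mapped residues rendered as a
#' `CODE CHAIN NUMBER` list, suitable for TSV export.
#'
#' @param hits A `site_hits` object.
#' @return A tibble.
#' @export
hits_table <- function(hits) {
  stopifnot(inherits(hits, "site_hits"))
  tibble::tibble(
    site_id = attr(hits, "site_id"),
    target_id = attr(hits, "target_id"),
    rank = hits$rank,
    rmsddm = hits$rmsddm,
    residues = purrr::map_chr(hits$mapping, function(mp) {
      paste(sprintf("%s %s %d%s", mp$code, mp$chain, mp$resno, mp$insert),
            collapse = "; ")
    }),
    n_substitutions = hits$n_substitutions,
    substitutions = purrr::map_chr(hits$substitutions, paste,
                                   collapse = ";")
  )
}
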