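#' Distance-matrix RMSD (rmsddm)
#'
#' Root-mean-square difference between the template distance matrix and the
#' matched substructure's distance matrix, taken over the unique
#' off-diagonal pairs: `sqrt(sum((d_T - d_S)^2) / m)` with
#' `m = n_T (n_T - 1) / 2`.
#'
#' @param d_T,d_S Symmetric distance matrices of equal size (n >= 2).
#' @return RMSD in Angstrom.
#' @export
rmsddm <- function(d_T, d_S) {
  if (!all(dim(d_T) == dim(d_S))) stop("distance matrices differ in size")
  n <- nrow(d_T)
  if (n < 2) stop("need at least 2 residues")
  up <- upper.tri(d_T)
  sqrt(sum((d_T[up] - d_S[up])^2) / (n * (n - 1) / 2))
}

#' Count edges within the inclusion threshold
#'
#' Number of unique residue pairs whose template and substructure distances
#' agree within `threshold` (default 0.5 Angstrom). This tolerance is a
#' descriptor-stage setting, deliberately tighter than the 1.5 Angstrom
#' screen used during the search.
#'
#' @inheritParams rmsddm
#' @param threshold Inclusion tolerance in Angstrom.
#' @return Integer count `e_inc`, between 0 and `n (n - 1) / 2`.
#' @export
count_included_edges <- function(d_T, d_S,
                                 threshold = .sm_defaults$inclusion_threshold) {
  if (!all(dim(d_T) == dim(d_S))) stop("distance matrices differ in size")
  up <- upper.tri(d_T)
  sum(abs(d_T[up] - d_S[up]) <= threshold)
}

#' Excluded-node estimate from the included-edge count
#'
#' Converts the number of out-of-tolerance edges into a real-valued
#' estimate of badly placed residues via the edge-loss model: removing the
#' first node loses `n_T - 1` edges, the next `n_T - 2`, and so on, so the
#' number of excluded edges `E_exc = n_T (n_T - 1) / 2 - e_inc` relates to
#' the excluded-node count quadratically. The physically meaningful
#' (smaller) root is
#' `n_exc = ((2 n_T - 1) - sqrt((2 n_T - 1)^2 - 8 E_exc)) / 2`,
#' ranging from 0 (all edges within tolerance) to `n_T - 1` (none are;
#' the final node is never counted as excluded). Not rounded.
#'
#' @param n_T Template residue count (>= 2).
#' @param e_inc Included-edge count.
#' @return Real-valued `n_exc`.
#' @export
excluded_nodes <- function(n_T, e_inc) {
  m <- n_T * (n_T - 1) / 2
  if (e_inc < 0 || e_inc > m) stop("e_inc out of range [0, ", m, "]")
  e_exc <- m - e_inc
  (2 * n_T - 1 - sqrt((2 * n_T - 1)^2 - 8 * e_exc)) / 2
}

#' Fraction of correctly placed residues
#'
#' `f = (n_T - n_exc) / n_T`, inheriting the continuity of
#' [excluded_nodes()]; ranges from `1 / n_T` to 1.
#'
#' @inheritParams excluded_nodes
#' @return Fraction `f`.
#' @export
fraction_included <- function(n_T, e_inc) {
  (n_T - excluded_nodes(n_T, e_inc)) / n_T
}

# Paired coordinate sets for the backbone alignment: standard and
# nonstandard residues contribute N, CA and carbonyl C; ions and cofactors
# contribute only their centroid atom.
backbone_pairs <- function(template, mapping) {
  tres <- template$residues
  ta <- list(); tb <- list()
  dropped <- 0L
  for (i in seq_len(nrow(tres))) {
    if (tres$category[i] %in% c("standard", "nonstandard")) {
      for (a in c("n", "ca", "c")) {
        t_xyz <- c(tres[[paste0(a, "_x")]][i], tres[[paste0(a, "_y")]][i],
                   tres[[paste0(a, "_z")]][i])
        s_xyz <- c(mapping[[paste0(a, "_x")]][i],
                   mapping[[paste0(a, "_y")]][i],
                   mapping[[paste0(a, "_z")]][i])
        if (anyNA(t_xyz) || anyNA(s_xyz)) {
          dropped <- dropped + 1L
          next
        }
        ta[[length(ta) + 1]] <- t_xyz
        tb[[length(tb) + 1]] <- s_xyz
      }
    } else {
      ta[[length(ta) + 1]] <- c(tres$x[i], tres$y[i], tres$z[i])
      tb[[length(tb) + 1]] <- c(mapping$x[i], mapping$y[i], mapping$z[i])
    }
  }
  if (dropped > 0) {
    warning(dropped, " backbone atom pair(s) missing; dropped from alignment")
  }
  list(a = do.call(rbind, ta), b = do.call(rbind, tb))
}

#' Backbone RMSD of aligned matched residues
#'
#' Superposes the template and matched-substructure atom sets (backbone
#' N/CA/C for amino-acid positions, centroid atom for ions and cofactors)
#' with the least-squares quaternion procedure and returns the residual
#' RMSD. Missing backbone atoms are dropped pairwise with a warning; fewer
#' than 3 surviving pairs is an error.
#'
#' @param template Resolved `site_template`.
#' @param mapping One mapping tibble from a `site_hits` row.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(template, mapping) {
  p <- backbone_pairs(template, mapping)
  if (is.null(p$a) || nrow(p$a) < 3) {
    stop("fewer than 3 paired atoms for backbone alignment")
  }
  quaternion_rmsd(p$a, p$b)
}

#' Mean distance from match centroids to the nearest pocket center
#'
#' For each pocket, the average of the distances from the match centroids
#' to the pocket center; the minimum over pockets is the descriptor `d_c`.
#' With no pockets a documented sentinel (50 Angstrom by default) is
#' returned, flagged via the `no_pocket` attribute.
#'
#' @param match_centroids Numeric n x 3 matrix of match centroid
#'   coordinates.
#' @param pockets List of `pocket` objects from [find_pockets()] /
#'   [read_pocket_gridpoints()].
#' @param sentinel Distance used when no pockets exist.
#' @return `d_c` in Angstrom (attribute `no_pocket` is `TRUE` when the
#'   sentinel was used).
#' @export
pocket_distance <- function(match_centroids, pockets,
                            sentinel = .sm_defaults$no_pocket_distance) {
  match_centroids <- as.matrix(match_centroids)
  if (length(pockets) == 0) {
    return(structure(sentinel, no_pocket = TRUE))
  }
  means <- vapply(pockets, function(p) {
    mean(sqrt(colSums((t(match_centroids) - p$center)^2)))
  }, numeric(1))
  structure(min(means), no_pocket = FALSE)
}

#' Interaction descriptor
#'
#' Extrinsic interaction term `f * e_inc / (d_c + 0.1)`; the 0.1 Angstrom
#' constant keeps the term finite when the match sits exactly on a pocket
#' center.
#'
#' @param f Fraction of correctly placed residues.
#' @param e_inc Included-edge count.
#' @param d_c Pocket-center distance in Angstrom.
#' @return Interaction term value.
#' @export
interaction_term <- function(f, e_inc, d_c) {
  stopifnot(is.finite(f), is.finite(e_inc), is.finite(d_c), d_c >= 0)
  f * e_inc / (d_c + 0.1)
}

#' Compute the full descriptor vector for a complete match
#'
#' Assembles the seven rescoring descriptors for one complete match:
#' rmsddm, included-edge count, excluded-node estimate and fraction of
#' correctly placed residues, removed-standard-residue count (carried from
#' template reduction), backbone superposition RMSD, pocket-center distance
#' (with its reciprocal transform), and the interaction term.
#'
#' @param template Resolved `site_template` (possibly reduced).
#' @param hits A `site_hits` object.
#' @param pockets List of pockets for the target (may be empty).
#' @param n_removed Removed standard residues from [reduce_template()].
#' @param config A [search_config()] (for the inclusion threshold).
#' @return Tibble with one row per hit: `rank`, `rmsddm`, `e_inc`, `n_exc`,
#'   `f`, `n_removed`, `backbone_rmsd`, `d_c`, `inv_dc`, `interaction`,
#'   `n_T`.
#' @export
compute_descriptors <- function(template, hits, pockets = list(),
                                n_removed = 0L, config = search_config()) {
  stopifnot(inherits(hits, "site_hits"))
  n <- template$n
  d_T <- template$dmat
  purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    mp <- hits$mapping[[i]]
    xyz <- as.matrix(mp[, c("x", "y", "z")])
    d_S <- coord_dist(xyz)
    e_inc <- count_included_edges(d_T, d_S, config$inclusion_threshold)
    f <- fraction_included(n, e_inc)
    d_c <- pocket_distance(xyz, pockets)
    tibble::tibble(
      rank = hits$rank[i],
      rmsddm = rmsddm(d_T, d_S),
      e_inc = e_inc,
      n_exc = excluded_nodes(n, e_inc),
      f = f,
      n_removed = as.integer(n_removed),
      backbone_rmsd = backbone_rmsd(template, mp),
      d_c = as.numeric(d_c),
      inv_dc = 1 / (as.numeric(d_c) + 0.1),
      interaction = interaction_term(f, e_inc, as.numeric(d_c)),
      n_T = n
    )
  })
}
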