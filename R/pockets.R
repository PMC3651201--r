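#' Pocket objects
#'
#' A pocket is a cluster of grid points inside a surface concavity; its
#' center is the simple average of the gridpoint coordinates and is the
#' only pocket property consumed downstream (descriptor 6).
#'
#' @param gridpoints Numeric n x 3 matrix of gridpoint coordinates.
#' @return A `pocket` list with `gridpoints` and `center`.
#' @export
new_pocket <- function(gridpoints) {
  gridpoints <- as.matrix(gridpoints)
  stopifnot(nrow(gridpoints) >= 1, ncol(gridpoints) == 3)
  structure(list(gridpoints = gridpoints, center = colMeans(gridpoints)),
            class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> %d gridpoints, center (%.2f, %.2f, %.2f)\n",
              nrow(x$gridpoints), x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# All heavy-atom coordinates of a structure (backbone + HET atoms).
structure_atoms <- function(target) {
  res <- target$residues
  coords <- list()
  for (a in c("n", "ca", "c")) {
    m <- as.matrix(res[, paste0(a, c("_x", "_y", "_z"))])
    coords[[a]] <- m[!is.na(m[, 1]), , drop = FALSE]
  }
  het <- as.matrix(target$het_atoms[, c("x", "y", "z")])
  out <- do.call(rbind, c(coords, list(het)))
  dimnames(out) <- NULL
  out
}

# Shift a 3D logical array by an integer cell offset, padding with FALSE.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    if (off[k] >= 0) {
      if (off[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - off[k]) + off[k]
      dst[[k]] <- seq_len(d[k] - off[k])
    } else {
      if (-off[k] >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + off[k])
      dst[[k]] <- seq_len(d[k] + off[k]) - off[k]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Cluster grid points into single-linkage components at a cutoff using a
# cell-hashed neighbor graph (avoids the O(n^2) distance matrix).
cluster_points <- function(pts, cutoff) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  cell <- floor(pts / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cell_members <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  edges <- list()
  for (i in seq_len(n)) {
    neigh_keys <- paste(cell[i, 1] + offs[, 1], cell[i, 2] + offs[, 2],
                        cell[i, 3] + offs[, 3])
    cand <- unlist(cell_members[neigh_keys], use.names = FALSE)
    cand <- cand[cand > i]
    if (length(cand) == 0) next
    d2 <- colSums((t(pts[cand, , drop = FALSE]) - pts[i, ])^2)
    hit <- cand[d2 <= cutoff^2]
    if (length(hit)) edges[[length(edges) + 1]] <- rbind(i, hit)
  }
  if (length(edges) == 0) return(seq_len(n))
  el <- t(do.call(cbind, edges))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::components(g)$membership
}

#' Geometric pocket detection by buriedness scanning
#'
#' Grid-based stand-in for an external pocket finder, pluggable via
#' [read_pocket_gridpoints()]. A regular grid is laid over the structure's
#' bounding box; grid cells closer than `clash` to any heavy atom are
#' protein; each remaining cell is scored by how many of the 7 scan lines
#' (3 axes + 4 cube diagonals) meet protein within `scan` Angstrom on
#' *both* sides. Cells blocked on at least `min_blocked` of the 7 lines
#' are buried, clustered by single linkage at twice the grid spacing, and
#' clusters of at least `min_points` cells become pockets.
#'
#' @param target A `target_structure`.
#' @param grid_spacing Grid spacing in Angstrom.
#' @param clash Minimum gridpoint-to-atom distance.
#' @param scan Scan range along each direction.
#' @param min_blocked Minimum blocked scan lines (of 7) for burial.
#' @param min_points Minimum cluster size retained as a pocket.
#' @return List of `pocket` objects (possibly empty).
#' @export
find_pockets <- function(target, grid_spacing = 1.0, clash = 1.6,
                         scan = 8, min_blocked = 5, min_points = 10) {
  atoms <- structure_atoms(target)
  if (nrow(atoms) == 0) return(list())
  lo <- apply(atoms, 2, min) - 2 * grid_spacing
  hi <- apply(atoms, 2, max) + 2 * grid_spacing
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = grid_spacing))
  d <- vapply(ax, length, integer(1))

  # protein occupancy: cells whose center lies within `clash` of an atom
  occ <- array(FALSE, d)
  r_cells <- ceiling(clash / grid_spacing)
  offs <- as.matrix(expand.grid(-r_cells:r_cells, -r_cells:r_cells,
                                -r_cells:r_cells))
  for (i in seq_len(nrow(atoms))) {
    ci <- vapply(1:3, function(k) {
      round((atoms[i, k] - lo[k]) / grid_spacing) + 1
    }, numeric(1))
    cells <- sweep(offs, 2, ci, "+")
    keep <- cells[, 1] >= 1 & cells[, 1] <= d[1] &
      cells[, 2] >= 1 & cells[, 2] <= d[2] &
      cells[, 3] >= 1 & cells[, 3] <= d[3]
    cells <- cells[keep, , drop = FALSE]
    ctr <- cbind(ax[[1]][cells[, 1]], ax[[2]][cells[, 2]],
                 ax[[3]][cells[, 3]])
    hit <- colSums((t(ctr) - atoms[i, ])^2) <= clash^2
    occ[cells[hit, , drop = FALSE]] <- TRUE
  }

  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  n_blocked <- array(0L, d)
  for (dd in seq_len(nrow(dirs))) {
    step_len <- sqrt(sum(dirs[dd, ]^2)) * grid_spacing
    n_steps <- floor(scan / step_len)
    if (n_steps < 1) next
    hit_pos <- array(FALSE, d)
    hit_neg <- array(FALSE, d)
    for (s in seq_len(n_steps)) {
      hit_pos <- hit_pos | shift_array(occ, -s * dirs[dd, ])
      hit_neg <- hit_neg | shift_array(occ, s * dirs[dd, ])
    }
    n_blocked <- n_blocked + as.integer(hit_pos & hit_neg)
  }

  buried_idx <- which(!occ & n_blocked >= min_blocked, arr.ind = TRUE)
  if (nrow(buried_idx) == 0) return(list())
  buried <- cbind(ax[[1]][buried_idx[, 1]], ax[[2]][buried_idx[, 2]],
                  ax[[3]][buried_idx[, 3]])

  membership <- cluster_points(buried, 2 * grid_spacing)
  pockets <- list()
  for (cl in sort(unique(membership))) {
    pts <- buried[membership == cl, , drop = FALSE]
    if (nrow(pts) >= min_points) {
      pockets[[length(pockets) + 1]] <- new_pocket(pts)
    }
  }
  pockets
}

#' Import externally computed pocket gridpoints
#'
#' Builds pockets verbatim from a gridpoint file, bypassing the geometric
#' scan, so output from an external pocket finder can be plugged in. The
#' file is either a whitespace-separated xyz table with a `pocket` id
#' column (`pocket x y z`) or a PDB file whose HETATM records carry one
#' pocket per residue number.
#'
#' @param file Path to the gridpoint file.
#' @return List of `pocket` objects.
#' @export
read_pocket_gridpoints <- function(file) {
  first <- readLines(file, n = 1)
  if (grepl("^(ATOM|HETATM)", first)) {
    pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE))
    at <- pdb$atom
    groups <- split(seq_len(nrow(at)), at$resno)
  } else {
    tab <- readr::read_table(file, show_col_types = FALSE)
    stopifnot(all(c("pocket", "x", "y", "z") %in% names(tab)))
    at <- tab
    groups <- split(seq_len(nrow(tab)), tab$pocket)
  }
  purrr::map(unname(groups), function(idx) {
    new_pocket(as.matrix(at[idx, c("x", "y", "z")]))
  })
}
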