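# Independent Kabsch (SVD) superposition oracle for descriptor 5 checks;
# deliberately a different algorithm from the package's quaternion route.
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fit <- bc %*% R
  sqrt(mean(rowSums((fit - ac)^2)))
}

empty_het <- function() {
  tibble::tibble(resid = character(0), chain = character(0),
                 resno = integer(0), elety = character(0),
                 x = numeric(0), y = numeric(0), z = numeric(0))
}

# Build a target_structure from a residue spec tibble with columns
# code, chain, resno, x, y, z (backbone copied onto CA with small offsets
# unless backbone = FALSE).
make_structure <- function(spec, id = "fix", het = empty_het(),
                           backbone = TRUE) {
  res <- tibble::tibble(
    chain = spec$chain, resno = as.integer(spec$resno), insert = "",
    resid = spec$code,
    n_x = if (backbone) spec$x + 1.2 else NA_real_,
    n_y = if (backbone) spec$y + 0.5 else NA_real_,
    n_z = if (backbone) spec$z else NA_real_,
    ca_x = spec$x, ca_y = spec$y, ca_z = spec$z,
    c_x = if (backbone) spec$x - 1.0 else NA_real_,
    c_y = if (backbone) spec$y + 0.9 else NA_real_,
    c_z = if (backbone) spec$z else NA_real_,
    has_backbone = backbone
  )
  new_target_structure(id, res, het)
}

# Random rigid-body transform of an n x 3 matrix.
rigid_transform <- function(xyz, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  t(R %*% t(as.matrix(xyz))) + matrix(runif(3, -20, 20), nrow(xyz), 3,
                                      byrow = TRUE)
}

# Small planted search instance used across search tests.
make_instance <- function(n_T, seed, jitter = 0.05, n_decoys = 8,
                          ion_prob = 0) {
  tpl <- generate_template(n_T, seed = seed, ec = "1.2.3.4",
                           site_id = "TST-0", ion_prob = ion_prob)
  pl <- plant_in_decoy(tpl, jitter_sigma = jitter, n_decoys = n_decoys,
                       seed = seed + 1000, target_id = "inst", box = 25)
  pool <- build_candidate_pool(pl$target, tpl)
  list(template = tpl, planted = pl, pool = pool)
}

hit_signature <- function(hits) {
  paste(sprintf("%.9f", hits$rmsddm),
        vapply(hits$mapping, function(mp) {
          paste(mp$chain, mp$resno, collapse = "|")
        }, character(1)))
}
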