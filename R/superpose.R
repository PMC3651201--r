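#' Least-squares quaternion superposition RMSD
#'
#' Optimal rigid-body superposition of two one-to-one paired coordinate
#' sets by the quaternion eigenvalue method: the optimal rotation's
#' residual is obtained from the largest eigenvalue of the 4 x 4 key matrix
#' built from the cross-covariance of the centered sets, and the RMSD
#' follows without explicitly constructing the rotation.
#'
#' @param a,b Numeric n x 3 coordinate matrices, rows paired.
#' @return Post-superposition RMSD in Angstrom.
#' @export
quaternion_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  n <- nrow(a)
  if (n < 3) stop("need at least 3 paired atoms for superposition")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  ga <- sum(ac^2)
  gb <- sum(bc^2)
  M <- crossprod(ac, bc)  # 3x3 cross-covariance
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- max(0, (ga + gb - 2 * lambda_max) / n)
  sqrt(msd)
}
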