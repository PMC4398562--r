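## Row-mode GSVD of two column-matched matrices via QR + CS decomposition.

numericalRank <- function(A, name = deparse(substitute(A))) {
  s <- svd(A, nu = 0, nv = 0)$d
  tol <- max(dim(A)) * .Machine$double.eps * s[1L]
  sum(s > tol)
}

#' Generalized singular value decomposition of two matrices
#'
#' Computes the exact simultaneous factorization \eqn{D_1 = U_1 \Sigma_1
#' V^T}, \eqn{D_2 = U_2 \Sigma_2 V^T} of two real full column-rank matrices
#' sharing their column dimension. The route is numerically stable: QR of
#' the stacked matrix \code{rbind(D1, D2)} followed by a cosine-sine
#' decomposition of the partitioned orthonormal factor (via an SVD of the
#' upper block), so \eqn{D_i^T D_i} is never formed and
#' \eqn{\Sigma_1^2 + \Sigma_2^2 = I} before the rows of \eqn{V^T} are
#' rescaled to unit norm (the rescaling is absorbed equally into both
#' sigma vectors, leaving all ratios and angular distances unchanged).
#'
#' Factors are ordered by decreasing \eqn{\sigma_{1,a}/\sigma_{2,a}}, i.e.
#' decreasing angular distance: index 1 is the direction most exclusive to
#' \code{D1}, index N the one most exclusive to \code{D2}. Each row of
#' \eqn{V^T} is sign-fixed so its largest-magnitude entry is positive (the
#' factorization is unique only up to phase factors of +-1, and only up to
#' rotation inside blocks of tied ratios); the compensating sign is
#' absorbed into the corresponding columns of \code{U1} and \code{U2}.
#'
#' @param D1,D2 real matrices with the same number of columns N,
#'   \code{nrow >= N}, each of full column rank
#' @return a [MatrixGSVD-class] object
#' @examples
#' f <- matrixGSVD(diag(c(2, 1)), diag(2))
#' f@sigma1 / f@sigma2    # 2, 1
#' @export
matrixGSVD <- function(D1, D2) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- ncol(D1)
  if (ncol(D2) != n)
    stop(sprintf("column dimensions differ: ncol(D1) = %d, ncol(D2) = %d",
                 n, ncol(D2)))
  if (nrow(D1) < n || nrow(D2) < n)
    stop("each input must have at least as many rows as columns")
  r1 <- numericalRank(D1)
  if (r1 < n)
    stop(sprintf("D1 is rank deficient: numerical rank %d < %d columns", r1, n))
  r2 <- numericalRank(D2)
  if (r2 < n)
    stop(sprintf("D2 is rank deficient: numerical rank %d < %d columns", r2, n))

  k1 <- nrow(D1)
  qrS <- qr(rbind(D1, D2))
  Q <- qr.Q(qrS)[, seq_len(n), drop = FALSE]
  Rq <- qr.R(qrS)[seq_len(n), , drop = FALSE]
  Q1 <- Q[seq_len(k1), , drop = FALSE]
  Q2 <- Q[-seq_len(k1), , drop = FALSE]

  ## CS decomposition: Q1 = U1 C W^T with C = diag(cosines of the
  ## complementary angle); then Q2 W has orthogonal columns of norm s,
  ## since (Q2 W)^T (Q2 W) = W^T (I - Q1^T Q1) W = I - C^2.
  sv <- svd(Q1)
  cs <- pmin(sv$d, 1)
  U1 <- sv$u
  W <- sv$v
  Q2W <- Q2 %*% W
  sn <- sqrt(colSums(Q2W^2))
  if (any(cs <= 0) || any(sn <= 0))
    stop("degenerate CS decomposition: an input is numerically rank deficient")
  U2 <- sweep(Q2W, 2L, sn, "/")

  ## D_i = Q_i Rq = U_i diag(c or s) (W^T Rq); svd() already sorts the
  ## cosines decreasingly, hence c/s ratios decreasingly (stable in ties).
  Vt <- crossprod(W, Rq)           # N x N, invertible
  sigma1 <- cs
  sigma2 <- sn

  ## unit-norm rows of V^T; scale absorbed equally into sigma1 and sigma2
  rn <- sqrt(rowSums(Vt^2))
  Vt <- Vt / rn
  sigma1 <- sigma1 * rn
  sigma2 <- sigma2 * rn

  ## sign convention: largest-magnitude entry of each row of V^T positive
  sgn <- vapply(seq_len(n), function(a) {
    r <- Vt[a, ]
    if (r[which.max(abs(r))] < 0) -1 else 1
  }, numeric(1))
  Vt <- Vt * sgn
  U1 <- sweep(U1, 2L, sgn, "*")
  U2 <- sweep(U2, 2L, sgn, "*")

  new("MatrixGSVD", U1 = U1, U2 = U2, sigma1 = sigma1, sigma2 = sigma2,
      V = t(Vt), theta = angularDistances(sigma1, sigma2))
}

#' GSVD angular distances
#'
#' \eqn{\theta_a = \arctan(\sigma_{1,a}/\sigma_{2,a}) - \pi/4}. Since the
#' generalized singular values are positive, each distance lies in
#' \eqn{[-\pi/4, \pi/4]}: +pi/4 marks a direction exclusive to dataset 1,
#' -pi/4 one exclusive to dataset 2, and 0 a direction of equal
#' significance in (common to) both. Swapping the arguments negates the
#' result (the measure is antisymmetric in the two datasets).
#'
#' @param sigma1,sigma2 strictly positive numeric vectors of equal length
#' @return numeric vector of angular distances, radians
#' @examples
#' angularDistances(2, 1)   # atan(2) - pi/4
#' @export
angularDistances <- function(sigma1, sigma2) {
  if (length(sigma1) != length(sigma2))
    stop("sigma1 and sigma2 must have equal length")
  if (any(sigma1 <= 0) || any(sigma2 <= 0))
    stop("generalized singular values must be strictly positive")
  atan2(sigma1, sigma2) - pi / 4
}

#' Generalized-eigenproblem oracle for GSVD ratios
#'
#' Independent reference route for the squared ratios
#' \eqn{(\sigma_{1,a}/\sigma_{2,a})^2}: they are the eigenvalues of the
#' symmetric-definite pencil \eqn{(D_1^T D_1, D_2^T D_2)}. Solved here by
#' reducing with a Cholesky factor of \eqn{D_2^T D_2}. Less stable than
#' [matrixGSVD()] (it squares the condition number); intended for
#' cross-checks, not production use.
#'
#' @inheritParams matrixGSVD
#' @return positive ratios sorted decreasingly
#' @export
gsvdRatioOracle <- function(D1, D2) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- ncol(D1)
  if (ncol(D2) != n) stop("column dimensions differ")
  if (numericalRank(D1) < n) stop("D1 is rank deficient")
  if (numericalRank(D2) < n) stop("D2 is rank deficient")
  A <- crossprod(D1)
  B <- crossprod(D2)
  Lc <- chol(B)                       # B = Lc^T Lc, Lc upper triangular
  M <- forwardsolve(t(Lc), t(forwardsolve(t(Lc), A)))  # Lc^-T A Lc^-1
  ## symmetrize against roundoff before eigen
  M <- (M + t(M)) / 2
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(lam, 0))
}
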