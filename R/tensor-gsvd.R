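## Tensor GSVD: unfoldings, shared right factors, core tensors, significance
## fractions, angular distances, and the HOSVD special case.

asValues <- function(x) {
  if (is(x, "CopyNumberTensor")) x <- tensorValues(x)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Tensor unfoldings (matricizations)
#'
#' \code{unfoldRow} flattens a K x L x M tensor into K x (L*M), appending
#' the LM patient-platform columns with the platform index m fastest:
#' column n = (l - 1) * M + m. This convention makes the Kronecker
#' reconstruction identity \eqn{D = U R (V_x^T \otimes V_y^T)} hold
#' literally. \code{unfoldX} stacks the K*M rows (m fastest within probe)
#' into a (K*M) x L matrix whose column l is the vectorized patient slice;
#' \code{unfoldY} stacks K*L rows (l fastest) into (K*L) x M.
#' \code{foldRow} inverts \code{unfoldRow}.
#'
#' @param x a [CopyNumberTensor-class] or a numeric K x L x M array
#' @return a numeric matrix (or array for \code{foldRow})
#' @examples
#' a <- array(seq_len(8), c(2, 2, 2))
#' all(foldRow(unfoldRow(a), 2, 2) == a)
#' @export
unfoldRow <- function(x) {
  v <- asValues(x)
  d <- dim(v)
  matrix(aperm(v, c(1L, 3L, 2L)), d[1L], d[2L] * d[3L])
}

#' @rdname unfoldRow
#' @param A a K x (L*M) matrix with columns in (l - 1) * M + m order
#' @param L,M patient and platform dimensions
#' @export
foldRow <- function(A, L, M) {
  stopifnot(ncol(A) == L * M)
  aperm(array(A, c(nrow(A), M, L)), c(1L, 3L, 2L))
}

#' @rdname unfoldRow
#' @export
unfoldX <- function(x) {
  v <- asValues(x)
  d <- dim(v)
  matrix(aperm(v, c(3L, 1L, 2L)), d[1L] * d[3L], d[2L])
}

#' @rdname unfoldRow
#' @export
unfoldY <- function(x) {
  v <- asValues(x)
  d <- dim(v)
  matrix(aperm(v, c(2L, 1L, 3L)), d[1L] * d[2L], d[3L])
}

## multiply tensor t (d1 x d2 x d3) along `mode` by matrix A (p x d_mode)
modeProduct <- function(t, A, mode) {
  d <- dim(t)
  perm <- switch(mode, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  tp <- aperm(t, perm)
  dp <- dim(tp)
  res <- A %*% matrix(tp, dp[1L], dp[2L] * dp[3L])
  res <- array(res, c(nrow(A), dp[2L], dp[3L]))
  aperm(res, order(perm))
}

checkFullRank <- function(A, what) {
  r <- numericalRank(A)
  if (r < ncol(A))
    stop(sprintf("%s is rank deficient: numerical rank %d < %d columns",
                 what, r, ncol(A)))
  invisible(TRUE)
}

#' Tensor GSVD of two column-matched, row-independent tensors
#'
#' Simultaneously decomposes two third-order tensors \code{D1} (K1 x L x M)
#' and \code{D2} (K2 x L x M) sharing their patient (L) and platform (M)
#' dimensions into weighted sums of LM paired rank-1 subtensors,
#' \eqn{D_i = R_i \times_a U_i \times_b V_x \times_c V_y}. The arraylets
#' \code{U_i} and shared row-mode factor come from the GSVD of the row-mode
#' unfoldings; \code{Vx} and \code{Vy} from the GSVDs of the x- and y-mode
#' unfoldings, each ordered by its own GSVD ratio. Cores are computed as
#' \eqn{R_i = \Sigma_i V^T (V_x^{-T} \otimes V_y^{-T})} via two small
#' mode-wise solves (the LM x LM Kronecker matrix is never materialized),
#' which also makes the ratio identity \eqn{R_{1,abc}/R_{2,abc} =
#' \sigma_{1,a}/\sigma_{2,a}} hold to machine precision.
#'
#' Arraylet index a = 1 is the direction most exclusive to dataset 1
#' (e.g. the tumor cohort); a = LM the one most exclusive to dataset 2.
#' With M = 1 the decomposition reduces to the matrix GSVD; with a first
#' tensor whose row unfolding is the identity it reduces to the HOSVD of
#' the second tensor.
#'
#' @param D1,D2 [CopyNumberTensor-class] objects or numeric arrays with
#'   matched L and M; requires \code{K_i >= L * M} and all unfoldings of
#'   full column rank
#' @return a [TensorGSVD-class] object
#' @seealso [reconstructTensor()], [subtensorSignificance()],
#'   [tensorAngularDistance()], [selectSignificantSubtensor()]
#' @export
tensorGSVD <- function(D1, D2) {
  ids <- list(
    probes1 = if (is(D1, "CopyNumberTensor")) probeIds(D1) else NULL,
    probes2 = if (is(D2, "CopyNumberTensor")) probeIds(D2) else NULL,
    patients = if (is(D1, "CopyNumberTensor")) patientIds(D1) else NULL,
    platforms = if (is(D1, "CopyNumberTensor")) platformIds(D1) else NULL
  )
  v1 <- asValues(D1); v2 <- asValues(D2)
  d1 <- dim(v1); d2 <- dim(v2)
  if (d1[2L] != d2[2L] || d1[3L] != d2[3L])
    stop(sprintf(
      "column dimensions must match one-to-one: L = %d vs %d, M = %d vs %d",
      d1[2L], d2[2L], d1[3L], d2[3L]))
  L <- d1[2L]; M <- d1[3L]; lm <- L * M
  if (d1[1L] < lm || d2[1L] < lm)
    stop(sprintf("row dimensions must satisfy K >= L*M = %d (got K1 = %d, K2 = %d)",
                 lm, d1[1L], d2[1L]))

  A1 <- unfoldRow(v1); A2 <- unfoldRow(v2)
  checkFullRank(A1, "row-mode unfolding of dataset 1")
  checkFullRank(A2, "row-mode unfolding of dataset 2")
  X1 <- unfoldX(v1); X2 <- unfoldX(v2)
  checkFullRank(X1, "x-mode unfolding of dataset 1")
  checkFullRank(X2, "x-mode unfolding of dataset 2")
  Y1 <- unfoldY(v1); Y2 <- unfoldY(v2)
  checkFullRank(Y1, "y-mode unfolding of dataset 1")
  checkFullRank(Y2, "y-mode unfolding of dataset 2")

  rowFit <- matrixGSVD(A1, A2)
  xFit <- matrixGSVD(X1, X2)
  yFit <- matrixGSVD(Y1, Y2)
  Vx <- xFit@V
  Vy <- yFit@V

  ## W = fold(V^T) x_b Vx^-1 x_c Vy^-1 ; R_i = diag(sigma_i) W
  W <- foldRow(t(rowFit@V), L, M)
  W <- modeProduct(W, solve(Vx), 2L)
  W <- modeProduct(W, solve(Vy), 3L)
  R1 <- W * rowFit@sigma1     # recycles along the first (arraylet) dim
  R2 <- W * rowFit@sigma2

  new("TensorGSVD",
      U1 = rowFit@U1, U2 = rowFit@U2, Vx = Vx, Vy = Vy,
      R1 = R1, R2 = R2,
      sigmaRow1 = rowFit@sigma1, sigmaRow2 = rowFit@sigma2,
      sigmaX1 = xFit@sigma1, sigmaX2 = xFit@sigma2,
      sigmaY1 = yFit@sigma1, sigmaY2 = yFit@sigma2,
      thetaRow = rowFit@theta,
      patientIds = ids$patients %||% sprintf("patient_%d", seq_len(L)),
      platformIds = ids$platforms %||% sprintf("platform_%d", seq_len(M)),
      probeIds1 = ids$probes1 %||% sprintf("probe_%d", seq_len(d1[1L])),
      probeIds2 = ids$probes2 %||% sprintf("probe_%d", seq_len(d2[1L])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct a dataset from its tensor GSVD
#'
#' Triple tensor-matrix contraction \eqn{R_i \times_a U_i \times_b V_x
#' \times_c V_y}; equals the corresponding input tensor up to numerical
#' round-off. Zeroing all but one core entry before calling this yields a
#' single weighted rank-1 subtensor.
#'
#' @param fit a [TensorGSVD-class]
#' @param dataset 1 or 2
#' @param core optional replacement core array (LM x L x M), e.g. with
#'   entries zeroed to isolate subtensors
#' @return numeric K_i x L x M array
#' @export
reconstructTensor <- function(fit, dataset = 1L, core = NULL) {
  stopifnot(is(fit, "TensorGSVD"), dataset %in% c(1L, 2L))
  R <- core %||% coreTensor(fit, dataset)
  U <- arraylets(fit, dataset)
  out <- modeProduct(R, U, 1L)
  out <- modeProduct(out, fit@Vx, 2L)
  modeProduct(out, fit@Vy, 3L)
}

#' Subtensor significance fractions
#'
#' The significance of subtensor (a, b, c) in dataset i is proportional to
#' the squared tensor generalized singular value:
#' \eqn{P_{i,abc} = R_{i,abc}^2 / \sum R_{i,abc}^2}. Fractions sum to 1.
#'
#' @param R a core array (LM x L x M), or a [TensorGSVD-class] with
#'   \code{dataset} selecting the core
#' @param dataset 1 or 2, used when \code{R} is a fit object
#' @return array of fractions, same shape as the core
#' @export
subtensorSignificance <- function(R, dataset = 1L) {
  if (is(R, "TensorGSVD")) R <- coreTensor(R, dataset)
  tot <- sum(R^2)
  if (tot == 0) stop("all-zero core tensor: significance undefined")
  R^2 / tot
}

#' Tensor GSVD angular distances
#'
#' \eqn{\Theta_{abc} = \arctan(R_{1,abc}/R_{2,abc}) - \pi/4} wherever the
#' ratio is defined; entries where both core values vanish are flagged
#' \code{NA} (the ratio is undefined there, not zero). By the decomposition's
#' ratio identity, \eqn{\Theta_{abc} = \theta_a}, the row-mode angular
#' distance of arraylet a, so \eqn{|\Theta| \le \pi/4}: +pi/4 marks a
#' subtensor exclusive to dataset 1, -pi/4 exclusive to dataset 2, 0 a
#' subtensor common to both.
#'
#' @param R1,R2 core arrays (LM x L x M)
#' @param sigmaRow1,sigmaRow2 optional row-mode generalized singular values;
#'   when supplied, the row-mode distances are returned alongside
#' @return list with \code{Theta} (array, NA where undefined) and
#'   \code{thetaRow} (vector, or NULL when sigmas are not supplied)
#' @export
tensorAngularDistance <- function(R1, R2, sigmaRow1 = NULL, sigmaRow2 = NULL) {
  stopifnot(identical(dim(R1), dim(R2)))
  tol <- 100 * .Machine$double.eps * max(abs(R1), abs(R2))
  undef <- abs(R1) <= tol & abs(R2) <= tol
  Theta <- atan(R1 / R2) - pi / 4
  Theta[undef] <- NA_real_
  thetaRow <- if (!is.null(sigmaRow1) && !is.null(sigmaRow2))
    angularDistances(sigmaRow1, sigmaRow2) else NULL
  list(Theta = Theta, thetaRow = thetaRow)
}

#' Angular distance of an arbitrary probe pattern
#'
#' Evaluates the generalized-singular-value ratio at a given probe pattern
#' rather than at a decomposition index: with unit patterns \eqn{u_i} in
#' each dataset's probe space, \eqn{\sigma_i(u) = \|D_i^T u_i\| =
#' \|V \Sigma_i U_i^T u_i\|} and the angular distance is
#' \eqn{\arctan(\sigma_1/\sigma_2) - \pi/4}, computed entirely from the
#' factorization. When \eqn{u_i} is the a-th paired arraylet this
#' reproduces the row-mode angular distance \eqn{\theta_a} exactly.
#'
#' This is the right tool for patterns whose ratio falls inside a
#' quasi-degenerate part of the spectrum — notably patterns common to both
#' datasets (ratio near 1, where factors are unique only up to rotation
#' among nearly tied ratios) — for which no single subtensor is
#' identifiable.
#'
#' @param fit a [TensorGSVD-class]
#' @param pattern1 per-probe vector in dataset 1's probe space
#' @param pattern2 per-probe vector in dataset 2's probe space (the same
#'   pattern as represented on dataset 2's probes)
#' @return angular distance in \eqn{[-\pi/4, \pi/4]}
#' @export
patternAngularDistance <- function(fit, pattern1, pattern2) {
  stopifnot(is(fit, "TensorGSVD"),
            length(pattern1) == nrow(fit@U1),
            length(pattern2) == nrow(fit@U2))
  u1 <- pattern1 / sqrt(sum(pattern1^2))
  u2 <- pattern2 / sqrt(sum(pattern2^2))
  n1 <- sqrt(sum((rowModeV(fit) %*% (fit@sigmaRow1 * crossprod(fit@U1, u1)))^2))
  n2 <- sqrt(sum((rowModeV(fit) %*% (fit@sigmaRow2 * crossprod(fit@U2, u2)))^2))
  atan2(n1, n2) - pi / 4
}

## shared row-mode right factor V, reassembled from the stored cores:
## R_i = Sigma_i V^T (Vx^-T x Vy^-T)  =>  V^T = Sigma_1^-1 R1_unf (Vx^T x Vy^T)
rowModeV <- function(fit) {
  Vt <- (unfoldRow(fit@R1) / fit@sigmaRow1) %*%
    kronecker(t(fit@Vx), t(fit@Vy))
  t(Vt)
}

#' Higher-order SVD (Tucker decomposition with orthonormal factors)
#'
#' Mode factors are the left singular vectors of the three unfoldings; the
#' core is the tensor contracted with their transposes. Used as the
#' single-tensor special case the tensor GSVD reduces to when the first
#' tensor's row unfolding is the identity.
#'
#' @param x a [CopyNumberTensor-class] or numeric array
#' @return list with \code{U} (list of three factor matrices), \code{core},
#'   and \code{d} (list of the mode singular values)
#' @export
hosvd <- function(x) {
  v <- asValues(x)
  s1 <- svd(unfoldRow(v))
  s2 <- svd(t(unfoldX(v)))   # mode-2 unfolding is L x (K*M)
  s3 <- svd(t(unfoldY(v)))
  core <- modeProduct(v, t(s1$u), 1L)
  core <- modeProduct(core, t(s2$u), 2L)
  core <- modeProduct(core, t(s3$u), 3L)
  list(U = list(s1$u, s2$u, s3$u), core = core,
       d = list(s1$d, s2$d, s3$d))
}

#' Select the most significant subtensor of one dataset
#'
#' Returns the index triple (a, b, c) maximizing the significance fraction
#' \eqn{P_{i,abc}} for the chosen dataset, with its angular distance and
#' significance in both datasets. Because arraylets are ordered by
#' decreasing angular distance, a = 1 marks the pattern most exclusive to
#' dataset 1; \code{exclusive} reports whether the selected subtensor
#' involves that most-exclusive arraylet (for dataset 2, a = LM). Ties in
#' the maximum beyond relative tolerance 1e-9 are broken to the
#' lexicographically lowest (a, b, c), with a warning.
#'
#' @param fit a [TensorGSVD-class]
#' @param dataset 1 or 2
#' @return list with \code{a}, \code{b}, \code{c}, \code{significance1},
#'   \code{significance2}, \code{theta}, \code{exclusive}
#' @export
selectSignificantSubtensor <- function(fit, dataset = 1L) {
  stopifnot(is(fit, "TensorGSVD"), dataset %in% c(1L, 2L))
  P <- subtensorSignificance(fit, dataset)
  pmax_ <- max(P)
  hits <- which(P >= pmax_ * (1 - 1e-9), arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    warning(sprintf(
      "%d subtensors tie for maximal significance; returning the lowest (a, b, c)",
      nrow(hits)))
    hits <- hits[order(hits[, 1L], hits[, 2L], hits[, 3L]), , drop = FALSE]
  }
  idx <- hits[1L, ]
  a <- idx[[1L]]; b <- idx[[2L]]; cc <- idx[[3L]]
  P1 <- subtensorSignificance(fit, 1L)
  P2 <- subtensorSignificance(fit, 2L)
  th <- tensorAngularDistance(fit@R1, fit@R2)$Theta[a, b, cc]
  lm <- length(fit@thetaRow)
  list(a = a, b = b, c = cc,
       significance1 = P1[a, b, cc], significance2 = P2[a, b, cc],
       theta = th,
       exclusive = if (dataset == 1L) a == 1L else a == lm)
}
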