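#' @import methods
NULL

#' CopyNumberTensor: probes x patients x platforms relative copy numbers
#'
#' Container for one cohort's copy-number measurements arranged as a
#' third-order tensor: \code{K} probes (rows, dataset-specific) by \code{L}
#' patients by \code{M} profiling platforms, with identifiers along each
#' dimension and an optional probe annotation table (probe id, chromosome,
#' arm, position) used to keep probes in genomic order.
#'
#' Values are relative copy numbers (e.g. log-ratios) and must be finite:
#' the decomposition requires complete tensors.
#'
#' @slot values numeric array, K x L x M
#' @slot probeIds character, length K, unique
#' @slot patientIds character, length L, unique
#' @slot platformIds character, length M, unique
#' @slot probeAnnotation data.frame with columns \code{probe_id},
#'   \code{arm}, \code{position} (zero-row data.frame when absent)
#'
#' @seealso [copyNumberTensor()], [tensorGSVD()]
#' @export
setClass("CopyNumberTensor",
  representation(
    values = "array",
    probeIds = "character",
    patientIds = "character",
    platformIds = "character",
    probeAnnotation = "data.frame"
  )
)

setValidity("CopyNumberTensor", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("values must be a three-dimensional array")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    return("values must be finite numeric (missing values are rejected)")
  d <- dim(v)
  if (length(object@probeIds) != d[1L])
    return(sprintf("probeIds length %d != K = %d", length(object@probeIds), d[1L]))
  if (length(object@patientIds) != d[2L])
    return(sprintf("patientIds length %d != L = %d", length(object@patientIds), d[2L]))
  if (length(object@platformIds) != d[3L])
    return(sprintf("platformIds length %d != M = %d", length(object@platformIds), d[3L]))
  if (anyDuplicated(object@probeIds)) return("duplicate probe ids")
  if (anyDuplicated(object@patientIds)) return("duplicate patient ids")
  if (anyDuplicated(object@platformIds)) return("duplicate platform ids")
  anno <- object@probeAnnotation
  if (nrow(anno) > 0L) {
    need <- c("probe_id", "arm", "position")
    if (!all(need %in% names(anno)))
      return("probeAnnotation must have columns probe_id, arm, position")
    if (nrow(anno) != d[1L] || !identical(as.character(anno$probe_id), object@probeIds))
      return("probeAnnotation rows must match probeIds in order")
  }
  TRUE
})

#' Construct a CopyNumberTensor
#'
#' @param values numeric K x L x M array (or K x L matrix, treated as M = 1)
#' @param probeIds,patientIds,platformIds identifiers; defaults are generated
#' @param probeAnnotation optional data.frame (probe_id, arm, position)
#'   aligned to \code{probeIds}
#' @return a [CopyNumberTensor-class] object
#' @examples
#' x <- copyNumberTensor(array(rnorm(2 * 3 * 2), c(2, 3, 2)))
#' dim(x)
#' @export
copyNumberTensor <- function(values, probeIds = NULL, patientIds = NULL,
                             platformIds = NULL, probeAnnotation = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  d <- dim(values)
  if (is.null(probeIds)) probeIds <- sprintf("probe_%d", seq_len(d[1L]))
  if (is.null(patientIds)) patientIds <- sprintf("patient_%d", seq_len(d[2L]))
  if (is.null(platformIds)) platformIds <- sprintf("platform_%d", seq_len(d[3L]))
  if (is.null(probeAnnotation))
    probeAnnotation <- data.frame(probe_id = character(0), arm = character(0),
                                  position = integer(0))
  new("CopyNumberTensor", values = values,
      probeIds = as.character(probeIds), patientIds = as.character(patientIds),
      platformIds = as.character(platformIds),
      probeAnnotation = probeAnnotation)
}

#' @describeIn CopyNumberTensor-class tensor dimensions (K, L, M)
#' @param x a CopyNumberTensor
#' @export
setMethod("dim", "CopyNumberTensor", function(x) dim(x@values))

#' Extract the value array of a CopyNumberTensor
#' @param object a CopyNumberTensor
#' @return numeric K x L x M array
#' @export
tensorValues <- function(object) object@values

#' @rdname tensorValues
#' @export
probeIds <- function(object) object@probeIds

#' @rdname tensorValues
#' @export
patientIds <- function(object) object@patientIds

#' @rdname tensorValues
#' @export
platformIds <- function(object) object@platformIds

#' @rdname tensorValues
#' @export
probeAnnotation <- function(object) object@probeAnnotation

setMethod("show", "CopyNumberTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("CopyNumberTensor: %d probes x %d patients x %d platforms\n",
              d[1L], d[2L], d[3L]))
  if (nrow(object@probeAnnotation) > 0L) {
    arms <- unique(object@probeAnnotation$arm)
    cat("  arms:", paste(arms, collapse = ", "), "\n")
  }
  cat("  value range: [", sprintf("%.4g", min(object@values)), ", ",
      sprintf("%.4g", max(object@values)), "]\n", sep = "")
})

#' MatrixGSVD: generalized SVD of two column-matched matrices
#'
#' Result of [matrixGSVD()]: the exact simultaneous factorization
#' \eqn{D_i = U_i \Sigma_i V^T} (i = 1, 2) of two full column-rank matrices
#' sharing their column dimension N. The \code{U_i} have orthonormal
#' columns; \code{V} is invertible and shared, with rows of \eqn{V^T}
#' scaled to unit norm; the generalized singular values \code{sigma1},
#' \code{sigma2} are positive and ordered by decreasing ratio
#' \eqn{\sigma_{1,a}/\sigma_{2,a}}, i.e. decreasing angular distance
#' \eqn{\theta_a = \arctan(\sigma_{1,a}/\sigma_{2,a}) - \pi/4}.
#'
#' @slot U1,U2 matrices with orthonormal columns (K1 x N, K2 x N)
#' @slot sigma1,sigma2 positive numeric vectors, length N
#' @slot V invertible N x N matrix (rows of V^T are the shared basis)
#' @slot theta numeric length N, angular distances in [-pi/4, pi/4]
#' @seealso [matrixGSVD()], [angularDistances()]
#' @export
setClass("MatrixGSVD",
  representation(U1 = "matrix", U2 = "matrix",
                 sigma1 = "numeric", sigma2 = "numeric",
                 V = "matrix", theta = "numeric")
)

setValidity("MatrixGSVD", function(object) {
  n <- ncol(object@U1)
  if (ncol(object@U2) != n || nrow(object@V) != n || ncol(object@V) != n)
    return("inconsistent factor dimensions")
  if (length(object@sigma1) != n || length(object@sigma2) != n ||
      length(object@theta) != n)
    return("inconsistent value-vector lengths")
  if (any(object@sigma1 <= 0) || any(object@sigma2 <= 0))
    return("generalized singular values must be strictly positive")
  TRUE
})

setMethod("show", "MatrixGSVD", function(object) {
  n <- ncol(object@U1)
  cat(sprintf("MatrixGSVD of %d x %d and %d x %d matrices\n",
              nrow(object@U1), n, nrow(object@U2), n))
  cat("  sigma1/sigma2 ratios:",
      paste(sprintf("%.4g", utils::head(object@sigma1 / object@sigma2, 5)),
            collapse = " "),
      if (n > 5) "..." else "", "\n")
  cat("  angular distances theta in [",
      sprintf("%.4f", min(object@theta)), ", ",
      sprintf("%.4f", max(object@theta)), "]\n", sep = "")
})

#' TensorGSVD: simultaneous decomposition of two column-matched tensors
#'
#' Result of [tensorGSVD()]: the exact simultaneous decomposition
#' \eqn{D_i = R_i \times_a U_i \times_b V_x \times_c V_y} of two
#' third-order tensors (K_i probes x L patients x M platforms) with
#' matched patient and platform dimensions. Columns of \code{U1}/\code{U2}
#' are the dataset-specific "arraylets"; rows of \eqn{V_x^T} and
#' \eqn{V_y^T} ("x-probelets" across patients, "y-probelets" across
#' platforms) are shared by both datasets. The core tensors \code{R1},
#' \code{R2} (LM x L x M) hold the tensor generalized singular values.
#'
#' @slot U1,U2 arraylet matrices K1 x LM, K2 x LM, orthonormal columns
#' @slot Vx L x L invertible; rows of Vx^T are unit-norm x-probelets
#' @slot Vy M x M invertible; rows of Vy^T are unit-norm y-probelets
#' @slot R1,R2 core arrays LM x L x M
#' @slot sigmaRow1,sigmaRow2 row-mode generalized singular values (length LM)
#' @slot sigmaX1,sigmaX2 x-mode values (length L)
#' @slot sigmaY1,sigmaY2 y-mode values (length M)
#' @slot thetaRow row-mode angular distances (length LM)
#' @slot patientIds,platformIds,probeIds1,probeIds2 identifiers carried over
#' @seealso [tensorGSVD()], [reconstructTensor()], [subtensorSignificance()]
#' @export
setClass("TensorGSVD",
  representation(
    U1 = "matrix", U2 = "matrix", Vx = "matrix", Vy = "matrix",
    R1 = "array", R2 = "array",
    sigmaRow1 = "numeric", sigmaRow2 = "numeric",
    sigmaX1 = "numeric", sigmaX2 = "numeric",
    sigmaY1 = "numeric", sigmaY2 = "numeric",
    thetaRow = "numeric",
    patientIds = "character", platformIds = "character",
    probeIds1 = "character", probeIds2 = "character"
  )
)

setValidity("TensorGSVD", function(object) {
  L <- nrow(object@Vx); M <- nrow(object@Vy)
  lm <- L * M
  if (ncol(object@U1) != lm || ncol(object@U2) != lm)
    return("U matrices must have LM columns")
  if (!identical(dim(object@R1), c(lm, L, M)) ||
      !identical(dim(object@R2), c(lm, L, M)))
    return("core tensors must be LM x L x M")
  if (length(object@sigmaRow1) != lm || length(object@thetaRow) != lm)
    return("row-mode value vectors must have length LM")
  TRUE
})

setMethod("show", "TensorGSVD", function(object) {
  L <- nrow(object@Vx); M <- nrow(object@Vy)
  cat(sprintf("TensorGSVD: %d- and %d-probe tensors, %d patients x %d platforms\n",
              nrow(object@U1), nrow(object@U2), L, M))
  cat(sprintf("  %d paired subtensor triples (a, b, c)\n", L * M * L * M))
  cat("  leading row-mode angular distances:",
      paste(sprintf("%.4f", utils::head(object@thetaRow, 5)), collapse = " "),
      "\n")
})

#' Accessors for TensorGSVD factors
#'
#' \code{arraylets} returns the probe-pattern basis \code{U_i} of one
#' dataset; \code{xProbelets}/\code{yProbelets} return the shared patient /
#' platform basis vectors as rows (i.e. \eqn{V_x^T}, \eqn{V_y^T});
#' \code{coreTensor} returns the LM x L x M array of tensor generalized
#' singular values.
#'
#' @param object a [TensorGSVD-class]
#' @param dataset 1 or 2
#' @return matrix or array as described
#' @export
arraylets <- function(object, dataset = 1L) {
  stopifnot(is(object, "TensorGSVD"), dataset %in% c(1L, 2L))
  if (dataset == 1L) object@U1 else object@U2
}

#' @rdname arraylets
#' @export
xProbelets <- function(object) t(object@Vx)

#' @rdname arraylets
#' @export
yProbelets <- function(object) t(object@Vy)

#' @rdname arraylets
#' @export
coreTensor <- function(object, dataset = 1L) {
  stopifnot(is(object, "TensorGSVD"), dataset %in% c(1L, 2L))
  if (dataset == 1L) object@R1 else object@R2
}

#' @rdname arraylets
#' @export
rowAngularDistances <- function(object) object@thetaRow
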