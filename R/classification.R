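## Patient stratification from a selected subtensor: median/sMAD threshold
## classification (discovery), Spearman arraylet-correlation classification
## (validation), robustness and platform-consistency checks, A/B/C groups.

#' Standardized median absolute deviation
#'
#' \code{1.4826 * median(|v - median(v)|)}: the median absolute deviation
#' rescaled by the consistency constant for the normal distribution, so it
#' estimates the standard deviation under normality. Returns 0 for a
#' constant vector (downstream thresholding then errors).
#'
#' @param v numeric vector, length >= 2
#' @return nonnegative scalar
#' @examples
#' smad(1:7)   # 2 * 1.4826
#' @export
smad <- function(v) {
  if (length(v) < 2L) stop("smad requires at least 2 values")
  stats::mad(v)   # default constant is 1.4826
}

newClassification <- function(patientIds, scores, labels, cutoff, direction,
                              robust = NA) {
  structure(
    list(patientIds = patientIds, scores = scores, labels = labels,
         cutoff = cutoff, direction = direction, robust = robust),
    class = "PatientClassification")
}

#' @export
print.PatientClassification <- function(x, ...) {
  cat(sprintf("PatientClassification: %d patients (%d high, %d low)\n",
              length(x$labels), sum(x$labels == "high"),
              sum(x$labels == "low")))
  cat(sprintf("  cutoff %.6g; hypothesized favorable label: %s; robust: %s\n",
              x$cutoff, x$direction, format(x$robust)))
  invisible(x)
}

#' Classify patients by x-probelet coefficients
#'
#' Discovery-set classification rule: a patient is labeled \code{high}
#' when its coefficient exceeds the cohort median by more than \code{k}
#' standardized median absolute deviations (default 0.5 sMAD), and
#' \code{low} otherwise. The threshold is one-sided above the median on
#' the signed coefficient; \code{direction} records which label is
#' hypothesized favorable for survival (it does not alter the labels).
#' Labels are invariant to affine rescaling of the coefficients.
#'
#' @param coeffs per-patient numeric coefficients (e.g. an x-probelet)
#' @param k threshold in sMAD units (default 0.5)
#' @param patientIds optional identifiers
#' @param direction "high" or "low": the hypothesized favorable label
#' @return a \code{PatientClassification} (list with patientIds, scores,
#'   labels, cutoff, direction, robust)
#' @export
classifyByProbelet <- function(coeffs, k = 0.5, patientIds = NULL,
                               direction = c("low", "high")) {
  direction <- match.arg(direction)
  if (length(coeffs) < 2L) stop("need at least 2 patients")
  s <- smad(coeffs)
  if (s == 0) stop("sMAD of the coefficients is 0: cutoff undefined")
  cutoff <- stats::median(coeffs) + k * s
  labels <- ifelse(coeffs > cutoff, "high", "low")
  if (is.null(patientIds)) patientIds <- sprintf("patient_%d", seq_along(coeffs))
  newClassification(patientIds, coeffs, labels, cutoff, direction)
}

#' Robustness scan of the classification cutoff
#'
#' Re-classifies at every cutoff in \code{[k - halfwidth, k + halfwidth]}
#' (sMAD units, stepped by \code{step}) and tests the two groups'
#' survival difference by the log-rank test. The classification is robust
#' when p < \code{alpha} at every cutoff in the scan; a cutoff leaving
#' fewer than two patients in either group is non-evaluable and makes the
#' verdict non-robust.
#'
#' @param coeffs per-patient coefficients
#' @param time,event survival times (months) and event indicators aligned
#'   to \code{coeffs}
#' @param k central threshold in sMAD units
#' @param halfwidth scan half-range in sMAD units
#' @param step scan step in sMAD units
#' @param alpha log-rank significance level
#' @return list with \code{robust} (logical) and \code{scan} (data.frame of
#'   cutoff_smad, n_high, n_low, p; p is NA where non-evaluable)
#' @export
robustnessScan <- function(coeffs, time, event, k = 0.5, halfwidth = 0.1,
                           step = 0.02, alpha = 0.05) {
  stopifnot(length(time) == length(coeffs), length(event) == length(coeffs))
  s <- smad(coeffs)
  if (s == 0) stop("sMAD of the coefficients is 0: cutoff undefined")
  med <- stats::median(coeffs)
  ks <- seq(k - halfwidth, k + halfwidth, by = step)
  scan <- lapply(ks, function(ki) {
    cut <- med + ki * s
    high <- coeffs > cut
    nh <- sum(high); nl <- sum(!high)
    p <- if (nh < 2L || nl < 2L) NA_real_ else
      logrankTest(time, event, ifelse(high, "high", "low"))$p.value
    data.frame(cutoff_smad = ki, n_high = nh, n_low = nl, p = p)
  })
  scan <- do.call(rbind, scan)
  list(robust = all(!is.na(scan$p)) && all(scan$p < alpha), scan = scan)
}

#' Classify validation patients by arraylet correlation
#'
#' Validation-set rule: each patient's copy-number profile (restricted to
#' the probes shared with the arraylet) is scored by its Spearman rank
#' correlation with the arraylet, then labeled high/low by the same
#' median + k sMAD rule used on the discovery set.
#'
#' @param profiles probes x patients matrix of the validation cohort, with
#'   probe ids as rownames (patient ids as colnames if available)
#' @param arraylet named per-probe numeric vector (the discovery pattern)
#' @param k threshold in sMAD units
#' @param minShared minimum number of shared probes required
#' @param direction hypothesized favorable label
#' @return a \code{PatientClassification}; scores are Spearman correlations
#' @export
classifyByArrayletCorrelation <- function(profiles, arraylet, k = 0.5,
                                          minShared = 10L,
                                          direction = c("low", "high")) {
  direction <- match.arg(direction)
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)) || is.null(names(arraylet)))
    stop("profiles need probe rownames and arraylet needs probe names")
  shared <- intersect(rownames(profiles), names(arraylet))
  if (length(shared) < minShared)
    stop(sprintf("only %d shared probes between profiles and arraylet (need >= %d)",
                 length(shared), minShared))
  a <- arraylet[shared]
  rho <- apply(profiles[shared, , drop = FALSE], 2L,
               function(p) stats::cor(p, a, method = "spearman"))
  pid <- colnames(profiles) %||% sprintf("patient_%d", seq_along(rho))
  cls <- classifyByProbelet(rho, k = k, patientIds = pid,
                            direction = direction)
  cls$scores <- rho
  cls
}

#' Platform consistency of a y-probelet
#'
#' A pattern is platform-consistent when its per-platform weights are
#' approximately equal: the maximal pairwise relative difference
#' \code{|a - b| / max(|a|, |b|)} is at most \code{tol}. The tolerance is a
#' package configuration (default 0.15), not a quantity with a canonical
#' value.
#'
#' @param yProbelet per-platform numeric vector, length >= 2
#' @param tol maximal relative difference
#' @return logical
#' @examples
#' platformConsistency(c(0.70, 0.72))   # TRUE
#' platformConsistency(c(0.9, 0.1))     # FALSE
#' @export
platformConsistency <- function(yProbelet, tol = 0.15) {
  if (length(yProbelet) < 2L)
    stop("platform consistency needs at least 2 platforms")
  pairs <- utils::combn(length(yProbelet), 2L)
  rel <- apply(pairs, 2L, function(ij) {
    a <- yProbelet[ij[1L]]; b <- yProbelet[ij[2L]]
    den <- max(abs(a), abs(b))
    if (den == 0) 0 else abs(a - b) / den
  })
  all(rel <= tol)
}

#' Combine three binomial classifications into prognosis groups A/B/C
#'
#' Given three aligned high/low labelings (one per pattern) and the
#' favorable label triple, each patient is assigned group A when all three
#' labels match the favorable triple, B when exactly one differs (three
#' combinations), and C when at least two differ (four combinations); the
#' eight possible triples partition as 1 + 3 + 4.
#'
#' @param labels1,labels2,labels3 character vectors of "high"/"low",
#'   aligned across the same patients, no missing values
#' @param favorable length-3 character vector: the favorable triple
#' @return factor of "A"/"B"/"C" per patient
#' @examples
#' combineGroups("low", "high", "high", favorable = c("low", "high", "high"))
#' @export
combineGroups <- function(labels1, labels2, labels3,
                          favorable = c("low", "high", "high")) {
  lab <- cbind(labels1, labels2, labels3)
  if (anyNA(lab)) stop("missing label for at least one patient")
  if (!all(lab %in% c("high", "low")) || length(favorable) != 3L)
    stop("labels must be 'high'/'low' and favorable a length-3 triple")
  dist <- rowSums(lab != matrix(favorable, nrow(lab), 3L, byrow = TRUE))
  factor(c("A", "B", "C")[pmin(dist, 2L) + 1L], levels = c("A", "B", "C"))
}
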