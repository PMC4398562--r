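## Recursive binary segmentation of an arraylet (per-probe pattern in
## genomic order) with a permutation test per candidate breakpoint, plus
## amplification/deletion calling, the focality rule, and per-patient
## alteration frequency. This is a deliberately simple changepoint engine
## with the same interface role as circular binary segmentation, not a
## reimplementation of it.

## max two-sample pooled t statistic over all breakpoints of x, O(n)
maxBreakStat <- function(x) {
  n <- length(x)
  cs <- cumsum(x)
  css <- cumsum(x * x)
  j <- seq_len(n - 1L)
  nL <- j; nR <- n - j
  meanL <- cs[j] / nL
  meanR <- (cs[n] - cs[j]) / nR
  ssL <- pmax(css[j] - cs[j]^2 / nL, 0)
  ssR <- pmax((css[n] - css[j]) - (cs[n] - cs[j])^2 / nR, 0)
  sp2 <- (ssL + ssR) / max(n - 2L, 1L)
  se <- sqrt(sp2 * (1 / nL + 1 / nR))
  diff <- meanL - meanR
  t <- ifelse(se > 0, abs(diff) / se, ifelse(abs(diff) > 0, Inf, 0))
  at <- which.max(t)
  list(stat = t[at], at = at)
}

#' Segment a copy-number pattern by recursive binary splitting
#'
#' Recursively splits the signal at the breakpoint maximizing the
#' two-sample pooled t statistic; a split is accepted when its permutation
#' p-value (probes shuffled within the candidate segment, \code{nPerm}
#' shuffles) is below \code{alpha}, and both sides are then segmented
#' further. Deterministic given \code{seed}. Segments tile the input
#' contiguously; on noiseless piecewise-constant signals with distinct
#' levels the recovered breakpoints are exact.
#'
#' @param arraylet numeric vector, per-probe values in genomic order
#'   (length >= 2)
#' @param alpha acceptance level for a split's permutation p-value
#' @param nPerm number of within-segment permutations per candidate split
#' @param seed integer seed for the permutation null (NULL leaves the RNG
#'   state untouched)
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive probe indices), \code{n_probes}, \code{mean_level}
#' @export
segmentArraylet <- function(arraylet, alpha = 0.01, nPerm = 1000L,
                            seed = NULL) {
  x <- as.numeric(arraylet)
  if (length(x) < 2L) stop("segmentation needs at least 2 probes")
  if (!is.null(seed)) set.seed(seed)

  splitP <- function(seg) {
    n <- length(seg)
    obs <- maxBreakStat(seg)
    if (obs$stat <= 0) return(list(p = 1, at = obs$at))
    exceed <- 0L
    for (r in seq_len(nPerm)) {
      if (maxBreakStat(sample(seg))$stat >= obs$stat) exceed <- exceed + 1L
    }
    list(p = (1L + exceed) / (nPerm + 1L), at = obs$at)
  }

  segs <- list()
  stack <- list(c(1L, length(x)))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- iv[1L]; hi <- iv[2L]
    if (hi - lo + 1L < 2L) {
      segs[[length(segs) + 1L]] <- iv
      next
    }
    sp <- splitP(x[lo:hi])
    if (sp$p < alpha) {
      cut <- lo + sp$at - 1L
      ## left-to-right output order: push right side first
      stack[[length(stack) + 1L]] <- c(cut + 1L, hi)
      stack[[length(stack) + 1L]] <- c(lo, cut)
    } else {
      segs[[length(segs) + 1L]] <- iv
    }
  }
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs[, 1L]), , drop = FALSE]
  data.frame(
    start = segs[, 1L], end = segs[, 2L],
    n_probes = segs[, 2L] - segs[, 1L] + 1L,
    mean_level = vapply(seq_len(nrow(segs)),
                        function(i) mean(x[segs[i, 1L]:segs[i, 2L]]),
                        numeric(1)))
}

#' Call segments as amplified, deleted or neutral
#'
#' A segment is amplified when its mean level exceeds
#' \code{baseline + delta}, deleted when below \code{baseline - delta},
#' neutral otherwise. \code{delta} defaults to one robust standard
#' deviation (sMAD) of the whole arraylet.
#'
#' @param segments data.frame from [segmentArraylet()]
#' @param arraylet the segmented signal (used for the default delta)
#' @param baseline reference level (default 0, i.e. no copy-number change)
#' @param delta calling threshold; default \code{smad(arraylet)}
#' @return the segments data.frame with an added \code{call} column
#' @export
callSegments <- function(segments, arraylet = NULL, baseline = 0,
                         delta = NULL) {
  if (is.null(delta)) {
    if (is.null(arraylet))
      stop("either delta or the arraylet (for the default delta) is required")
    delta <- smad(arraylet)
  }
  segments$call <- ifelse(
    segments$mean_level > baseline + delta, "amplified",
    ifelse(segments$mean_level < baseline - delta, "deleted", "neutral"))
  segments
}

#' Focal alterations among called segments
#'
#' A segment is focal when it is altered (amplified or deleted) and spans
#' fewer than \code{maxProbes} probes; the bound is strict (a 125-probe
#' segment is not focal at the default).
#'
#' @param segments called segments (from [callSegments()])
#' @param maxProbes strict upper bound on focal segment length in probes
#' @return the subset of focal segments
#' @export
focalFilter <- function(segments, maxProbes = 125L) {
  if (is.null(segments$call)) stop("segments must be called first")
  segments[segments$n_probes < maxProbes & segments$call != "neutral", ,
           drop = FALSE]
}

#' Per-patient alteration frequency of a segment
#'
#' A patient carries the alteration when their mean copy number over the
#' segment's probes exceeds \code{baseline + delta} (amplified segment) or
#' falls below \code{baseline - delta} (deleted segment). A segment is
#' frequent when the carrier fraction exceeds \code{frequentAbove}
#' (default 0.23, i.e. altered in more than 23% of patients).
#'
#' @param profiles probes x patients matrix aligned to the arraylet's
#'   probe order
#' @param segment single-row data.frame (or list) with \code{start},
#'   \code{end}, \code{call}
#' @param delta per-patient alteration threshold
#' @param baseline reference level
#' @param frequentAbove strict lower bound on the "frequent" fraction
#' @return list with \code{fraction} and \code{frequent}
#' @export
segmentFrequency <- function(profiles, segment, delta, baseline = 0,
                             frequentAbove = 0.23) {
  profiles <- as.matrix(profiles)
  start <- segment$start; end <- segment$end
  if (start < 1L || end > nrow(profiles) || start > end)
    stop(sprintf("segment [%d, %d] outside probe range 1..%d",
                 start, end, nrow(profiles)))
  if (!segment$call %in% c("amplified", "deleted"))
    stop("alteration frequency is defined for amplified or deleted segments")
  m <- colMeans(profiles[start:end, , drop = FALSE])
  altered <- if (segment$call == "amplified") m > baseline + delta
             else m < baseline - delta
  frac <- mean(altered)
  list(fraction = frac, frequent = frac > frequentAbove)
}
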