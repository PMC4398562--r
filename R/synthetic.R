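## Synthetic paired tumor/normal cohorts with planted, segment-like
## copy-number patterns and proportional-hazards survival, so the whole
## pipeline is verifiable against known truth without external data.

#' Configuration for a synthetic paired cohort
#'
#' Defines the study conditions the generator emulates: two cohorts of
#' \code{K1} tumor and \code{K2} normal probes over the same \code{L}
#' patients and \code{M} platforms, i.i.d. Gaussian measurement noise, and
#' a list of planted rank-1 patterns. Each pattern is a piecewise-constant
#' probe profile (segment-like, in relative copy-number units) times a
#' patient carrier indicator times per-platform weights, present in the
#' tumor tensor only (\code{presence = "tumor"}), in both
#' (\code{"common"}, e.g. a normal-genome feature such as the
#' female-specific X amplification), or in the normal tensor only
#' (\code{"normal"}).
#'
#' The defaults plant one platform-consistent tumor-exclusive pattern
#' carried by 30% of 60 patients (a -0.5 deletion block and a +0.5
#' amplification block, single-copy-scale log ratios), one common pattern
#' across all patients, and one normal-exclusive pattern, under noise of
#' standard deviation 0.1.
#'
#' @param K1,K2 tumor and normal probe counts (each must be >= L * M)
#' @param L,M patient and platform counts
#' @param noiseSd standard deviation of the i.i.d. Gaussian noise
#' @param hazardRatio planted carrier vs non-carrier hazard ratio
#' @param censoringRate target fraction of censored patients
#' @param baselineMedianMonths median survival of non-carriers, months
#' @param seed integer seed
#' @param patterns list of planted patterns; each a list with \code{name},
#'   \code{presence} ("tumor"/"common"/"normal"), \code{probeSegments}
#'   (data.frame with startFrac, endFrac, level), \code{carrierFraction}
#'   in (0, 1], and \code{platformWeights} (length M)
#' @return a \code{SyntheticConfig} list
#' @export
syntheticConfig <- function(K1 = 500L, K2 = 480L, L = 60L, M = 2L,
                            noiseSd = 0.1, hazardRatio = 2,
                            censoringRate = 0.2,
                            baselineMedianMonths = 48,
                            seed = 1L, patterns = NULL) {
  if (is.null(patterns)) {
    patterns <- list(
      list(name = "tumor_cna", presence = "tumor",
           probeSegments = data.frame(startFrac = c(0.10, 0.55),
                                      endFrac = c(0.40, 0.70),
                                      level = c(-0.5, 0.5)),
           carrierFraction = 0.3,
           platformWeights = rep(1, M)),
      list(name = "normal_genome", presence = "common",
           probeSegments = data.frame(startFrac = 0.75, endFrac = 0.95,
                                      level = 0.4),
           carrierFraction = 1,
           platformWeights = rep(1, M)),
      list(name = "normal_only", presence = "normal",
           probeSegments = data.frame(startFrac = 0.02, endFrac = 0.08,
                                      level = 0.3),
           carrierFraction = 1,
           platformWeights = rep(1, M))
    )
  }
  cfg <- list(K1 = as.integer(K1), K2 = as.integer(K2), L = as.integer(L),
              M = as.integer(M), noiseSd = noiseSd,
              hazardRatio = hazardRatio, censoringRate = censoringRate,
              baselineMedianMonths = baselineMedianMonths,
              seed = as.integer(seed), patterns = patterns)
  class(cfg) <- "SyntheticConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  lm <- cfg$L * cfg$M
  if (cfg$K1 < lm || cfg$K2 < lm)
    stop(sprintf("probe counts must satisfy K >= L*M = %d", lm))
  if (cfg$noiseSd < 0) stop("noiseSd must be nonnegative")
  if (cfg$hazardRatio <= 0) stop("hazardRatio must be positive")
  if (cfg$censoringRate < 0 || cfg$censoringRate >= 1)
    stop("censoringRate must be in [0, 1)")
  for (p in cfg$patterns) {
    if (!p$presence %in% c("tumor", "common", "normal"))
      stop("pattern presence must be 'tumor', 'common' or 'normal'")
    if (p$carrierFraction <= 0 || p$carrierFraction > 1)
      stop("carrierFraction must be in (0, 1]")
    if (length(p$platformWeights) != cfg$M)
      stop("platformWeights must have length M")
    ps <- p$probeSegments
    if (any(ps$startFrac < 0) || any(ps$endFrac > 1) ||
        any(ps$startFrac >= ps$endFrac))
      stop("probeSegments fractions must satisfy 0 <= start < end <= 1")
  }
  invisible(cfg)
}

## piecewise-constant probe profile on K probes from fractional segments
probeShape <- function(K, probeSegments) {
  shape <- numeric(K)
  for (i in seq_len(nrow(probeSegments))) {
    lo <- max(1L, floor(probeSegments$startFrac[i] * K) + 1L)
    hi <- min(K, floor(probeSegments$endFrac[i] * K))
    shape[lo:hi] <- probeSegments$level[i]
  }
  shape
}

#' Generate a paired tumor/normal synthetic tensor cohort
#'
#' Builds \code{D1} (tumor) as the sum of the tumor-exclusive and common
#' planted patterns plus noise, and \code{D2} (normal) as the sum of the
#' common and normal-exclusive patterns plus independent noise. Each
#' planted term is the outer product of its piecewise-constant probe
#' profile, its patient carrier indicator, and its platform weights.
#' Deterministic given the config seed.
#'
#' @param cfg a [syntheticConfig()]
#' @return list with \code{D1}, \code{D2} ([CopyNumberTensor-class]) and
#'   \code{truth}: per pattern its probe shapes in each tensor, carrier
#'   indicator and platform weights, plus \code{carriers} (of the first
#'   tumor-exclusive pattern) for downstream survival simulation
#' @export
generatePair <- function(cfg) {
  validateConfig(cfg)
  set.seed(cfg$seed)
  L <- cfg$L; M <- cfg$M
  T1 <- array(0, c(cfg$K1, L, M))
  T2 <- array(0, c(cfg$K2, L, M))
  truth <- list(patterns = list())
  for (p in cfg$patterns) {
    carriers <- rep(FALSE, L)
    nC <- round(p$carrierFraction * L)
    carriers[sample.int(L, nC)] <- TRUE
    s1 <- probeShape(cfg$K1, p$probeSegments)
    s2 <- probeShape(cfg$K2, p$probeSegments)
    w <- p$platformWeights
    if (p$presence %in% c("tumor", "common"))
      T1 <- T1 + outer(outer(s1, as.numeric(carriers)), w)
    if (p$presence %in% c("common", "normal"))
      T2 <- T2 + outer(outer(s2, as.numeric(carriers)), w)
    truth$patterns[[p$name]] <- list(
      presence = p$presence, shape1 = s1, shape2 = s2,
      carriers = carriers, platformWeights = w)
  }
  if (cfg$noiseSd > 0) {
    T1 <- T1 + array(stats::rnorm(length(T1), sd = cfg$noiseSd), dim(T1))
    T2 <- T2 + array(stats::rnorm(length(T2), sd = cfg$noiseSd), dim(T2))
  }
  tumorPatterns <- vapply(cfg$patterns, function(p) p$presence == "tumor",
                          logical(1))
  truth$carriers <- if (any(tumorPatterns))
    truth$patterns[[which(tumorPatterns)[1L]]]$carriers else NULL
  pid <- sprintf("patient_%03d", seq_len(L))
  plat <- sprintf("platform_%d", seq_len(M))
  list(
    D1 = copyNumberTensor(T1, probeIds = sprintf("tprobe_%04d", seq_len(cfg$K1)),
                          patientIds = pid, platformIds = plat),
    D2 = copyNumberTensor(T2, probeIds = sprintf("nprobe_%04d", seq_len(cfg$K2)),
                          patientIds = pid, platformIds = plat),
    truth = truth)
}

#' Generate clinical survival data tied to a planted pattern
#'
#' Event times are exponential with a baseline hazard set by the
#' non-carrier median survival; carriers' hazard is multiplied by the
#' planted hazard ratio (proportional hazards). Censoring is independent
#' uniform on (0, tau), with tau solved so the expected censored fraction
#' matches \code{censoringRate}; at rate 0 all events are observed.
#'
#' @param carrier logical per-patient carrier indicator
#' @param hazardRatio carrier vs non-carrier hazard ratio (> 0)
#' @param censoringRate target censored fraction in [0, 1)
#' @param baselineMedianMonths non-carrier median survival, months
#' @param patientIds optional identifiers
#' @param seed optional integer seed
#' @return data.frame with patient_id, time_months, event (0/1), carrier
#' @export
generateClinical <- function(carrier, hazardRatio = 2, censoringRate = 0.2,
                             baselineMedianMonths = 48, patientIds = NULL,
                             seed = NULL) {
  if (hazardRatio <= 0) stop("hazardRatio must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(carrier)
  rate0 <- log(2) / baselineMedianMonths
  rate <- rate0 * ifelse(carrier, hazardRatio, 1)
  tEvent <- stats::rexp(n, rate)
  if (censoringRate > 0) {
    censFrac <- function(tau)
      mean((1 - exp(-rate * tau)) / (rate * tau)) - censoringRate
    tau <- stats::uniroot(censFrac, c(1e-6, 1e6))$root
    tCens <- stats::runif(n, 0, tau)
  } else {
    tCens <- rep(Inf, n)
  }
  if (is.null(patientIds)) patientIds <- sprintf("patient_%03d", seq_len(n))
  data.frame(patient_id = patientIds,
             time_months = pmin(tEvent, tCens),
             event = as.integer(tEvent <= tCens),
             carrier = carrier)
}

#' Generate a probe annotation table
#'
#' Probe ids with arm labels and strictly increasing positions within each
#' arm, mirroring the annotation format the readers expect.
#'
#' @param K total probe count; must equal the sum of the arm counts
#' @param arms named integer vector: probes per arm, in genomic order
#' @param spacing base-pair spacing between consecutive probes
#' @return data.frame with probe_id, arm, position
#' @export
generateProbeAnnotation <- function(K, arms, spacing = 10000L) {
  if (sum(arms) != K)
    stop(sprintf("arm probe counts sum to %d, not K = %d", sum(arms), K))
  do.call(rbind, lapply(seq_along(arms), function(i) {
    n <- arms[[i]]
    data.frame(probe_id = sprintf("%s_p%04d", names(arms)[i], seq_len(n)),
               arm = names(arms)[i],
               position = seq_len(n) * spacing)
  }))
}

#' Generate a validation cohort from a planted arraylet
#'
#' Carrier patients' profiles are the planted probe pattern plus noise;
#' non-carriers are pure noise. Used to exercise the Spearman
#' arraylet-correlation classifier against known labels.
#'
#' @param shape per-probe pattern (named or unnamed; names are generated
#'   when absent)
#' @param carrier logical per-patient indicator
#' @param noiseSd Gaussian noise standard deviation
#' @param seed optional integer seed
#' @return probes x patients matrix with probe rownames and patient colnames
#' @export
generateValidationProfiles <- function(shape, carrier, noiseSd = 0.25,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(shape)
  n <- length(carrier)
  m <- outer(shape, as.numeric(carrier)) +
    matrix(stats::rnorm(K * n, sd = noiseSd), K, n)
  rownames(m) <- names(shape) %||% sprintf("probe_%04d", seq_len(K))
  colnames(m) <- sprintf("patient_%03d", seq_len(n))
  m
}
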