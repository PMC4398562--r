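## Tab-delimited readers/writers for profile, annotation, clinical and
## result tables. All writes are deterministic: stable column order and
## 17-significant-digit float formatting, so numeric round trips are exact.

fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a probes x patients profile table
#'
#' Tab-delimited: first column \code{probe_id}, remaining columns one per
#' patient with patient ids in the header. Values are written with 17
#' significant digits so doubles round-trip exactly.
#'
#' @param mat numeric matrix with probe rownames and patient colnames
#' @param path output file
#' @return \code{path}, invisibly (writer); the matrix (reader)
#' @export
writeProfileTable <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeProfileTable
#' @export
readProfileTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  if (names(df)[1L] != "probe_id") stop("first column must be probe_id: ", path)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in ", path, ": ",
         df$probe_id[duplicated(df$probe_id)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric profile values in ", path)
  rownames(m) <- df$probe_id
  m
}

#' Write a CopyNumberTensor as per-platform profile tables
#'
#' @param x a [CopyNumberTensor-class]
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return named character vector of the written profile paths (one per
#'   platform) plus an \code{annotation} entry when annotation is present
#' @export
writeTensor <- function(x, dir, prefix = "profiles") {
  stopifnot(is(x, "CopyNumberTensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- tensorValues(x)
  paths <- vapply(seq_along(platformIds(x)), function(m) {
    mat <- v[, , m]
    rownames(mat) <- probeIds(x)
    colnames(mat) <- patientIds(x)
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, platformIds(x)[m]))
    writeProfileTable(mat, p)
    p
  }, character(1))
  names(paths) <- platformIds(x)
  if (nrow(probeAnnotation(x)) > 0L) {
    ap <- file.path(dir, sprintf("%s_annotation.tsv", prefix))
    writeTsv(probeAnnotation(x), ap)
    paths <- c(paths, annotation = ap)
  }
  paths
}

#' Read a copy-number tensor from per-platform profile tables
#'
#' Patient columns must agree exactly (same ids, same order) across all
#' platform tables. When an annotation table and an arm selection are
#' given, probes are restricted to the selected arms and ordered by
#' ascending position within arm, arms concatenated in the requested order
#' (e.g. \code{c("6p", "12p")}). Requires \code{K >= L * M}, the
#' decomposition's precondition.
#'
#' @param profilePaths character vector of profile tables, one per
#'   platform; names (or file names) become platform ids
#' @param annotationPath optional probe annotation table (probe_id, arm,
#'   position)
#' @param arms optional character vector of arms to keep, in order
#' @return a [CopyNumberTensor-class]
#' @export
readTensor <- function(profilePaths, annotationPath = NULL, arms = NULL) {
  mats <- lapply(profilePaths, readProfileTable)
  pats <- colnames(mats[[1L]])
  for (m in seq_along(mats)[-1L]) {
    pm <- colnames(mats[[m]])
    if (!identical(pm, pats)) {
      bad <- which(pm != pats)[1L]
      if (is.na(bad)) bad <- min(length(pm), length(pats)) + 1L
      stop(sprintf(
        "patient columns differ between platforms 1 and %d (first mismatch at column %d: '%s' vs '%s')",
        m, bad, pats[bad], pm[bad]))
    }
    if (!identical(rownames(mats[[m]]), rownames(mats[[1L]])))
      stop(sprintf("probe ids differ between platform tables 1 and %d", m))
  }
  anno <- data.frame(probe_id = character(0), arm = character(0),
                     position = integer(0))
  keep <- rownames(mats[[1L]])
  if (!is.null(annotationPath)) {
    anno <- utils::read.delim(annotationPath, check.names = FALSE)
    need <- c("probe_id", "arm", "position")
    if (!all(need %in% names(anno)))
      stop("annotation must have columns probe_id, arm, position")
    if (!is.null(arms)) {
      missing <- setdiff(arms, unique(anno$arm))
      if (length(missing) > 0L)
        stop("arm(s) not present in annotation: ",
             paste(missing, collapse = ", "))
      anno <- do.call(rbind, lapply(arms, function(a) {
        ai <- anno[anno$arm == a, , drop = FALSE]
        ai[order(ai$position), , drop = FALSE]
      }))
    }
    keep <- intersect(anno$probe_id, rownames(mats[[1L]]))
    anno <- anno[match(keep, anno$probe_id), , drop = FALSE]
    rownames(anno) <- NULL
  }
  K <- length(keep)
  L <- length(pats)
  M <- length(mats)
  if (K < L * M)
    stop(sprintf("K = %d probes < L*M = %d: too few probes for the decomposition",
                 K, L * M))
  v <- array(0, c(K, L, M))
  for (m in seq_len(M)) v[, , m] <- mats[[m]][keep, , drop = FALSE]
  platIds <- names(profilePaths) %||%
    sub("\\.tsv$", "", basename(unlist(profilePaths)))
  copyNumberTensor(v, probeIds = keep, patientIds = pats,
                   platformIds = platIds, probeAnnotation = anno)
}

#' Read / write a clinical table
#'
#' Tab-delimited with required columns \code{patient_id},
#' \code{time_months}, \code{event} and optional covariates (stage, grade,
#' therapy, ...). Negative times and non-0/1 events are errors reported
#' with their line number; missing optional fields are permitted and
#' flagged with a message.
#'
#' @param path file path
#' @return data.frame
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("patient_id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$time_months) | df$time_months < 0)
  if (length(bad) > 0L)
    stop(sprintf("invalid time_months at line %d of %s", bad[1L] + 1L, path))
  bad <- which(!df$event %in% c(0L, 1L))
  if (length(bad) > 0L)
    stop(sprintf("event must be 0 or 1 at line %d of %s", bad[1L] + 1L, path))
  optional <- c("stage", "grade", "therapy")
  absent <- setdiff(optional, names(df))
  if (length(absent) > 0L)
    message("optional clinical field(s) absent: ", paste(absent, collapse = ", "))
  df
}

#' @rdname readClinical
#' @param clinical data.frame to write
#' @export
writeClinical <- function(clinical, path) writeTsv(clinical, path)

#' Serialize / restore a tensor GSVD factorization
#'
#' Writes a directory of tab-delimited matrices (U1, U2, Vx, Vy, each with
#' row identifiers), a mode-values table (mode, index, sigma1, sigma2) and
#' a long-format core table (a, b, c, R1, R2, P1, P2, theta). Numeric
#' round trips are exact.
#'
#' @param fit a [TensorGSVD-class]
#' @param dir directory to write to / read from
#' @return \code{dir} invisibly (writer); a [TensorGSVD-class] (reader)
#' @export
writeFactorization <- function(fit, dir) {
  stopifnot(is(fit, "TensorGSVD"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, ids, name) {
    df <- data.frame(id = ids, as.data.frame(m), check.names = FALSE)
    writeTsv(df, file.path(dir, paste0(name, ".tsv")))
  }
  wm(fit@U1, fit@probeIds1, "U1")
  wm(fit@U2, fit@probeIds2, "U2")
  wm(fit@Vx, fit@patientIds, "Vx")
  wm(fit@Vy, fit@platformIds, "Vy")
  sig <- rbind(
    data.frame(mode = "row", index = seq_along(fit@sigmaRow1),
               sigma1 = fit@sigmaRow1, sigma2 = fit@sigmaRow2),
    data.frame(mode = "x", index = seq_along(fit@sigmaX1),
               sigma1 = fit@sigmaX1, sigma2 = fit@sigmaX2),
    data.frame(mode = "y", index = seq_along(fit@sigmaY1),
               sigma1 = fit@sigmaY1, sigma2 = fit@sigmaY2))
  writeTsv(sig, file.path(dir, "sigma.tsv"))
  d <- dim(fit@R1)
  idx <- expand.grid(a = seq_len(d[1L]), b = seq_len(d[2L]),
                     c = seq_len(d[3L]))
  P1 <- subtensorSignificance(fit, 1L)
  P2 <- subtensorSignificance(fit, 2L)
  Th <- tensorAngularDistance(fit@R1, fit@R2)$Theta
  core <- data.frame(idx, R1 = as.vector(fit@R1), R2 = as.vector(fit@R2),
                     P1 = as.vector(P1), P2 = as.vector(P2),
                     theta = as.vector(Th))
  writeTsv(core, file.path(dir, "core.tsv"))
  invisible(dir)
}

#' @rdname writeFactorization
#' @export
readFactorization <- function(dir) {
  rm_ <- function(name) {
    df <- utils::read.delim(file.path(dir, paste0(name, ".tsv")),
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    dimnames(m) <- NULL
    list(m = m, ids = as.character(df[[1L]]))
  }
  u1 <- rm_("U1"); u2 <- rm_("U2"); vx <- rm_("Vx"); vy <- rm_("Vy")
  sig <- utils::read.delim(file.path(dir, "sigma.tsv"))
  core <- utils::read.delim(file.path(dir, "core.tsv"))
  L <- nrow(vx$m); M <- nrow(vy$m); lm <- L * M
  srow <- sig[sig$mode == "row", ]
  sx <- sig[sig$mode == "x", ]
  sy <- sig[sig$mode == "y", ]
  core <- core[order(core$c, core$b, core$a), ]
  R1 <- array(core$R1, c(lm, L, M))
  R2 <- array(core$R2, c(lm, L, M))
  new("TensorGSVD", U1 = u1$m, U2 = u2$m, Vx = vx$m, Vy = vy$m,
      R1 = R1, R2 = R2,
      sigmaRow1 = srow$sigma1, sigmaRow2 = srow$sigma2,
      sigmaX1 = sx$sigma1, sigmaX2 = sx$sigma2,
      sigmaY1 = sy$sigma1, sigmaY2 = sy$sigma2,
      thetaRow = angularDistances(srow$sigma1, srow$sigma2),
      patientIds = vx$ids, platformIds = vy$ids,
      probeIds1 = u1$ids, probeIds2 = u2$ids)
}

#' Write called segments in BED-like form
#'
#' Columns: chrom (arm label), start, end in 0-based half-open genomic
#' coordinates derived from probe positions (probe indices elsewhere in
#' the package are 1-based inclusive), n_probes, mean_level, call, focal,
#' and frequency when supplied.
#'
#' @param segments called segments ([callSegments()] output)
#' @param path output file
#' @param annotation probe annotation aligned to the segmented arraylet
#'   (probe_id, arm, position); NULL uses probe indices as positions
#' @param frequency optional per-segment carrier fraction
#' @param maxProbes focality bound passed to the focal flag
#' @return \code{path}, invisibly
#' @export
writeSegments <- function(segments, path, annotation = NULL,
                          frequency = NULL, maxProbes = 125L) {
  if (is.null(segments$call)) stop("segments must be called first")
  if (is.null(annotation)) {
    chrom <- rep(".", nrow(segments))
    start0 <- segments$start - 1L
    end0 <- segments$end
  } else {
    chrom <- annotation$arm[segments$start]
    start0 <- annotation$position[segments$start] - 1L
    end0 <- annotation$position[segments$end]
  }
  out <- data.frame(
    chrom = chrom, start = start0, end = end0,
    n_probes = segments$n_probes, mean_level = segments$mean_level,
    call = segments$call,
    focal = segments$n_probes < maxProbes & segments$call != "neutral")
  if (!is.null(frequency)) out$frequency <- frequency
  writeTsv(out, path)
}

#' Write a patient classification table
#'
#' Tab-delimited patient_id, score, label, and optionally the combined
#' A/B/C group.
#'
#' @param cls a \code{PatientClassification}
#' @param path output file
#' @param group optional per-patient group factor (from [combineGroups()])
#' @return \code{path}, invisibly
#' @export
writeClassification <- function(cls, path, group = NULL) {
  out <- data.frame(patient_id = cls$patientIds, score = cls$scores,
                    label = cls$labels)
  if (!is.null(group)) out$group <- as.character(group)
  writeTsv(out, path)
}
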