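# Shared fixtures: seeded random tensors/matrices and small comparison
# helpers used across the suite.

randMatrix <- function(k, n, seed) {
  set.seed(seed)
  matrix(rnorm(k * n), k, n)
}

randTensor <- function(k, l, m, seed) {
  set.seed(seed)
  array(rnorm(k * l * m), c(k, l, m))
}

relFrob <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# |cosine| between two vectors
absCos <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))

# principal angle between two unit-ish vectors, radians
vecAngle <- function(u, v) acos(min(1, absCos(u, v)))

# small two-pattern config used by the separation tests: one
# tumor-exclusive pattern (30% carriers) and one common normal-genome
# pattern across all patients, equal probe counts so the common planted
# term is identical in both tensors
separationConfig <- function(seed, noiseSd = 0.05) {
  syntheticConfig(
    K1 = 200L, K2 = 200L, L = 60L, M = 2L, noiseSd = noiseSd, seed = seed,
    patterns = list(
      list(name = "tumor_cna", presence = "tumor",
           probeSegments = data.frame(startFrac = c(0.10, 0.55),
                                      endFrac = c(0.40, 0.70),
                                      level = c(-0.5, 0.5)),
           carrierFraction = 0.3, platformWeights = rep(1, 2)),
      list(name = "normal_genome", presence = "common",
           probeSegments = data.frame(startFrac = 0.75, endFrac = 0.95,
                                      level = 0.4),
           carrierFraction = 1, platformWeights = rep(1, 2))))
}

# the default tumor-exclusive piecewise-constant probe shape on K probes
probeShapeFixture <- function(K) {
  tensorGSVD:::probeShape(K, data.frame(startFrac = c(0.10, 0.55),
                                        endFrac = c(0.40, 0.70),
                                        level = c(-0.5, 0.5)))
}

# index of the arraylet best matching a planted probe shape
matchArraylet <- function(U, shape) {
  which.max(abs(crossprod(U, shape)) / sqrt(sum(shape^2)))
}
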