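test_that("smad matches its closed form and is translation invariant", {
  expect_equal(smad(rep(3, 10)), 0)
  expect_equal(smad(1:7), 2 * 1.4826)
  v <- rnorm(50)
  expect_equal(smad(v + 17.3), smad(v))
  expect_error(smad(1), "at least 2")
})

test_that("probelet classification thresholds at median + k sMAD, one-sided", {
  set.seed(4)
  base <- rnorm(40)
  s <- smad(base); med <- median(base)
  coeffs <- c(base, med + 0.6 * s, med + 0.4 * s)
  cls <- classifyByProbelet(coeffs, k = 0.5)
  # recompute against the definition (median/sMAD shift slightly with the
  # two added points, so compare to the rule, not to the construction)
  expect_equal(cls$labels,
               ifelse(coeffs > median(coeffs) + 0.5 * smad(coeffs),
                      "high", "low"))
  expect_error(classifyByProbelet(rep(1, 10)), "sMAD")
  # affine invariance
  cls2 <- classifyByProbelet(3 * coeffs - 2, k = 0.5)
  expect_equal(cls2$labels, cls$labels)
})

test_that("planted carriers are recovered exactly at zero noise", {
  set.seed(9)
  carrier <- rep(c(TRUE, FALSE), c(15, 35))[sample(50)]
  coeffs <- ifelse(carrier, 2, 0)
  coeffs <- coeffs + seq_along(coeffs) * 1e-6   # break exact ties
  cls <- classifyByProbelet(coeffs)
  expect_equal(cls$labels == "high", carrier)
})

test_that("robustness scan: separated cohorts robust, null and degenerate not", {
  set.seed(21)
  n <- 200
  carrier <- seq_len(n) %in% sample(n, 60)
  coeffs <- ifelse(carrier, 2, 0) + rnorm(n, sd = 0.25)
  clin <- generateClinical(carrier, hazardRatio = 3, censoringRate = 0.2,
                           seed = 22)
  rs <- robustnessScan(coeffs, clin$time_months, clin$event)
  expect_true(rs$robust)
  expect_equal(nrow(rs$scan), 11L)   # k - 0.1 .. k + 0.1 step 0.02
  # survival independent of the coefficients: not robust
  clinNull <- generateClinical(rep(FALSE, n), hazardRatio = 1,
                               censoringRate = 0.2, seed = 23)
  rsNull <- robustnessScan(coeffs, clinNull$time_months, clinNull$event)
  expect_false(rsNull$robust)
  # a cutoff isolating a single patient is non-evaluable -> not robust
  coeffsDeg <- c(rep(0, 100), rep(-1, n - 101), 10)
  rsDeg <- robustnessScan(coeffsDeg, clin$time_months, clin$event)
  expect_false(rsDeg$robust)
  expect_true(anyNA(rsDeg$scan$p))
})

test_that("arraylet correlation classifier: rank invariance and recovery", {
  set.seed(31)
  shape <- probeShapeFixture(200)
  carrier <- seq_len(60) %in% sample(60, 18)
  profiles <- generateValidationProfiles(shape, carrier, noiseSd = 0.25,
                                         seed = 32)
  # a patient profile equal to the arraylet gets correlation 1
  arr <- setNames(shape, rownames(profiles))
  profiles[, 1] <- shape; carrier[1] <- TRUE
  cls <- classifyByArrayletCorrelation(profiles, arr)
  expect_equal(unname(cls$scores[1]), 1)
  expect_equal(unname(cls$labels[1]), "high")
  # strictly monotone transform of the arraylet: still correlation 1
  profiles[, 2] <- exp(shape) + shape^3; carrier[2] <- TRUE
  cls <- classifyByArrayletCorrelation(profiles, arr)
  expect_equal(unname(cls$scores[2]), 1)
  # planted-cohort label accuracy at noise sd 0.25
  acc <- mean((cls$labels == "high") == carrier)
  expect_gte(acc, 0.95)
  expect_error(
    classifyByArrayletCorrelation(profiles[1:5, , drop = FALSE], arr[1:5]),
    "shared probes")
})

test_that("platform consistency compares relative differences", {
  expect_true(platformConsistency(c(0.707, 0.707)))
  expect_false(platformConsistency(c(0.9, 0.1)))
  expect_true(platformConsistency(c(0.70, 0.72)))   # rel. diff 0.028
  expect_error(platformConsistency(0.7), "at least 2")
})

test_that("A/B/C groups partition the eight label triples as 1 + 3 + 4", {
  fav <- c("low", "high", "high")
  expect_equal(as.character(combineGroups("low", "high", "high", fav)), "A")
  expect_equal(as.character(combineGroups("high", "high", "high", fav)), "B")
  expect_equal(as.character(combineGroups("high", "low", "high", fav)), "C")
  expect_equal(as.character(combineGroups("high", "low", "low", fav)), "C")
  triples <- expand.grid(l1 = c("high", "low"), l2 = c("high", "low"),
                         l3 = c("high", "low"), stringsAsFactors = FALSE)
  g <- combineGroups(triples$l1, triples$l2, triples$l3, fav)
  expect_equal(as.vector(table(g)), c(1L, 3L, 4L))
  expect_error(combineGroups(c("high", NA), c("low", "low"),
                             c("low", "low"), fav), "missing label")
})

test_that("label accuracy does not improve as noise grows", {
  # monotone non-increasing accuracy over a 3-point noise grid (20 seeds)
  shape <- probeShapeFixture(150)
  accAt <- function(noise) {
    mean(vapply(1:20, function(s) {
      set.seed(1000 + s)
      carrier <- seq_len(60) %in% sample(60, 18)
      prof <- generateValidationProfiles(shape, carrier, noiseSd = noise,
                                         seed = 2000 + s)
      arr <- setNames(shape, rownames(prof))
      cls <- classifyByArrayletCorrelation(prof, arr)
      mean((cls$labels == "high") == carrier)
    }, numeric(1)))
  }
  acc <- vapply(c(0.1, 0.5, 2.0), accAt, numeric(1))
  expect_true(all(diff(acc) <= 0.02))  # allow tiny Monte-Carlo wiggle
  expect_gte(acc[1], 0.95)
})
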