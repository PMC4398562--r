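test_that("Kaplan-Meier product-limit values and median", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  # all censored: median undefined and flagged
  km2 <- kaplanMeier(c(5, 8, 9), c(0, 0, 0))
  expect_false(km2$medianDefined)
  expect_true(is.na(km2$median))
  # hand-computed product-limit with censoring:
  # times (2,3,4,5,7,9), events (1,1,0,1,0,1):
  # S = 5/6, 5/6*4/5 = 2/3, [censor], 2/3*2/3 = 4/9, [censor], 0
  km3 <- kaplanMeier(c(2, 3, 4, 5, 7, 9), c(1, 1, 0, 1, 0, 1))
  ev <- km3$surv[km3$time %in% c(2, 3, 5, 9)]
  expect_equal(ev, c(5 / 6, 2 / 3, 4 / 9, 0))
  expect_equal(km3$median, 5)
  # curve properties
  expect_true(all(diff(km3$surv) <= 0))
  expect_lte(max(km3$surv), 1)
  expect_error(kaplanMeier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank: null on duplicated data, df, permutation oracle", {
  t0 <- c(3, 5, 8, 10, 12, 14)
  e0 <- c(1, 0, 1, 1, 0, 1)
  lr <- logrankTest(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 6))
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p.value, 1, tolerance = 1e-10)
  g3 <- logrankTest(c(t0, t0 + 1, t0 + 2), rep(e0, 3),
                    rep(c("a", "b", "c"), each = 6))
  expect_equal(g3$df, 2L)
  expect_error(logrankTest(t0, e0, rep("a", 6)), "2 nonempty groups")

  # permutation-null oracle on a toy two-group dataset
  set.seed(55)
  n <- 30
  grp <- rep(c("a", "b"), each = n / 2)
  tt <- rexp(n, ifelse(grp == "a", 1 / 20, 1 / 10))
  ee <- rbinom(n, 1, 0.8)
  obs <- logrankTest(tt, ee, grp)
  nperm <- 4000
  exceed <- 0L
  for (r in seq_len(nperm)) {
    chq <- logrankTest(tt, ee, sample(grp))$chisq
    if (chq >= obs$chisq) exceed <- exceed + 1L
  }
  pPerm <- (exceed + 1) / (nperm + 1)
  mcErr <- 4 * sqrt(pPerm * (1 - pPerm) / nperm)
  expect_lt(abs(pPerm - obs$p.value), max(mcErr, 0.02))
})

test_that("Cox fit: recovery, duplication invariance, explicit failures", {
  # planted proportional-hazards effect HR* = 2, exponential baseline
  hrs <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rbinom(400, 1, 0.4)
    clin <- generateClinical(x == 1, hazardRatio = 2, censoringRate = 0.2,
                             seed = s + 500)
    coxFit(clin$time_months, clin$event, data.frame(x = x))$hr
  }, numeric(1))
  expect_gte(median(hrs), 1.8)
  expect_lte(median(hrs), 2.2)

  set.seed(77)
  x <- rnorm(100)
  clin <- generateClinical(x > 0.5, hazardRatio = 2, seed = 78)
  f1 <- coxFit(clin$time_months, clin$event, data.frame(x = x))
  f2 <- coxFit(rep(clin$time_months, 2), rep(clin$event, 2),
               data.frame(x = rep(x, 2)))
  expect_equal(f2$coef, f1$coef, tolerance = 1e-6)

  expect_error(coxFit(clin$time_months, clin$event,
                      data.frame(x = rep(1, 100))), "constant covariate")
  expect_error(coxFit(clin$time_months, rep(0, 100), data.frame(x = x)),
               "no events")
  # complete separation: the only event belongs to an extreme covariate
  tsep <- c(1, rep(10, 20)); esep <- c(1, rep(0, 20))
  xsep <- c(100, rnorm(20))
  expect_error(coxFit(tsep, esep, data.frame(x = xsep)), "Cox fit failed")
})

test_that("uni- vs bivariate hazard ratios flag independent predictors", {
  expect_true(all(independenceCheck(c(a = 0.5, b = 1.4), c(a = 0.5, b = 1.4))))
  expect_error(independenceCheck(c(a = 0.5), c(b = 0.5)), "covariate sets")
  # two independently planted moderate effects: the joint fit reproduces
  # each univariate log HR within the relative tolerance (hazard ratios are
  # non-collapsible, so some attenuation of the univariate values is
  # expected and must stay inside the rule)
  ok <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 800
    x1 <- rbinom(n, 1, 0.5)
    x2 <- rbinom(n, 1, 0.5)
    rate <- (log(2) / 48) * 1.7^x1 * 2.2^x2
    tt <- rexp(n, rate)
    cens <- runif(n, 0, 150)
    time <- pmin(tt, cens)
    ee <- as.integer(tt <= cens)
    uni <- rbind(coxFit(time, ee, data.frame(x1 = x1)),
                 coxFit(time, ee, data.frame(x2 = x2)))
    bi <- coxFit(time, ee, data.frame(x1 = x1, x2 = x2))
    all(independenceCheck(uni, bi, tol = 0.25))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
  # perfectly collinear covariates cannot be fit jointly
  set.seed(3)
  x <- rbinom(200, 1, 0.5)
  clin2 <- generateClinical(x == 1, hazardRatio = 2, seed = 4)
  expect_error(coxFit(clin2$time_months, clin2$event,
                      data.frame(x1 = x, x2 = 2 * x)),
               "Cox fit failed|singular")
})
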