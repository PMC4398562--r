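numberedTensor <- function() {
  a <- array(0, c(2, 2, 2))
  for (k in 1:2) for (l in 1:2) for (m in 1:2) a[k, l, m] <- 100 * k + 10 * l + m
  a
}

test_that("unfolding conventions: platform index fastest, bijective folds", {
  a <- numberedTensor()
  expect_equal(unfoldRow(a),
               rbind(c(111, 112, 121, 122), c(211, 212, 221, 222)))
  expect_equal(unfoldX(a)[, 1], c(111, 112, 211, 212))
  expect_equal(unfoldY(a)[, 1], c(111, 121, 211, 221))
  t3 <- randTensor(5, 3, 2, 4)
  expect_identical(foldRow(unfoldRow(t3), 3, 2), t3)
  # identical patient slices: x-unfolding has rank 1
  tt <- array(rep(rnorm(10), times = 4), c(5, 4, 2))
  tt <- aperm(array(rep(as.vector(tt[, 1, ]), 4), c(5, 2, 4)), c(1, 3, 2))
  expect_equal(qr(unfoldX(tt))$rank, 1L)
})

test_that("Kronecker identity: D = U R (Vx' x Vy') on the unfoldings", {
  T1 <- randTensor(9, 3, 2, 21)
  T2 <- randTensor(8, 3, 2, 22)
  f <- tensorGSVD(T1, T2)
  for (i in 1:2) {
    Runf <- unfoldRow(coreTensor(f, i))
    D <- arraylets(f, i) %*% Runf %*% kronecker(t(f@Vx), t(f@Vy))
    expect_lt(relFrob(D, unfoldRow(if (i == 1) T1 else T2)), 1e-10)
  }
})

test_that("both tensors are reconstructed exactly from the decomposition", {
  T1 <- randTensor(40, 4, 2, 1)
  T2 <- randTensor(50, 4, 2, 2)
  f <- tensorGSVD(T1, T2)
  expect_lt(relFrob(reconstructTensor(f, 1), T1), 1e-8)
  expect_lt(relFrob(reconstructTensor(f, 2), T2), 1e-8)
  # zeroing all but one core entry isolates one weighted rank-1 subtensor
  core <- array(0, dim(f@R1))
  core[3, 2, 1] <- f@R1[3, 2, 1]
  sub <- reconstructTensor(f, 1, core = core)
  expected <- f@R1[3, 2, 1] *
    outer(outer(f@U1[, 3], f@Vx[, 2]), f@Vy[, 1])
  expect_equal(sub, expected, tolerance = 1e-10)
})

test_that("identical tensors give zero angular distance everywhere defined", {
  T1 <- randTensor(30, 3, 2, 9)
  f <- tensorGSVD(T1, T1)
  th <- tensorAngularDistance(f@R1, f@R2)$Theta
  expect_lt(max(abs(th), na.rm = TRUE), 1e-8)
})

test_that("order-2 inputs reduce to the matrix GSVD", {
  D1 <- randMatrix(12, 4, 31)
  D2 <- randMatrix(10, 4, 32)
  fm <- matrixGSVD(D1, D2)
  ft <- tensorGSVD(array(D1, c(12, 4, 1)), array(D2, c(10, 4, 1)))
  for (a in 1:4) {
    expect_lt(vecAngle(ft@U1[, a], fm@U1[, a]), 1e-8)
    expect_lt(vecAngle(ft@U2[, a], fm@U2[, a]), 1e-8)
    expect_lt(vecAngle(ft@Vx[, a], fm@V[, a]), 1e-8)
  }
  expect_equal(ft@sigmaRow1, fm@sigma1, tolerance = 1e-8)
  expect_equal(ft@sigmaRow2, fm@sigma2, tolerance = 1e-8)
  # the core is diagonal: R_i[a, b, 1] = sigma_i[a] delta_ab up to sign
  expect_equal(abs(diag(ft@R1[, , 1])), fm@sigma1, tolerance = 1e-8)
  offdiag <- ft@R1[, , 1]; diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 1e-8)
})

test_that("identity-unfolding first tensor reduces to the HOSVD of the second", {
  L <- 3L; M <- 2L
  T1 <- foldRow(diag(L * M), L, M)
  T2 <- randTensor(10, L, M, 77)
  f <- tensorGSVD(T1, T2)
  h <- hosvd(T2)
  # row mode: sigma2 (reversed: the GSVD orders most-D1-exclusive first)
  expect_equal(rev(f@sigmaRow2), h$d[[1]][seq_len(L * M)], tolerance = 1e-8)
  for (a in seq_len(L * M))
    expect_lt(vecAngle(f@U2[, L * M + 1 - a], h$U[[1]][, a]), 1e-6)
  # x and y modes match the HOSVD mode factors up to sign and order
  expect_equal(rev(f@sigmaX2), h$d[[2]][seq_len(L)], tolerance = 1e-8)
  for (b in seq_len(L))
    expect_lt(vecAngle(f@Vx[, L + 1 - b], h$U[[2]][, b]), 1e-6)
  for (cc in seq_len(M))
    expect_lt(vecAngle(f@Vy[, M + 1 - cc], h$U[[3]][, cc]), 1e-6)
})

test_that("significance fractions normalize, square, and localize", {
  R <- array(0, c(4, 2, 2))
  R[1, 1, 1] <- 5
  P <- subtensorSignificance(R)
  expect_equal(P[1, 1, 1], 1)
  expect_equal(sum(P), 1)
  R[2, 2, 2] <- -5   # equal magnitude, opposite sign
  P <- subtensorSignificance(R)
  expect_equal(unname(c(P[1, 1, 1], P[2, 2, 2])), c(0.5, 0.5))
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_error(subtensorSignificance(array(0, c(2, 2, 2))), "all-zero")
})

test_that("tensor angular distance equals the row-mode distance (Theorem 1)", {
  for (seed in c(3, 14)) {
    T1 <- randTensor(25, 3, 2, seed)
    T2 <- randTensor(28, 3, 2, seed + 50)
    f <- tensorGSVD(T1, T2)
    td <- tensorAngularDistance(f@R1, f@R2, f@sigmaRow1, f@sigmaRow2)
    dev <- abs(sweep(td$Theta, 1, td$thetaRow, "-"))
    expect_lt(max(dev, na.rm = TRUE), 1e-10)
    expect_true(all(abs(td$Theta) <= pi / 4 + 1e-12, na.rm = TRUE))
    # cross-product identity R1 * sigma2 = R2 * sigma1 holds at zeros too
    expect_equal(f@R1 * f@sigmaRow2, f@R2 * f@sigmaRow1, tolerance = 1e-10)
  }
})

test_that("undefined ratio entries are flagged NA, not zero", {
  R1 <- array(1, c(2, 2, 1)); R2 <- array(2, c(2, 2, 1))
  R1[1, 1, 1] <- 0; R2[1, 1, 1] <- 0
  th <- tensorAngularDistance(R1, R2)$Theta
  expect_true(is.na(th[1, 1, 1]))
  expect_equal(th[2, 2, 1], atan(0.5) - pi / 4)
})

test_that("hosvd: rank-1 core, exact reconstruction, column-space factor", {
  u <- rnorm(6); v <- rnorm(4); w <- rnorm(2)
  t1 <- outer(outer(u, v), w)
  h <- hosvd(t1)
  expect_equal(max(abs(h$core)),
               sqrt(sum(u^2) * sum(v^2) * sum(w^2)), tolerance = 1e-10)
  t2 <- randTensor(8, 4, 2, 123)
  h2 <- hosvd(t2)
  rec <- t2
  rec <- tensorGSVD:::modeProduct(h2$core, h2$U[[1]], 1L)
  rec <- tensorGSVD:::modeProduct(rec, h2$U[[2]], 2L)
  rec <- tensorGSVD:::modeProduct(rec, h2$U[[3]], 3L)
  expect_lt(relFrob(rec, t2), 1e-10)
  # mode-1 factor spans the column space of the row unfolding
  A <- unfoldRow(t2)
  proj <- h2$U[[1]] %*% crossprod(h2$U[[1]], A)
  expect_lt(relFrob(proj, A), 1e-10)
})

test_that("most significant subtensor selection and exclusivity flag", {
  T1 <- randTensor(30, 3, 2, 8)
  f <- tensorGSVD(T1, T1)
  sel <- selectSignificantSubtensor(f, 1)
  expect_lt(abs(sel$theta), 1e-8)
  # identical tensors: nothing is exclusive to dataset 1 in angle
  expect_lt(abs(f@thetaRow[sel$a]), 1e-8)
  # a unique dominant core entry is selected
  g <- f
  g@R1[1, 1, 1] <- 100
  sel2 <- selectSignificantSubtensor(g, 1)
  expect_equal(c(sel2$a, sel2$b, sel2$c), c(1, 1, 1))
  expect_true(sel2$exclusive)
  # exact ties warn and break to the lowest (a, b, c)
  h <- f
  h@R1[] <- 0; h@R1[2, 1, 1] <- 3; h@R1[1, 2, 2] <- 3
  expect_warning(sel3 <- selectSignificantSubtensor(h, 1), "tie")
  expect_equal(c(sel3$a, sel3$b, sel3$c), c(1, 2, 2))
})

test_that("patient permutation permutes x-probelet coefficients consistently", {
  T1 <- randTensor(30, 5, 2, 61)
  T2 <- randTensor(32, 5, 2, 62)
  f <- tensorGSVD(T1, T2)
  set.seed(63); perm <- sample(5)
  fp <- tensorGSVD(T1[, perm, , drop = FALSE], T2[, perm, , drop = FALSE])
  expect_equal(fp@Vx, f@Vx[perm, ], tolerance = 1e-8)
  # downstream labels are permutation-equivariant
  b <- selectSignificantSubtensor(f, 1)$b
  cls <- classifyByProbelet(f@Vx[, b])
  clsp <- classifyByProbelet(fp@Vx[, b])
  expect_equal(clsp$labels, cls$labels[perm])
})

test_that("pattern-level angular distance reproduces theta at paired arraylets", {
  T1 <- randTensor(25, 3, 2, 91)
  T2 <- randTensor(27, 3, 2, 92)
  f <- tensorGSVD(T1, T2)
  for (a in c(1L, 3L, 6L))
    expect_equal(patternAngularDistance(f, f@U1[, a], f@U2[, a]),
                 f@thetaRow[a], tolerance = 1e-10)
  expect_error(patternAngularDistance(f, rnorm(5), rnorm(27)))
})

test_that("dimension and rank preconditions give explicit errors", {
  expect_error(tensorGSVD(randTensor(20, 3, 2, 1), randTensor(20, 4, 2, 2)),
               "column dimensions must match")
  expect_error(tensorGSVD(randTensor(5, 3, 2, 1), randTensor(20, 3, 2, 2)),
               "K >= L\\*M")
  T1 <- randTensor(20, 3, 2, 3)
  T1[, , 2] <- T1[, , 1]           # duplicated platform slice
  expect_error(tensorGSVD(T1, randTensor(20, 3, 2, 4)),
               "unfolding of dataset 1 is rank deficient")
})
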