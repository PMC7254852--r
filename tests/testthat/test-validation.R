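test_that("Q2 obeys its defining identity and extremes", {
  # noiseless linear response is predicted almost perfectly out of fold
  set.seed(1)
  X <- matrix(rnorm(70 * 5), 70, 5, dimnames = list(sprintf("s%02d", 1:70), NULL))
  y <- (X %*% c(1, -2, 0.5, 1, 3))[, 1]
  # noiseless y in the column space: with the y-orthogonal X-variation
  # filtered out (J - 1 components) prediction is essentially perfect
  cv <- kfoldQ2(X, y, nOrth = 4, k = 7)
  expect_gte(cv$q2, 0.99)
  expect_equal(cv$q2, 1 - cv$press / cv$ssy, tolerance = 1e-15)

  # y independent of X: Q2 is negatively biased under the null
  q2null <- vapply(1:30, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 10), 40, 10, dimnames = list(sprintf("s%02d", 1:40), NULL))
    suppressWarnings(kfoldQ2(X, rnorm(40), nOrth = 0, k = 7)$q2)
  }, 0)
  expect_lt(mean(q2null), 0)

  expect_error(kfoldQ2(X, y, k = 1), class = "SpecError")
  # fold with zero-variance training y errors cleanly
  expect_error(kfoldQ2(X[1:6, ], rep(1, 6), k = 2),
               class = "FoldDegenerateError")
})

test_that("fold scaling never leaks held-out information", {
  set.seed(3)
  X <- matrix(rnorm(28 * 6), 28, 6, dimnames = list(sprintf("s%02d", 1:28), NULL))
  y <- rnorm(28)
  cv1 <- kfoldQ2(X, y, nOrth = 0, k = 7)
  # perturbing one sample leaves its fold-mates' out-of-fold predictions
  # untouched: their training split (and hence its scaling) excludes it
  f <- cv1$fold[1]
  X2 <- X; X2[1, ] <- X2[1, ] + 100
  cv2 <- kfoldQ2(X2, y, nOrth = 0, k = 7)
  mates <- cv1$fold == f & seq_len(28) != 1
  expect_equal(cv2$yhatOof[mates], cv1$yhatOof[mates], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv2$yhatOof[1], cv1$yhatOof[1])))
})

test_that("the orthogonal-component count is selected by stalled Q2 gain", {
  # pure predictive structure: adding orthogonal components buys nothing
  set.seed(4)
  tp <- rnorm(60)
  w <- rnorm(8); w <- w / sqrt(sum(w^2))
  X <- tcrossprod(tp, w) + matrix(rnorm(60 * 8, sd = 0.05), 60, 8)
  rownames(X) <- sprintf("s%02d", 1:60)
  y <- tp + rnorm(60, sd = 0.05)
  expect_equal(selectNOrth(X, y, maxOrth = 3, k = 7), 0L)

  # one strong y-orthogonal component: exactly one is selected
  cons <- oplsConstruction(n = 60, J = 10, seed = 5, orthScale = 6)
  Xn <- cons$Xaug + matrix(rnorm(60 * 10, sd = 0.02), 60, 10)
  rownames(Xn) <- sprintf("s%02d", 1:60)
  sel <- selectNOrth(Xn, cons$y, maxOrth = 4, k = 7)
  expect_equal(sel, 1L)

  expect_lte(selectNOrth(X, y, maxOrth = 2, k = 7), 2L)
})

test_that("the permutation null sits below a planted-signal model", {
  set.seed(6)
  X <- matrix(rnorm(30 * 12), 30, 12, dimnames = list(sprintf("s%02d", 1:30), NULL))
  sv <- svd(scale(X, scale = FALSE))
  y <- sv$u[, 1] * sv$d[1] + rnorm(30, sd = 0.1)   # rides the dominant direction
  cv <- kfoldQ2(X, y, nOrth = 0, k = 7)
  expect_gt(cv$q2, 0.9)
  pt <- permutationTest(X, y, nOrth = 0, nPerm = 50, k = 7, seed = 11)
  expect_lt(pt$q2yCumPerm, 0)
  expect_true(all(pt$permQ2 < cv$q2))
  # seeded determinism
  pt2 <- permutationTest(X, y, nOrth = 0, nPerm = 50, k = 7, seed = 11)
  expect_identical(pt$permQ2, pt2$permQ2)
  expect_error(permutationTest(X, y, nPerm = 5), class = "SpecError")
  expect_error(permutationTest(X, rep(1, 30), nPerm = 20),
               class = "DegenerateYError")
})

test_that("CV-ANOVA behaves as an F-test of cross-validated residuals", {
  r <- cvAnova(press = 10, ssy = 10, n = 20, modelDf = 2)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  ps <- vapply(c(8, 4, 2, 1, 0.25), function(press)
    cvAnova(press, ssy = 10, n = 20, modelDf = 2)$p, 0)
  expect_true(all(diff(ps) < 0))               # p falls monotonically with PRESS

  expect_error(cvAnova(1, 10, n = 3, modelDf = 2), class = "DegenerateError")

  # approximate type-I error under the null stays near nominal
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(sprintf("s%02d", 1:40), NULL))
    cv <- suppressWarnings(kfoldQ2(X, rnorm(40), nOrth = 0, k = 7))
    cvAnova(cv$press, cv$ssy, 40, modelDf = 1)$p < 0.05
  }, TRUE)
  expect_lte(mean(hits), 0.13)
})

test_that("Mann-Whitney U and exact p match the enumeration oracle", {
  r <- mannWhitneyU(1:5, 6:10)
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 252, tolerance = 1e-12)

  # symmetry in the arguments
  r2 <- mannWhitneyU(6:10, 1:5)
  expect_equal(r2$U, r$U)
  expect_equal(r2$p, r$p)

  # identical multisets: ties fallback, p = 1
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)

  # exact agreement with enumeration across all shapes with n <= 10
  set.seed(7)
  for (na in 1:9) for (nb in 1:(10 - na)) {
    x <- sample(seq_len(100), na + nb)       # distinct values, no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mannWhitneyU(a, b)$p, mwEnumP(a, b), tolerance = 1e-12,
                 label = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("Spearman rho equals the rank-Pearson oracle", {
  expect_equal(spearmanRho(1:10, 2 * (1:10) + 3), 1)
  expect_equal(spearmanRho(1:10, rev(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 1, 2, 2)
  expect_equal(spearmanRho(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(spearmanRho(x, y), 2 / sqrt(5), tolerance = 1e-12)
  expect_warning(val <- spearmanRho(c(1, 1, 1), c(1, 2, 3)),
                 class = "DegenerateWarning")
  expect_true(is.na(val))
})

test_that("validateModel bundles the verdict triple correctly", {
  set.seed(8)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(sprintf("s%02d", 1:30), NULL))
  y <- (X %*% rnorm(10))[, 1] + rnorm(30, sd = 0.1)
  rep <- validateModel(X, y, nOrth = 0, k = 7, nPerm = 30, seed = 2)
  expect_s4_class(rep, "ValidationReport")
  expect_equal(q2yCum(rep), 1 - rep@press / rep@ssy, tolerance = 1e-15)
  expect_true(verdict(rep))
  repNull <- suppressWarnings(
    validateModel(X, rnorm(30), nOrth = 0, k = 7, nPerm = 30, seed = 2))
  expect_false(verdict(repNull))
})
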