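test_that("NIPALS recovers rank-1 structure exactly", {
  X <- scale(cbind(a = c(1, 2, 3), b = c(1, 2, 3)), scale = FALSE)[, ]
  rownames(X) <- paste0("s", 1:3)
  m <- pcaFit(X, 1)
  expect_equal(r2x(m), 1)
  expect_equal(unname(loadings(m)[, 1]), c(1, 1) / sqrt(2))
})

test_that("NIPALS matches the SVD oracle up to sign on random matrices", {
  for (seed in c(1, 2, 3)) {
    X <- centeredMatrix(20, 10, seed)
    A <- min(nrow(X) - 1, ncol(X))
    m <- pcaFit(X, A)
    sv <- svd(X)
    for (a in seq_len(A)) {
      sgn <- sign(sum(loadings(m)[, a] * sv$v[, a]))
      expect_lt(max(abs(loadings(m)[, a] - sgn * sv$v[, a])), 1e-8)
      expect_lt(max(abs(scores(m)[, a] - sgn * sv$u[, a] * sv$d[a])), 1e-8)
    }
    expect_equal(sum(r2x(m)), 1, tolerance = 1e-8)
    expect_equal(r2x(m), sv$d[1:A]^2 / sum(sv$d^2), tolerance = 1e-8)
    # deterministic sign convention: largest |loading| positive
    expect_true(all(apply(loadings(m), 2, function(p) p[which.max(abs(p))] > 0)))
  }
})

test_that("non-centered input and out-of-range component counts are rejected", {
  X <- centeredMatrix(10, 4)
  expect_error(pcaFit(X + 1, 2), class = "NotCenteredError")
  expect_error(pcaFit(X, 0), class = "SpecError")
  expect_error(pcaFit(X, 10), class = "SpecError")
})

test_that("Hotelling T2 flags planted outliers and respects symmetry", {
  X <- centeredMatrix(20, 6, seed = 5)
  m <- pcaFit(X, 2)
  h <- hotellingT2(m)
  expect_equal(length(h$t2), 20)
  expect_gt(h$limit, 0)

  # a sample displaced by 10 pooled-sd units on t1 is flagged
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    X <- matrix(rnorm(20 * 6), 20, 6)
    X[1, ] <- X[1, ] + 10 * svd(scale(X, scale = FALSE))$v[, 1]
    X <- scale(X, scale = FALSE)[, ]
    rownames(X) <- paste0("s", 1:20)
    h <- hotellingT2(pcaFit(X, 2), alpha = 0.05)
    h$outlier[1]
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # flags do not depend on row order
  perm <- sample(20)
  h2 <- hotellingT2(pcaFit(X[perm, ], 2))
  expect_equal(unname(h2$outlier[order(perm)]), unname(h$outlier))

  expect_error(hotellingT2(pcaFit(centeredMatrix(4, 6), 3)),
               class = "DegenerateError")
})

test_that("OPLS with no orthogonal components reduces to closed-form PLS1", {
  X <- centeredMatrix(15, 8, seed = 2)
  set.seed(2)
  y <- rnorm(15)
  m <- oplsFit(X, y, nOrth = 0)
  yc <- y - mean(y)
  w <- crossprod(X, yc)[, 1]; w <- w / sqrt(sum(w^2))   # PLS1 oracle
  t <- (X %*% w)[, 1]
  b <- sum(t * yc) / sum(t^2)
  expect_lt(max(abs(m@wPred - w)), 1e-12)
  expect_lt(max(abs(m@tPred - t)), 1e-12)
  expect_equal(m@b, b, tolerance = 1e-12)
  expect_equal(r2y(m), 1 - sum((yc - b * t)^2) / sum(yc^2), tolerance = 1e-12)
})

test_that("y-orthogonal structured variation changes r2x_orth but not predictions", {
  cons <- oplsConstruction()
  m0 <- oplsFit(cons$X0, cons$y, nOrth = 0)
  m1 <- oplsFit(cons$Xaug, cons$y, nOrth = 1)
  expect_gt(r2x(m1)[["orth"]], 0)
  # fitted values agree on the training samples
  f0 <- predict(m0, cons$X0)$yhat
  f1 <- predict(m1, cons$Xaug)$yhat
  expect_lt(max(abs(f0 - f1)), 1e-8)
  # the filtered predictive component equals the clean one
  expect_lt(max(abs(abs(m1@tPred) - abs(m0@tPred))), 1e-8)
})

test_that("orthogonal scores are exactly uncorrelated with y", {
  for (seed in c(3, 4)) {
    X <- centeredMatrix(25, 12, seed)
    set.seed(seed)
    y <- rnorm(25)
    m <- oplsFit(X, y, nOrth = 3)
    yc <- y - mean(y)
    for (a in seq_len(ncol(m@TOrth))) {
      expect_lt(abs(sum(m@TOrth[, a] * yc)),
                1e-8 * sqrt(sum(m@TOrth[, a]^2) * sum(yc^2)))
    }
    # r2y never decreases with more orthogonal components
    r2 <- vapply(0:3, function(A) r2y(oplsFit(X, y, A)), 0)
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("OPLS-DA separates a one-metabolite contrast and is encoding-symmetric", {
  X <- cbind(m1 = rep(c(0, 1), each = 4), m2 = rep(0.25, 8), m3 = rep(c(0.5, 0), 4))
  X <- scale(X, scale = FALSE)[, ]
  X[, 2] <- 0
  rownames(X) <- paste0("s", 1:8)
  labels <- rep(c("A", "B"), each = 4)
  m <- oplsdaFit(X, labels, nOrth = 0)
  expect_equal(which.max(abs(m@wPred)), c(m1 = 1L))
  expect_equal(predict(m, X)$labels, labels)    # zero training misclassification

  m2 <- oplsdaFit(X, labels, nOrth = 0, positiveClass = "A")
  expect_equal(m2@tPred, -m@tPred)
  expect_equal(vip(m2), vip(m))
  expect_equal(predict(m2, X)$labels, labels)

  expect_error(oplsdaFit(X, rep(c("A", "B", "C"), c(3, 3, 2))),
               class = "NotImplementedError")
  expect_error(oplsdaFit(X, rep(c("A", "B"), c(1, 7))), class = "DesignError")
})

test_that("permuting class labels degrades the training fit of planted data", {
  set.seed(9)
  n <- 20
  labels <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * 15, sd = 0.5), n, 15)
  X[labels == "B", 1:5] <- X[labels == "B", 1:5] + 2
  X <- scale(X, scale = FALSE)[, ]
  rownames(X) <- sprintf("s%02d", 1:n)
  r2True <- r2y(oplsdaFit(X, labels, 0))
  worse <- vapply(1:40, function(i) {
    r2y(oplsdaFit(X, sample(labels), 0)) < r2True
  }, TRUE)
  expect_gte(mean(worse), 0.95)
})

test_that("VIP concentrates mass as sqrt(J) and has unit mean square", {
  # identical informative columns -> uniform weights -> VIP all 1
  t <- scale(rnorm(12), scale = FALSE)[, 1]
  X4 <- matrix(rep(t, 4), ncol = 4, dimnames = list(sprintf("s%02d", 1:12), paste0("m", 1:4)))
  m <- oplsFit(X4, t, 0)
  expect_equal(unname(vip(m)), rep(1, 4), tolerance = 1e-10)

  # single informative column among 9 -> VIP = (3, 0, ..., 0)
  set.seed(6)
  y <- scale(rnorm(12), scale = FALSE)[, 1]
  Z <- matrix(rnorm(12 * 8), 12, 8)
  Z <- Z - y %*% crossprod(y, Z) / sum(y^2)          # orthogonal to y
  X9 <- cbind(y, Z)
  X9 <- scale(X9, scale = FALSE)[, ]
  colnames(X9) <- paste0("m", 1:9); rownames(X9) <- sprintf("s%02d", 1:12)
  v <- vip(oplsFit(X9, y, 0))
  expect_equal(unname(v[1]), 3, tolerance = 1e-6)
  expect_lt(max(v[-1]), 1e-6)

  # invariant: mean squared VIP is 1 for arbitrary fits
  for (seed in c(2, 5)) {
    X <- centeredMatrix(18, 11, seed)
    set.seed(seed); yy <- rnorm(18)
    expect_equal(mean(vip(oplsFit(X, yy, 1))^2), 1, tolerance = 1e-10)
  }
})

test_that("prediction is consistent, deterministic and centered", {
  X <- centeredMatrix(16, 7, seed = 8)
  set.seed(8); y <- rnorm(16)
  m <- oplsFit(X, y, nOrth = 2)
  pr <- predict(m, X)
  yc <- y - mean(y)
  expect_lt(max(abs(pr$yhat - (m@b * m@tPred + mean(y)))), 1e-10)
  dup <- predict(m, X[c(1, 1), , drop = FALSE])$yhat
  expect_equal(dup[1], dup[2])
  centerRow <- matrix(0, 1, 7)
  expect_equal(unname(predict(m, centerRow)$yhat), mean(y))
  expect_error(predict(m, X[, 1:3]), class = "ShapeError")
})
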