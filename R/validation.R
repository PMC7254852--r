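## Model validation: cross-validated Q2Y, permutation null, CV-ANOVA, plus
## the univariate statistics the signature step uses. Centering/scaling is
## redone inside every training fold (never on the full data), so Q2 cannot
## leak information from held-out samples.

.foldAssign <- function(ids, k) {
  ord <- order(ids)                       # deterministic: sort by sample id
  fold <- integer(length(ids))
  fold[ord] <- ((seq_along(ids) - 1L) %% k) + 1L
  fold
}

.scaleTrain <- function(Xtr) {
  centers <- colMeans(Xtr)
  scales <- apply(Xtr, 2, stats::sd)
  scales[!is.finite(scales) | scales == 0] <- 1   # centered constants stay 0
  list(centers = centers, scales = scales)
}

.applyScale <- function(X, s) sweep(sweep(X, 2, s$centers, "-"), 2, s$scales, "/")

#' Cross-validated Q2Y of an OPLS(-DA) model
#'
#' Venetian-blind k-fold cross-validation: after ordering samples by
#' identifier, sample i goes to fold `i mod k`. Within each fold the
#' centering/scaling and the full OPLS fit use the training split only;
#' held-out samples are scaled with the training parameters and predicted.
#' `Q2 = 1 - PRESS/SSY` with `PRESS = sum (y - yhat_oof)^2` and
#' `SSY = sum (y - mean(y))^2`.
#'
#' @param X raw (unscaled) samples-as-rows matrix with row identifiers.
#' @param y numeric response, or a two-level class vector.
#' @param nOrth orthogonal components of each fold's model.
#' @param k number of folds (default 7).
#' @return list with `q2`, `press`, `ssy`, `yhatOof`, `fold`.
#' @export
kfoldQ2 <- function(X, y, nOrth = 0L, k = 7L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L) metaboError("SpecError", "k must be >= 2")
  if (n < 2L * k)
    metaboWarning("SmallSampleWarning",
                  "n = %d is below the recommended 2k = %d", n, 2L * k)
  if (!is.numeric(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L)
      metaboError("NotImplementedError", "class y must have exactly two levels")
    y <- as.numeric(as.character(y) == lev[2])
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(n))
  fold <- .foldAssign(ids, k)
  yhat <- rep(NA_real_, n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (stats::sd(y[tr]) == 0)
      metaboError("FoldDegenerateError", "fold %d has zero-variance training y", f)
    s <- .scaleTrain(X[tr, , drop = FALSE])
    m <- oplsFit(.applyScale(X[tr, , drop = FALSE], s), y[tr], nOrth)
    yhat[!tr] <- predict(m, .applyScale(X[!tr, , drop = FALSE], s))$yhat
  }
  press <- sum((y - yhat)^2)
  ssy <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ssy, press = press, ssy = ssy,
       yhatOof = stats::setNames(yhat, ids), fold = fold)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Scans A = 0..maxOrth and returns the smallest A whose successor gains less
#' than `gain` in Q2 (i.e. stop adding components once the improvement stalls).
#' If the deflated matrix runs out of rank first, the largest feasible A is
#' returned.
#'
#' @param X raw samples-as-rows matrix.
#' @param y response (numeric or two-level).
#' @param maxOrth largest A considered (default 5).
#' @param k folds.
#' @param gain minimal Q2 improvement to accept one more component.
#' @return integer number of orthogonal components.
#' @export
selectNOrth <- function(X, y, maxOrth = 5L, k = 7L, gain = 0.01) {
  if (maxOrth < 0L) metaboError("SpecError", "maxOrth must be >= 0")
  q2 <- rep(NA_real_, maxOrth + 2L)
  for (A in 0:(maxOrth + 1L)) {
    res <- tryCatch(.quietly(kfoldQ2(X, y, nOrth = A, k = k)),
                    metabOPLSError = function(e) NULL)
    if (is.null(res)) break
    q2[A + 1L] <- res$q2
    if (A >= 1L && q2[A + 1L] - q2[A] < gain) return(A - 1L)
  }
  feasible <- which(!is.na(q2)) - 1L
  min(max(feasible), maxOrth)
}

#' Permutation null distribution of Q2Y
#'
#' Randomly reorders y `nPerm` times (seeded) and refits the full
#' cross-validation each time; the summary `q2yCumPerm` is the mean of the
#' permuted Q2 values. The identity permutation is not excluded — with
#' realistic n its probability is negligible and results are reported as-is.
#'
#' @param X raw samples-as-rows matrix.
#' @param y response.
#' @param nOrth orthogonal components.
#' @param nPerm number of permutations (>= 20).
#' @param k folds.
#' @param seed RNG seed for the permutations.
#' @return list with `permQ2` and `q2yCumPerm`.
#' @export
permutationTest <- function(X, y, nOrth = 0L, nPerm = 200L, k = 7L, seed = 1L) {
  if (nPerm < 20L) metaboError("SpecError", "nPerm must be >= 20")
  if (is.numeric(y) && stats::sd(y) == 0)
    metaboError("DegenerateYError", "constant response cannot be permuted")
  permQ2 <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      .quietly(kfoldQ2(X, sample(y), nOrth = nOrth, k = k)$q2)
    }, 0)
  })
  list(permQ2 = permQ2, q2yCumPerm = mean(permQ2))
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test of the cross-validated residuals against total Y variation:
#' `F = ((SSY - PRESS)/d1) / (PRESS/d2)` with `d1` the number of fitted
#' latent components (predictive + orthogonal) and `d2 = n - d1 - 1`;
#' p is the upper tail of F(d1, d2). The degrees of freedom follow the
#' published components-as-df approximation; when PRESS >= SSY the statistic
#' is clipped at 0 (p = 1).
#'
#' @param press prediction residual sum of squares.
#' @param ssy total sum of squares of centered y.
#' @param n number of samples.
#' @param modelDf fitted latent components (>= 1).
#' @return list with `F` and `p`.
#' @export
cvAnova <- function(press, ssy, n, modelDf) {
  d1 <- modelDf
  d2 <- n - modelDf - 1L
  if (d2 <= 0L)
    metaboError("DegenerateError", "n too small for CV-ANOVA (d2 = %d)", d2)
  f <- max(0, ((ssy - press) / d1) / (press / d2))
  list(F = f, p = stats::pf(f, d1, d2, lower.tail = FALSE))
}

#' Mann-Whitney-Wilcoxon rank test
#'
#' U is computed from rank sums with average ranks for ties and reported as
#' `min(U_a, U_b)`. The two-sided p-value is exact (full enumeration of the
#' rank distribution) when `n_a + n_b <= 12` and the data are tie-free,
#' otherwise the normal approximation with tie and continuity correction is
#' used.
#'
#' @param a,b sample vectors.
#' @return list with `U` and `p`.
#' @export
mannWhitneyU <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) metaboError("SpecError", "both samples must be non-empty")
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  ties <- any(duplicated(c(a, b)))
  exact <- (na + nb) <= 12L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = min(ua, ub), p = min(1, p))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average ranks. A constant input yields `NA`
#' (propagated as missing in volcano output) with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return scalar rho, or `NA` for degenerate input.
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    metaboError("SpecError", "need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    metaboWarning("DegenerateWarning", "constant vector: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Validate a fitted OPLS(-DA) model
#'
#' Bundles cross-validated Q2Y, the permutation null and CV-ANOVA into a
#' [ValidationReport]. The verdict is TRUE when Q2Y_cum > 0.5, the mean
#' permuted Q2 is negative and CV-ANOVA p < 0.05.
#'
#' @param X raw (unscaled) samples-as-rows matrix.
#' @param y response (numeric, or two-level class vector).
#' @param nOrth orthogonal components (e.g. from [selectNOrth()]).
#' @param k folds.
#' @param nPerm permutations; 0 skips the permutation test (`q2yCumPerm` is
#'   then `NA` and the verdict cannot be established, so it is `FALSE`).
#' @param seed permutation seed.
#' @return a [ValidationReport].
#' @export
validateModel <- function(X, y, nOrth = 0L, k = 7L, nPerm = 200L, seed = 1L) {
  cv <- kfoldQ2(X, y, nOrth = nOrth, k = k)
  perm <- if (nPerm > 0L) permutationTest(X, y, nOrth, nPerm, k, seed)
          else list(permQ2 = numeric(), q2yCumPerm = NA_real_)
  an <- cvAnova(cv$press, cv$ssy, nrow(X), modelDf = 1L + nOrth)
  new("ValidationReport", q2yCum = cv$q2, press = cv$press, ssy = cv$ssy,
      nFolds = as.integer(k), nOrthSelected = as.integer(nOrth),
      permQ2 = perm$permQ2, q2yCumPerm = perm$q2yCumPerm,
      cvAnovaF = an$F, cvAnovaP = an$p)
}
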