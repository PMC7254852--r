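## From-scratch latent-variable core: NIPALS PCA, Hotelling T2, single-y OPLS
## and OPLS-DA with VIP. NIPALS is the reference implementation (it tolerates
## the small-n / large-J shape usual in targeted panels); a full SVD serves as
## the independent oracle in the test suite, never here.

.checkCentered <- function(X, tol = 1e-8) {
  cm <- colMeans(X)
  if (any(abs(cm) > tol))
    metaboError("NotCenteredError",
                "input must be column-centered (max |mean| = %.3g)", max(abs(cm)))
}

#' Fit a principal component model by NIPALS
#'
#' One component at a time: iterate `p = X't/t't` (normalised), `t = Xp`
#' until the score vector is stable (relative change < 1e-12, cap 10000
#' iterations; power iteration slows as neighbouring eigenvalues approach
#' each other, so the cap is generous), deflate `X <- X - t p'`. The fraction of explained
#' X-variance per component is `||t p'||_F^2 / ||X_0||_F^2`. The sign of each
#' component is fixed so its largest-magnitude loading is positive. The
#' iteration starts from the column of maximal variance, so the fit is
#' deterministic.
#'
#' @param X centered (and typically autoscaled) samples-as-rows matrix.
#' @param nComponents number of components, at most `min(n - 1, J)`.
#' @return a [PCAModel].
#' @export
pcaFit <- function(X, nComponents = 2L) {
  X <- as.matrix(X)
  .checkCentered(X)
  n <- nrow(X); J <- ncol(X)
  maxA <- min(n - 1L, J)
  if (nComponents < 1L || nComponents > maxA)
    metaboError("SpecError", "nComponents must be in 1..%d", maxA)
  totalSS <- sum(X^2)
  scores <- matrix(0, n, nComponents,
                   dimnames = list(rownames(X), paste0("t", seq_len(nComponents))))
  loadings <- matrix(0, J, nComponents,
                     dimnames = list(colnames(X), paste0("p", seq_len(nComponents))))
  r2x <- numeric(nComponents)
  for (a in seq_len(nComponents)) {
    start <- which.max(apply(X, 2, stats::var))
    t <- X[, start]
    if (sum(t^2) == 0)
      metaboError("ConvergenceError", "residual matrix is zero at component %d", a)
    for (it in seq_len(10000L)) {
      p <- crossprod(X, t)[, 1] / sum(t^2)
      p <- p / sqrt(sum(p^2))
      tNew <- X %*% p
      delta <- sqrt(sum((tNew - t)^2)) / sqrt(sum(tNew^2))
      t <- tNew[, 1]
      if (delta < 1e-12) break
      if (it == 10000L)
        metaboError("ConvergenceError", "NIPALS did not converge at component %d", a)
    }
    if (p[which.max(abs(p))] < 0) { p <- -p; t <- -t }
    X <- X - tcrossprod(t, p)
    scores[, a] <- t
    loadings[, a] <- p
    r2x[a] <- sum(t^2) / totalSS      # p unit norm => ||t p'||_F^2 = t't
  }
  new("PCAModel", scores = scores, loadings = loadings, r2x = r2x,
      totalSS = totalSS, center = numeric(), scale = numeric())
}

#' Hotelling T2 outlier limits on PCA scores
#'
#' `T2_i = sum_a t_ia^2 / var(t_a)`; the critical limit at level `alpha` is
#' `A (n-1) (n+1) / (n (n-A)) * F_(1-alpha)(A, n-A)`.
#'
#' @param model a fitted [PCAModel].
#' @param alpha significance level (default 0.05).
#' @return list with `t2` (per sample), `limit` and logical `outlier` flags.
#' @export
hotellingT2 <- function(model, alpha = 0.05) {
  T <- scores(model)
  n <- nrow(T); A <- ncol(T)
  if (n <= A + 1L)
    metaboError("DegenerateError", "need n > A + 1 samples for the T2 limit")
  v <- apply(T, 2, stats::var)
  v[v == 0] <- Inf                     # a constant score axis contributes 0
  t2 <- rowSums(sweep(T^2, 2, v, "/"))
  limit <- A * (n - 1) * (n + 1) / (n * (n - A)) * stats::qf(1 - alpha, A, n - A)
  list(t2 = t2, limit = limit, outlier = t2 > limit)
}

.oplsCore <- function(X, y, nOrth) {
  X0 <- as.matrix(X)
  .checkCentered(X0)
  y <- as.numeric(y)
  if (stats::sd(y) == 0)
    metaboError("DegenerateYError", "response has zero variance")
  yc <- y - mean(y)
  totalSS <- sum(X0^2)
  J <- ncol(X0)
  w <- crossprod(X0, yc)[, 1]
  nw <- sqrt(sum(w^2))
  if (nw == 0) metaboError("DegenerateYError", "X carries no covariance with y")
  w <- w / nw
  WO <- matrix(0, J, 0); TO <- matrix(0, nrow(X0), 0); PO <- matrix(0, J, 0)
  Xd <- X0
  for (a in seq_len(nOrth)) {
    t <- (Xd %*% w)[, 1]
    p <- crossprod(Xd, t)[, 1] / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12)
      metaboError("RankError",
                  "no orthogonal variation left at component %d", a)
    wo <- wo / nwo
    to <- (Xd %*% wo)[, 1]
    if (sum(to^2) < 1e-24)
      metaboError("RankError", "degenerate orthogonal scores at component %d", a)
    po <- crossprod(Xd, to)[, 1] / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    WO <- cbind(WO, wo); TO <- cbind(TO, to); PO <- cbind(PO, po)
  }
  t <- (Xd %*% w)[, 1]
  p <- crossprod(Xd, t)[, 1] / sum(t^2)
  b <- sum(t * yc) / sum(t^2)
  r2y <- 1 - sum((yc - b * t)^2) / sum(yc^2)
  r2xPred <- sum(t^2) * sum(p^2) / totalSS
  r2xOrth <- if (ncol(TO)) sum(colSums(TO^2) * colSums(PO^2)) / totalSS else 0
  if (ncol(WO)) {
    dimnames(WO) <- list(colnames(X0), paste0("wo", seq_len(ncol(WO))))
    dimnames(TO) <- list(rownames(X0), paste0("to", seq_len(ncol(TO))))
    dimnames(PO) <- list(colnames(X0), paste0("po", seq_len(ncol(PO))))
  }
  list(w = stats::setNames(w, colnames(X0)), t = t,
       p = stats::setNames(p, colnames(X0)),
       WO = WO, TO = TO, PO = PO, b = b, yCenter = mean(y), r2y = r2y,
       r2xPred = r2xPred, r2xOrth = r2xOrth)
}

#' Fit a single-response OPLS model
#'
#' Single-y orthogonal projections to latent structures: the predictive
#' weight is `w = X'y / ||X'y||`; each orthogonal component takes the part of
#' the current loading not aligned with `w`, deflates X by it, and the
#' predictive component is recomputed on the filtered matrix. Orthogonal
#' scores are exactly uncorrelated with y by construction.
#'
#' @param X centered-and-scaled samples-as-rows matrix.
#' @param y response vector (centered internally).
#' @param nOrth number of Y-orthogonal components (>= 0).
#' @return an [OPLSModel] with `yKind = "quantitative"`.
#' @export
oplsFit <- function(X, y, nOrth = 0L) {
  if (nOrth < 0) metaboError("SpecError", "nOrth must be >= 0")
  core <- .oplsCore(X, y, nOrth)
  new("OPLSModel", wPred = core$w, tPred = core$t, pPred = core$p,
      WOrth = core$WO, TOrth = core$TO, POrth = core$PO,
      b = core$b, yCenter = core$yCenter, r2y = core$r2y,
      r2xPred = core$r2xPred, r2xOrth = core$r2xOrth,
      yKind = "quantitative", classMap = numeric(),
      center = numeric(), scale = numeric())
}

#' Fit an OPLS-DA model for a two-class contrast
#'
#' Labels are encoded 0/1 (in sorted label order), centered, and passed to
#' the quantitative fit; the encoding is recorded so predictions can be
#' decoded to the nearest class.
#'
#' @param X centered-and-scaled samples-as-rows matrix.
#' @param labels two-class vector (factor or character), one entry per row.
#' @param nOrth number of Y-orthogonal components.
#' @param positiveClass label encoded as 1 (default: second level in sorted
#'   order); positive loadings then mark metabolites elevated in that class.
#' @return an [OPLSModel] with `yKind = "two_class"`.
#' @export
oplsdaFit <- function(X, labels, nOrth = 0L, positiveClass = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    metaboError("NotImplementedError",
                "OPLS-DA supports exactly two classes, got %d", length(lev))
  if (!is.null(positiveClass)) {
    if (!positiveClass %in% lev)
      metaboError("DesignError", "positiveClass '%s' is not a label", positiveClass)
    lev <- c(setdiff(lev, positiveClass), positiveClass)
  }
  if (any(table(labels) < 2L))
    metaboError("DesignError", "each class needs at least 2 samples")
  yEnc <- as.numeric(labels == lev[2])
  core <- .oplsCore(X, yEnc, nOrth)
  new("OPLSModel", wPred = core$w, tPred = core$t, pPred = core$p,
      WOrth = core$WO, TOrth = core$TO, POrth = core$PO,
      b = core$b, yCenter = core$yCenter, r2y = core$r2y,
      r2xPred = core$r2xPred, r2xOrth = core$r2xOrth,
      yKind = "two_class", classMap = stats::setNames(c(0, 1), lev),
      center = numeric(), scale = numeric())
}

#' @describeIn vip VIP for a single-predictive-component OPLS(-DA) model:
#'   `VIP_j = sqrt(J) * |w_pred_j|` (unit-norm weights), so the mean squared
#'   VIP is exactly 1.
#' @export
setMethod("vip", "OPLSModel", function(object) {
  J <- length(object@wPred)
  sqrt(J) * abs(object@wPred)
})

#' Predict from a fitted OPLS(-DA) model
#'
#' Orthogonal components are stripped from the new observations sequentially
#' (`t_o = X w_o; X <- X - t_o p_o'`), then `yhat = b * (X w) + yCenter`. For
#' a two-class model the decoded label of the nearest encoded value is
#' returned alongside.
#'
#' @param object a fitted [OPLSModel].
#' @param newdata matrix scaled with the training centers/scales.
#' @param ... unused.
#' @return list with `yhat`, `tPred` and (two-class only) `labels`.
#' @export
setMethod("predict", "OPLSModel", function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@wPred))
    metaboError("ShapeError", "newdata has %d columns, model expects %d",
                ncol(X), length(object@wPred))
  for (a in seq_len(ncol(object@WOrth))) {
    to <- (X %*% object@WOrth[, a])[, 1]
    X <- X - tcrossprod(to, object@POrth[, a])
  }
  t <- (X %*% object@wPred)[, 1]
  yhat <- object@b * t + object@yCenter
  out <- list(yhat = yhat, tPred = t)
  if (object@yKind == "two_class") {
    enc <- object@classMap
    out$labels <- names(enc)[apply(abs(outer(yhat, enc, "-")), 1, which.min)]
  }
  out
})
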