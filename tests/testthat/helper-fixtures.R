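# Small in-code fixtures shared across test files.

# Minimal MetaboSet: values is a samples-as-rows matrix with dimnames.
tinySet <- function(values, batch = rep(1L, nrow(values)),
                    bridge = rep(FALSE, nrow(values)),
                    group = rep("G", nrow(values)),
                    sample_id = rownames(values),
                    lod = NULL, panel = NULL) {
  design <- data.frame(measurement_id = rownames(values),
                       sample_id = sample_id, group = group,
                       batch = as.integer(batch),
                       replicate = seq_len(nrow(values)),
                       is_bridge = bridge, stringsAsFactors = FALSE)
  MetaboSet(values, design, annotations = panel, lod = lod)
}

# Centered random matrix with reproducible contents.
centeredMatrix <- function(n, J, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("m%02d", 1:J)))
  scale(X, center = TRUE, scale = FALSE)[, ]
}

# Rank-2 construction exercising the defining property of OPLS: a predictive
# part t_p w_p' plus structured variation t_o w_o' with t_o orthogonal to
# both y and t_p, and w_o deliberately NOT orthogonal to w_p (otherwise the
# orthogonal structure is invisible to the algorithm).
oplsConstruction <- function(n = 30, J = 12, seed = 4, orthScale = 3) {
  set.seed(seed)
  tp <- scale(rnorm(n), scale = FALSE)[, 1]
  y <- tp + 0.2 * rnorm(n)
  y <- y - mean(y)
  # orthogonal to the constant, to y and to t_p simultaneously (projecting
  # sequentially would reintroduce components: y and t_p are correlated)
  Q <- qr.Q(qr(cbind(1, y, tp)))
  to <- rnorm(n)
  to <- to - Q %*% crossprod(Q, to)
  to <- to[, 1]
  wp <- rnorm(J); wp <- wp / sqrt(sum(wp^2))
  wq <- rnorm(J)
  wo <- 0.7 * wp + wq / sqrt(sum(wq^2))      # overlaps w_p on purpose
  X0 <- tcrossprod(tp, wp)
  Xaug <- X0 + orthScale * tcrossprod(to, wo)
  dimnames(X0) <- dimnames(Xaug) <-
    list(sprintf("s%02d", 1:n), sprintf("m%02d", 1:J))
  list(X0 = X0, Xaug = Xaug, y = y, tp = tp, to = to, wp = wp, wo = wo)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free data only) — the independent oracle for small samples.
mwEnumP <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  uaObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  allRanks <- seq_len(na + nb)
  ua <- apply(sets, 2, function(ix) sum(allRanks[ix]) - na * (na + 1) / 2)
  pLo <- mean(ua <= uaObs)
  pHi <- mean(ua >= uaObs)
  min(1, 2 * min(pLo, pHi))
}
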