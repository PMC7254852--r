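## The cleaning/normalization chain, in its fixed order:
## LOD filter -> bridge-sample batch normalization -> total-sum (row)
## normalization -> autoscaling. Each stage returns the transformed data plus
## a PreprocessReport (a plain list) recording what was done.

.report <- function(stage, ...) {
  structure(c(list(stage = stage), list(...)), class = "PreprocessReport")
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat("PreprocessReport [", x$stage, "]\n", sep = "")
  for (f in setdiff(names(x), "stage")) {
    v <- x[[f]]
    cat("  ", f, ": ", if (length(v) > 6) paste0("<", length(v), " values>")
        else paste(format(v, digits = 4), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

.setConc <- function(mset, values) {
  SummarizedExperiment::assay(mset, "concentrations") <- t(values)
  mset
}

#' Exclude metabolites with too many values below the detection limit
#'
#' A metabolite is dropped iff the fraction of its measurements strictly below
#' its LOD exceeds `maxFraction` (strict `>`, so exactly 20% at the default is
#' retained). Retained values are kept as reported — no imputation. Missing
#' (`NA`) measurements count as below the limit (not detected).
#'
#' @param mset a [MetaboSet] with LOD annotation.
#' @param maxFraction largest tolerated below-LOD fraction (default 0.20).
#' @return list with `mset` (retained metabolites only) and `report`.
#' @export
filterByLOD <- function(mset, maxFraction = 0.20) {
  if (maxFraction < 0 || maxFraction >= 1)
    metaboError("SpecError", "maxFraction must be in [0, 1)")
  lod <- lodValues(mset)
  if (any(is.na(lod)))
    metaboError("MissingLODError", "no LOD for: %s",
                paste(head(names(lod)[is.na(lod)], 5), collapse = ", "))
  v <- concentrations(mset)                     # samples x metabolites
  below <- is.na(v) | sweep(v, 2, lod[colnames(v)], "<")
  frac <- colMeans(below)
  drop <- frac > maxFraction
  report <- .report("lod_filter",
                    n_input_metabolites = ncol(v),
                    n_retained = sum(!drop),
                    dropped_ids = colnames(v)[drop],
                    below_lod_fraction = frac,
                    max_fraction = maxFraction)
  list(mset = mset[!drop, ], report = report)
}

.pickBridge <- function(design, referenceBatch) {
  batches <- sort(unique(design$batch))
  cand <- sort(unique(design$sample_id[design$is_bridge]))
  for (s in cand) {
    got <- design$batch[design$sample_id == s]
    if (all(batches %in% got)) return(s)
  }
  metaboError("DegenerateBridgeError",
              "no bridge sample measured in every batch")
}

#' Batch normalization against a bridge sample
#'
#' For each non-reference batch b and metabolite j the factor
#' `f_bj = value(bridge, reference batch, j) / value(bridge, b, j)` rescales
#' every measurement of batch b; the reference batch is untouched. The bridge
#' measurements actually used (one per batch, all belonging to the normalizer
#' sample) are removed from the analysis table; the remaining bridge
#' replicates stay for verification. With a single batch this is the
#' identity.
#'
#' @param mset a [MetaboSet].
#' @param referenceBatch batch whose scale is kept (default 1).
#' @param bridgeSample normalizer sample id; default the lexicographically
#'   first bridge sample measured in every batch.
#' @return list with `mset` and `report` (the per-batch factors).
#' @export
bridgeNormalize <- function(mset, referenceBatch = 1L, bridgeSample = NULL) {
  design <- studyDesign(mset)
  batches <- sort(unique(design$batch))
  if (length(batches) == 1L) {
    return(list(mset = mset,
                report = .report("bridge_normalize", bridge_sample = NA_character_,
                                 reference_batch = referenceBatch,
                                 per_batch_factors = list())))
  }
  if (!referenceBatch %in% batches)
    metaboError("DesignError", "reference batch %s not present", referenceBatch)
  if (is.null(bridgeSample)) bridgeSample <- .pickBridge(design, referenceBatch)
  v <- concentrations(mset)
  bridgeRows <- design$measurement_id[design$sample_id == bridgeSample]
  refRow <- design$measurement_id[design$sample_id == bridgeSample &
                                    design$batch == referenceBatch]
  if (length(refRow) != 1L)
    metaboError("DegenerateBridgeError",
                "bridge sample '%s' not measured exactly once in the reference batch",
                bridgeSample)
  refVal <- v[refRow, ]
  factors <- list()
  for (b in setdiff(batches, referenceBatch)) {
    bRow <- design$measurement_id[design$sample_id == bridgeSample & design$batch == b]
    if (length(bRow) != 1L)
      metaboError("DegenerateBridgeError",
                  "bridge sample '%s' missing from batch %s", bridgeSample, b)
    bVal <- v[bRow, ]
    if (any(is.na(bVal) | bVal == 0 | is.na(refVal) | refVal == 0))
      metaboError("DegenerateBridgeError",
                  "bridge value missing or zero in batch %s", b)
    f <- refVal / bVal
    inBatch <- design$measurement_id[design$batch == b]
    v[inBatch, ] <- sweep(v[inBatch, , drop = FALSE], 2, f, "*")
    factors[[as.character(b)]] <- f
  }
  keep <- !rownames(v) %in% bridgeRows
  out <- .setConc(mset, v)[, keep]
  list(mset = out,
       report = .report("bridge_normalize", bridge_sample = bridgeSample,
                        reference_batch = referenceBatch,
                        removed_measurements = bridgeRows,
                        per_batch_factors = factors))
}

#' Collapse bridge re-runs to a single measurement per sample
#'
#' After bridge normalization the remaining bridge samples still carry one
#' measurement per batch; downstream models need one row per sample. Keeps
#' the reference-batch measurement of any sample measured more than once.
#'
#' @param mset a [MetaboSet].
#' @param referenceBatch batch whose measurement is kept.
#' @return a [MetaboSet] with one measurement per sample.
#' @export
collapseBridge <- function(mset, referenceBatch = 1L) {
  design <- studyDesign(mset)
  dup <- names(which(table(design$sample_id) > 1L))
  keep <- !(design$sample_id %in% dup) | design$batch == referenceBatch
  mset[, keep]
}

#' Total-sum (row) normalization
#'
#' Divides each measurement row by its total metabolite sum, then multiplies
#' by the grand mean of the original totals so values keep a micromolar-like
#' magnitude; after the transform all row totals are equal. Guards against
#' spurious between-sample differences driven by the amount of collected
#' material.
#'
#' @param mset a [MetaboSet].
#' @return list with `mset` and `report` (original row totals).
#' @export
rowNormalize <- function(mset) {
  v <- concentrations(mset)
  totals <- rowSums(v, na.rm = TRUE)
  if (any(!is.finite(totals)) || any(totals <= 0))
    metaboError("DegenerateSampleError", "zero or invalid row total for: %s",
                paste(head(rownames(v)[totals <= 0], 5), collapse = ", "))
  v <- sweep(v, 1, totals, "/") * mean(totals)
  list(mset = .setConc(mset, v),
       report = .report("row_normalize", row_totals = totals,
                        restored_total = mean(totals)))
}

#' Autoscale a concentration matrix
#'
#' Centers every metabolite to mean 0 and scales to unit sample standard
#' deviation (n-1 denominator), recording centers and scales for the inverse
#' transform.
#'
#' @param x samples-as-rows matrix or a [MetaboSet].
#' @return list with `X` (scaled matrix), `centers`, `scales` and `report`.
#' @export
autoscale <- function(x) {
  if (is(x, "MetaboSet")) x <- concentrations(x)
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  if (any(!is.finite(scales)) || any(scales == 0))
    metaboError("ConstantMetaboliteError",
                "zero-variance metabolite(s): %s",
                paste(head(colnames(x)[!is.finite(scales) | scales == 0], 5),
                      collapse = ", "))
  X <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  list(X = X, centers = centers, scales = scales,
       report = .report("autoscale", centers = centers, scales = scales,
                        sd_denominator = "n-1"))
}

#' Invert an autoscaling transform
#'
#' @param X scaled matrix.
#' @param scaling the list returned by [autoscale()].
#' @return matrix on the original concentration scale.
#' @export
inverseAutoscale <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$scales, "*"), 2, scaling$centers, "+")
}

#' Run the full preprocessing chain
#'
#' LOD filter, bridge batch normalization, collapse of duplicated bridge
#' runs, total-sum normalization, autoscaling — in that fixed order. The
#' composition is deterministic.
#'
#' @param mset a [MetaboSet] with LOD annotation.
#' @param maxFraction LOD-filter threshold.
#' @param referenceBatch reference batch of the bridge normalization.
#' @param bridgeSample optional normalizer sample id.
#' @return list with `mset` (cleaned, still in concentration units), `X`
#'   (autoscaled matrix ready for latent models), `scaling` and `reports`
#'   (one per stage).
#' @export
preprocessPipeline <- function(mset, maxFraction = 0.20, referenceBatch = 1L,
                               bridgeSample = NULL) {
  s1 <- filterByLOD(mset, maxFraction)
  s2 <- bridgeNormalize(s1$mset, referenceBatch, bridgeSample)
  s2$mset <- collapseBridge(s2$mset, referenceBatch)
  s3 <- rowNormalize(s2$mset)
  s4 <- autoscale(s3$mset)
  list(mset = s3$mset, X = s4$X, scaling = s4,
       reports = list(lod = s1$report, bridge = s2$report, row = s3$report,
                      scale = s4$report))
}
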