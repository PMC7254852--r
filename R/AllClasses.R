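#' MetaboSet: a targeted-metabolomics panel experiment
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' one `concentrations` assay (metabolites as rows, measurements as columns,
#' micromolar by default), the study design in `colData` (`sample_id`,
#' `group`, `batch`, `replicate`, `is_bridge`, `severity_rank`) and the panel
#' annotation plus per-metabolite limits of detection in `rowData` (`klass`,
#' `subclass`, `total_carbons`, `total_double_bonds`, `hydroxylated`, `lod`).
#'
#' Column names are unique measurement identifiers; a bridge sample run in
#' several batches keeps one `sample_id` shared by its per-batch measurement
#' columns. Missing measurements are `NA`, never 0: zero is a legal
#' concentration bound, absence is not.
#'
#' @slot unit concentration unit of the assay (default `"uM"`).
#' @export
setClass("MetaboSet",
         contains = "SummarizedExperiment",
         slots = c(unit = "character"),
         prototype = prototype(unit = "uM"))

.validMetaboSet <- function(object) {
  msg <- character()
  if (!"concentrations" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'concentrations' is required")
  else {
    v <- SummarizedExperiment::assay(object, "concentrations")
    if (!is.numeric(v)) msg <- c(msg, "concentrations must be numeric")
    else {
      if (any(is.infinite(v))) msg <- c(msg, "concentrations must be finite (use NA for missing)")
      if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "concentrations must be non-negative")
    }
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "measurement (column) identifiers must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "metabolite (row) identifiers must be unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "group", "batch", "replicate", "is_bridge")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if ("batch" %in% colnames(cd) && any(cd$batch < 1L))
    msg <- c(msg, "batch numbers must be >= 1")
  rd <- SummarizedExperiment::rowData(object)
  if (all(c("klass", "subclass") %in% colnames(rd))) {
    bad <- (rd$subclass %in% c("PC_aa", "PC_ae", "lysoPC") & rd$klass != "glycerophospholipid") |
           (rd$subclass %in% c("SM", "SM_OH") & rd$klass != "sphingolipid")
    if (any(bad)) msg <- c(msg, "lipid subclass inconsistent with class")
    if ("total_carbons" %in% colnames(rd) &&
        any(rd$subclass != "none" & rd$total_carbons <= 0))
      msg <- c(msg, "lipids (subclass != none) must have total_carbons > 0")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MetaboSet", .validMetaboSet)

#' Construct a MetaboSet
#'
#' @param values numeric concentration matrix in the canonical samples-as-rows
#'   orientation; row names are measurement ids, column names metabolite ids.
#' @param design data.frame as returned by [readDesign()] / [defaultDesign()]:
#'   one row per measurement, columns `measurement_id`, `sample_id`, `group`,
#'   `batch`, `replicate`, `is_bridge` and optionally `severity_rank`.
#' @param annotations optional panel annotation data.frame
#'   ([readAnnotations()] / [defaultPanel()]).
#' @param lod optional named numeric vector or data.frame
#'   (`metabolite_id`, `lod`) of detection limits.
#' @param unit concentration unit.
#' @return a validated [MetaboSet].
#' @export
MetaboSet <- function(values, design, annotations = NULL, lod = NULL, unit = "uM") {
  values <- validateConcentrations(values)
  mids <- colnames(values)
  design <- as.data.frame(design)
  if (!"measurement_id" %in% colnames(design))
    design$measurement_id <- design$sample_id
  rownames(design) <- design$measurement_id
  miss <- setdiff(rownames(values), design$measurement_id)
  if (length(miss))
    metaboError("DesignError", "measurements absent from design: %s",
                paste(head(miss, 5), collapse = ", "))
  design <- design[rownames(values), , drop = FALSE]
  if (!"severity_rank" %in% colnames(design)) design$severity_rank <- NA_integer_

  if (is.null(annotations)) {
    rd <- S4Vectors::DataFrame(row.names = mids)
  } else {
    annotations <- as.data.frame(annotations)
    rownames(annotations) <- annotations$metabolite_id
    miss <- setdiff(mids, annotations$metabolite_id)
    if (length(miss))
      metaboError("FormatError", "metabolites absent from annotation: %s",
                  paste(head(miss, 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(annotations[mids, , drop = FALSE])
  }
  if (!is.null(lod)) {
    if (is.data.frame(lod)) lod <- stats::setNames(lod$lod, lod$metabolite_id)
    rd$lod <- unname(lod[mids])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(concentrations = t(values)),
    colData = S4Vectors::DataFrame(design),
    rowData = rd)
  new("MetaboSet", se, unit = unit)
}

#' @describeIn MetaboSet accessor for the concentration matrix.
#' @param object,samplesAsRows see generic.
#' @export
setMethod("concentrations", "MetaboSet", function(object, samplesAsRows = TRUE) {
  m <- SummarizedExperiment::assay(object, "concentrations")
  if (samplesAsRows) t(m) else m
})

#' @describeIn MetaboSet accessor for the study design.
#' @export
setMethod("studyDesign", "MetaboSet", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @describeIn MetaboSet accessor for the panel annotation.
#' @export
setMethod("panelAnnotation", "MetaboSet", function(object) {
  rd <- as.data.frame(SummarizedExperiment::rowData(object))
  rd$metabolite_id <- rownames(rd)
  rd[, c("metabolite_id", setdiff(colnames(rd), "metabolite_id")), drop = FALSE]
})

#' @describeIn MetaboSet accessor for the per-metabolite detection limits.
#' @export
setMethod("lodValues", "MetaboSet", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"lod" %in% colnames(rd))
    metaboError("MissingLODError", "MetaboSet carries no LOD annotation")
  stats::setNames(rd$lod, rownames(object))
})

setMethod("show", "MetaboSet", function(object) {
  cat("MetaboSet:", nrow(object), "metabolites x", ncol(object),
      "measurements [", object@unit, "]\n")
  d <- SummarizedExperiment::colData(object)
  cat("  groups:", paste(unique(d$group), collapse = ", "), "\n")
  cat("  batches:", paste(sort(unique(d$batch)), collapse = ", "),
      "| bridge measurements:", sum(d$is_bridge), "\n")
  if ("lod" %in% colnames(SummarizedExperiment::rowData(object)))
    cat("  LOD annotation present\n")
})

#' Principal component model fitted by NIPALS
#'
#' @slot scores n x A score matrix (column 1 is t1).
#' @slot loadings J x A unit-norm loading matrix.
#' @slot r2x fraction of total X-variance captured per component.
#' @slot totalSS total sum of squares of the fitted (centered/scaled) matrix.
#' @slot center,scale the centering/scaling applied upstream (may be empty).
#' @export
setClass("PCAModel",
         slots = c(scores = "matrix", loadings = "matrix", r2x = "numeric",
                   totalSS = "numeric", center = "numeric", scale = "numeric"))

.validPCA <- function(object) {
  msg <- character()
  A <- ncol(object@scores)
  if (ncol(object@loadings) != A || length(object@r2x) != A)
    msg <- c(msg, "scores, loadings and r2x must agree on component count")
  pn <- colSums(object@loadings^2)
  if (any(abs(pn - 1) > 1e-6)) msg <- c(msg, "loadings must be unit norm")
  if (A > 1) {
    g <- crossprod(object@scores)
    off <- abs(g[upper.tri(g)])
    lim <- 1e-8 * sqrt(diag(g) %o% diag(g))[upper.tri(g)]
    if (any(off > pmax(lim, 1e-12))) msg <- c(msg, "score columns must be orthogonal")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PCAModel", .validPCA)

#' @describeIn PCAModel score matrix.
#' @param object a PCAModel.
#' @param ... unused.
#' @export
setMethod("scores", "PCAModel", function(object, ...) object@scores)

#' @describeIn PCAModel loading matrix.
#' @export
setMethod("loadings", "PCAModel", function(object, ...) object@loadings)

#' @describeIn PCAModel explained-variance fractions.
#' @export
setMethod("r2x", "PCAModel", function(object) object@r2x)

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel (NIPALS):", nrow(object@scores), "samples,",
      ncol(object@scores), "components\n")
  cat("  R2X:", paste(sprintf("%.3f", object@r2x), collapse = " "), "\n")
})

#' Single-response OPLS(-DA) model
#'
#' One predictive latent variable plus `A_orth` Y-orthogonal components, per
#' the single-y orthogonal projections to latent structures algorithm.
#'
#' @slot wPred unit-norm predictive weight vector.
#' @slot tPred predictive scores.
#' @slot pPred predictive loadings.
#' @slot WOrth,TOrth,POrth orthogonal-component weight/score/loading matrices.
#' @slot b regression coefficient of (centered) y on tPred.
#' @slot yCenter centering constant of y (class midpoint for OPLS-DA).
#' @slot r2y explained Y-variance on the training data.
#' @slot r2xPred,r2xOrth explained X-variance of the predictive and
#'   orthogonal parts.
#' @slot yKind `"quantitative"` or `"two_class"`.
#' @slot classMap named numeric label -> 0/1 encoding (two_class only).
#' @slot center,scale training centers/scales when the model was fitted
#'   through a pipeline that scaled for the caller (may be empty).
#' @export
setClass("OPLSModel",
         slots = c(wPred = "numeric", tPred = "numeric", pPred = "numeric",
                   WOrth = "matrix", TOrth = "matrix", POrth = "matrix",
                   b = "numeric", yCenter = "numeric", r2y = "numeric",
                   r2xPred = "numeric", r2xOrth = "numeric",
                   yKind = "character", classMap = "numeric",
                   center = "numeric", scale = "numeric"))

.validOPLS <- function(object) {
  msg <- character()
  if (abs(sum(object@wPred^2) - 1) > 1e-8)
    msg <- c(msg, "wPred must be unit norm")
  if (ncol(object@WOrth) > 0) {
    ip <- abs(crossprod(object@wPred, object@WOrth))
    if (any(ip > 1e-10)) msg <- c(msg, "orthogonal weights must be orthogonal to wPred")
  }
  if (!object@yKind %in% c("quantitative", "two_class"))
    msg <- c(msg, "yKind must be 'quantitative' or 'two_class'")
  if (length(msg)) msg else TRUE
}
setValidity("OPLSModel", .validOPLS)

#' @describeIn OPLSModel predictive + orthogonal scores (tPred first column).
#' @param object an OPLSModel.
#' @param ... unused.
#' @export
setMethod("scores", "OPLSModel", function(object, ...)
  cbind(t_pred = object@tPred, object@TOrth))

#' @describeIn OPLSModel predictive loadings (column `p_pred`) and orthogonal
#'   loadings.
#' @export
setMethod("loadings", "OPLSModel", function(object, ...)
  cbind(p_pred = object@pPred, object@POrth))

#' @describeIn OPLSModel explained X-variance: predictive then orthogonal.
#' @export
setMethod("r2x", "OPLSModel", function(object)
  c(pred = object@r2xPred, orth = object@r2xOrth))

#' @describeIn OPLSModel explained Y-variance on training data.
#' @export
setMethod("r2y", "OPLSModel", function(object) object@r2y)

setMethod("show", "OPLSModel", function(object) {
  cat(sprintf("OPLSModel (%s): %d samples, 1 predictive + %d orthogonal\n",
              object@yKind, length(object@tPred), ncol(object@TOrth)))
  cat(sprintf("  R2Y = %.4f | R2X pred = %.3f, orth = %.3f\n",
              object@r2y, object@r2xPred, object@r2xOrth))
})

#' Cross-validation and permutation report for an OPLS(-DA) model
#'
#' @slot q2yCum cross-validated Q2Y_cum = 1 - PRESS/SSY.
#' @slot press prediction residual sum of squares (out-of-fold).
#' @slot ssy total sum of squares of centered y.
#' @slot nFolds folds used.
#' @slot nOrthSelected orthogonal components of the validated model.
#' @slot permQ2 per-permutation Q2 values.
#' @slot q2yCumPerm summary (mean) of permQ2.
#' @slot cvAnovaF,cvAnovaP CV-ANOVA F statistic and upper-tail p-value.
#' @export
setClass("ValidationReport",
         slots = c(q2yCum = "numeric", press = "numeric", ssy = "numeric",
                   nFolds = "integer", nOrthSelected = "integer",
                   permQ2 = "numeric", q2yCumPerm = "numeric",
                   cvAnovaF = "numeric", cvAnovaP = "numeric"))

.validReport <- function(object) {
  msg <- character()
  if (length(object@press) && length(object@ssy) &&
      abs(object@q2yCum - (1 - object@press / object@ssy)) > 1e-12)
    msg <- c(msg, "q2yCum must equal 1 - press/ssy")
  if (length(msg)) msg else TRUE
}
setValidity("ValidationReport", .validReport)

#' @describeIn ValidationReport cross-validated Q2Y_cum.
#' @param object a ValidationReport.
#' @export
setMethod("q2yCum", "ValidationReport", function(object) object@q2yCum)

#' @describeIn ValidationReport the low-overfit verdict triple.
#' @export
setMethod("verdict", "ValidationReport", function(object) {
  isTRUE(object@q2yCum > 0.5) &&
    isTRUE(object@q2yCumPerm < 0) &&
    isTRUE(object@cvAnovaP < 0.05)
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: Q2Y_cum = %.4f (%d folds, %d orthogonal)\n",
              object@q2yCum, object@nFolds, object@nOrthSelected))
  if (length(object@permQ2))
    cat(sprintf("  permuted Q2: mean = %.3f over %d permutations\n",
                object@q2yCumPerm, length(object@permQ2)))
  cat(sprintf("  CV-ANOVA: F = %.3f, p = %.3g\n", object@cvAnovaF, object@cvAnovaP))
  cat("  verdict (low overfit):", verdict(object), "\n")
})
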