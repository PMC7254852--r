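#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd cor pf qf predict lm coef wilcox.test
#' @importFrom utils read.table write.table head
NULL

#' Latent-variable scores
#'
#' Extract the score matrix (sample coordinates on the latent components) of a
#' fitted [PCAModel] or [OPLSModel].
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return numeric matrix, samples in rows.
#' @export
setGeneric("scores", function(object, ...) standardGeneric("scores"))

#' Latent-variable loadings
#'
#' Extract the loading matrix (metabolite weights of each latent component).
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return numeric matrix, metabolites in rows.
#' @export
setGeneric("loadings", function(object, ...) standardGeneric("loadings"))

#' Explained X-variance per component
#'
#' @param object a fitted model.
#' @return numeric vector of R2X fractions.
#' @export
setGeneric("r2x", function(object) standardGeneric("r2x"))

#' Explained Y-variance of a supervised model
#'
#' @param object a fitted [OPLSModel].
#' @return scalar R2Y on the training data.
#' @export
setGeneric("r2y", function(object) standardGeneric("r2y"))

#' Variable importance in projection
#'
#' VIP of each metabolite in a fitted OPLS(-DA) model, normalised so the mean
#' squared VIP over metabolites is 1; VIP >= 1 is the conventional importance
#' cut-off.
#'
#' @param object a fitted [OPLSModel].
#' @return named non-negative numeric vector.
#' @export
setGeneric("vip", function(object) standardGeneric("vip"))

#' Concentration matrix of a MetaboSet
#'
#' @param object a [MetaboSet].
#' @param samplesAsRows return in the canonical samples-as-rows orientation
#'   (default) or metabolites-as-rows.
#' @return numeric matrix of concentrations.
#' @export
setGeneric("concentrations",
           function(object, samplesAsRows = TRUE) standardGeneric("concentrations"))

#' Study design table of a MetaboSet
#'
#' @param object a [MetaboSet].
#' @return data.frame with one row per measurement.
#' @export
setGeneric("studyDesign", function(object) standardGeneric("studyDesign"))

#' Panel annotation table of a MetaboSet
#'
#' @param object a [MetaboSet].
#' @return data.frame with one row per metabolite.
#' @export
setGeneric("panelAnnotation", function(object) standardGeneric("panelAnnotation"))

#' Limits of detection of a MetaboSet
#'
#' @param object a [MetaboSet].
#' @return named numeric vector of per-metabolite LOD (same unit as the data).
#' @export
setGeneric("lodValues", function(object) standardGeneric("lodValues"))

#' Cross-validated goodness of prediction
#'
#' @param object a [ValidationReport].
#' @return scalar Q2Y_cum = 1 - PRESS/SSY.
#' @export
setGeneric("q2yCum", function(object) standardGeneric("q2yCum"))

#' Low-overfit verdict of a validated model
#'
#' TRUE when Q2Y_cum > 0.5, the mean permuted Q2 is negative and the CV-ANOVA
#' p-value is below 0.05 — the conventional triple for accepting a latent
#' model as predictive rather than overfitted.
#'
#' @param object a [ValidationReport].
#' @return logical scalar.
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))
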