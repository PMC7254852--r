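## The two study analyses and their derived outputs:
##  A. OPLS-DA of knockout vs wild type, with VIP/loading signature.
##  B. Transfected-only PCA -> t1 as a quantitative severity proxy -> OPLS,
##     with VIP/Spearman signature, group ordering and index regressions.

#' Pipeline configuration
#'
#' @param wtGroup,koGroup wild-type and knockout group labels.
#' @param mostSevere group expected at the severe end; t1 is oriented so this
#'   group has the largest mean score.
#' @param contrast two groups compared by Mann-Whitney on t1 (default the
#'   hypomorphic variant against the wild-type cDNA control).
#' @param transfectedGroups groups entering the severity analysis; default
#'   the design's `transfected` flag.
#' @param k cross-validation folds.
#' @param nPerm permutations for the validation null (0 skips).
#' @param seed seed for the permutation draws.
#' @param vipThreshold VIP cut-off of the signature (conventionally 1).
#' @param topLoadingFraction keep this fraction of VIP-passing metabolites,
#'   ranked by |loading| (or |rho|); 1 keeps all.
#' @param maxOrth largest number of orthogonal components scanned.
#' @return configuration list.
#' @export
pipelineConfig <- function(wtGroup = "Opa1_WT", koGroup = "Opa1_KO",
                           mostSevere = "R445H",
                           contrast = c("I382M", "ISO1"),
                           transfectedGroups = NULL,
                           k = 7L, nPerm = 200L, seed = 7L,
                           vipThreshold = 1, topLoadingFraction = 1,
                           maxOrth = 5L) {
  list(wtGroup = wtGroup, koGroup = koGroup, mostSevere = mostSevere,
       contrast = contrast, transfectedGroups = transfectedGroups,
       k = k, nPerm = nPerm, seed = seed, vipThreshold = vipThreshold,
       topLoadingFraction = topLoadingFraction, maxOrth = maxOrth)
}

## Fit with the CV-selected component count, backing off when the full-data
## matrix supports fewer orthogonal components than the folds did (with y
## exactly the first principal score, the predictive component IS PC1 and no
## orthogonal component is extractable at all).
.fitCapped <- function(fitFun, nOrth) {
  repeat {
    m <- tryCatch(fitFun(nOrth), RankError = function(e) NULL)
    if (!is.null(m)) return(list(model = m, nOrth = nOrth))
    if (nOrth == 0L) metaboError("RankError", "predictive component unfittable")
    nOrth <- nOrth - 1L
  }
}

.makeSignature <- function(vipv, assoc, vipThreshold, topFraction) {
  keep <- which(vipv >= vipThreshold & !is.na(assoc))
  keep <- keep[order(-abs(assoc[keep]))]
  keep <- keep[seq_len(ceiling(length(keep) * topFraction))]
  data.frame(metabolite_id = names(vipv)[keep],
             vip = unname(vipv[keep]),
             association = unname(assoc[keep]),
             direction = ifelse(assoc[keep] >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analysis A: OPLS-DA of knockout vs wild type
#'
#' Subsets the cleaned data to the two groups, autoscales, selects the number
#' of orthogonal components by cross-validation, fits the OPLS-DA (knockout
#' encoded 1, so positive loadings mark metabolites elevated in the
#' knockout), validates (Q2Y, permutations, CV-ANOVA) and derives the
#' VIP/loading signature and the volcano table.
#'
#' @param mset cleaned [MetaboSet] (post normalization, concentration scale).
#' @param config a [pipelineConfig()].
#' @return list: `model`, `validation`, `signature`, `volcano`, `nOrth`.
#' @export
runKOvsWT <- function(mset, config = pipelineConfig()) {
  design <- studyDesign(mset)
  pick <- design$group %in% c(config$wtGroup, config$koGroup)
  if (!all(c(config$wtGroup, config$koGroup) %in% design$group))
    metaboError("DesignError", "both contrast groups must be present")
  sub <- mset[, pick]
  labels <- studyDesign(sub)$group
  if (any(table(labels) < 3L))
    metaboError("DesignError", "each group needs >= 3 samples")
  raw <- concentrations(sub)
  sc <- autoscale(raw)
  nOrth <- selectNOrth(raw, labels, maxOrth = config$maxOrth, k = config$k)
  fit <- .fitCapped(function(A) oplsdaFit(sc$X, labels, A,
                                          positiveClass = config$koGroup), nOrth)
  model <- fit$model; nOrth <- fit$nOrth
  validation <- validateModel(raw, as.numeric(labels == config$koGroup),
                              nOrth = nOrth, k = config$k,
                              nPerm = config$nPerm, seed = config$seed)
  vipv <- vip(model)
  loading <- model@pPred
  volcano <- data.frame(metabolite_id = names(vipv),
                        loading = unname(loading), vip = unname(vipv),
                        row.names = NULL, stringsAsFactors = FALSE)
  sig <- .makeSignature(vipv, loading, config$vipThreshold,
                        config$topLoadingFraction)
  list(model = model, validation = validation, signature = sig,
       volcano = volcano, nOrth = nOrth)
}

#' Analysis B: transfected-only severity ranking
#'
#' Subsets to the transfected groups, autoscales, fits a two-component NIPALS
#' PCA and orients t1 so the declared most-severe group sits at the positive
#' end. t1 then serves as the quantitative response of an OPLS model
#' (validated like analysis A); per-metabolite Spearman rho against t1 feeds
#' the volcano and the signature; the groups are ordered by mean t1, and the
#' configured contrast pair is compared by Mann-Whitney on t1.
#'
#' @param mset cleaned [MetaboSet].
#' @param config a [pipelineConfig()].
#' @return list: `t1`, `groupMeanT1`, `groupOrder`, `pca`, `model`,
#'   `validation`, `signature`, `volcano`, `rho`, `contrastP`, `nOrth`.
#' @export
runVariantRanking <- function(mset, config = pipelineConfig()) {
  design <- studyDesign(mset)
  groups <- config$transfectedGroups
  if (is.null(groups)) {
    if (!"transfected" %in% colnames(design))
      metaboError("DesignError",
                  "no transfected flag in design and no transfectedGroups in config")
    groups <- unique(design$group[design$transfected])
  }
  if (length(groups) < 3L)
    metaboError("DesignError", "severity ranking needs >= 3 transfected groups")
  sub <- mset[, design$group %in% groups]
  dsub <- studyDesign(sub)
  raw <- concentrations(sub)
  sc <- autoscale(raw)
  pca <- pcaFit(sc$X, nComponents = 2L)
  t1 <- scores(pca)[, 1]
  if (mean(t1[dsub$group == config$mostSevere]) < 0) {
    t1 <- -t1
    pca@scores[, 1] <- -pca@scores[, 1]
    pca@loadings[, 1] <- -pca@loadings[, 1]
  }
  nOrth <- selectNOrth(raw, t1, maxOrth = config$maxOrth, k = config$k)
  fit <- .fitCapped(function(A) oplsFit(sc$X, t1, A), nOrth)
  model <- fit$model; nOrth <- fit$nOrth
  validation <- validateModel(raw, t1, nOrth = nOrth, k = config$k,
                              nPerm = config$nPerm, seed = config$seed)
  vipv <- vip(model)
  rho <- apply(raw, 2, function(col) suppressWarnings(spearmanRho(col, t1)))
  volcano <- data.frame(metabolite_id = names(vipv), rho = unname(rho[names(vipv)]),
                        vip = unname(vipv), row.names = NULL,
                        stringsAsFactors = FALSE)
  sig <- .makeSignature(vipv, rho[names(vipv)], config$vipThreshold,
                        config$topLoadingFraction)
  gm <- tapply(t1, dsub$group, mean)
  contrast <- config$contrast
  cp <- if (all(contrast %in% dsub$group))
    mannWhitneyU(t1[dsub$group == contrast[1]], t1[dsub$group == contrast[2]])$p
  else NA_real_
  list(t1 = t1, groupMeanT1 = gm, groupOrder = names(sort(gm)),
       pca = pca, model = model, validation = validation, signature = sig,
       volcano = volcano, rho = rho, contrastP = cp, nOrth = nOrth)
}

#' Overlap between two signatures
#'
#' @param a,b signature data.frames (or vectors of metabolite ids).
#' @return list with `nShared`, `fractionOfA`, `fractionOfB` (both
#'   denominators reported; empty signatures give 0).
#' @export
signatureOverlap <- function(a, b) {
  ida <- if (is.data.frame(a)) a$metabolite_id else as.character(a)
  idb <- if (is.data.frame(b)) b$metabolite_id else as.character(b)
  shared <- length(intersect(ida, idb))
  list(nShared = shared,
       fractionOfA = if (length(ida)) shared / length(ida) else 0,
       fractionOfB = if (length(idb)) shared / length(idb) else 0)
}
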