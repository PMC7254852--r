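## Lipid-class and polyamine indices tracked against severity, computed on
## post-normalization concentrations (ratios on autoscaled data would be
## meaningless). PUFA / MUFA / SFA are defined on the summed double-bond
## count of the sum-composition shorthand: >= 2, == 1, == 0.

.colOrNA <- function(v, id) {
  if (id %in% colnames(v)) v[, id] else {
    metaboWarning("MissingAnalyteWarning", "analyte '%s' absent; index is NA", id)
    rep(NA_real_, nrow(v))
  }
}

.safeRatio <- function(num, den) {
  out <- num / den
  bad <- !is.na(den) & den == 0
  if (any(bad, na.rm = TRUE))
    metaboWarning("DegenerateWarning", "zero denominator; ratio set to NA")
  out[bad] <- NA_real_
  out[is.na(den) | is.na(num)] <- NA_real_
  out
}

#' Per-sample derived metabolic indices
#'
#' The severity-tracking sums and ratios: total amino acids, t4-OH-Pro,
#' spermine/spermidine, SM 18:0 / SM 16:0, the two hydroxylated
#' sphingomyelins SM (OH) C22:1 and C22:2, the polyunsaturated diacyl PC sum
#' (PUFA aa), PUFA/MUFA within diacyl PC, and MUFA/SFA within acyl-alkyl PC.
#' Missing analytes (e.g. removed by the LOD filter) yield a missing index
#' with a warning, never an infinity.
#'
#' @param mset cleaned [MetaboSet] (concentration scale).
#' @return data.frame, one row per measurement, one column per index.
#' @export
derivedIndices <- function(mset) {
  v <- concentrations(mset)
  ann <- panelAnnotation(mset)
  if (!"klass" %in% colnames(ann))
    metaboError("FormatError", "MetaboSet carries no panel annotation")
  aaIds <- ann$metabolite_id[ann$klass == "amino_acid"]
  sumOf <- function(ids) {
    ids <- intersect(ids, colnames(v))
    if (!length(ids)) return(rep(NA_real_, nrow(v)))
    rowSums(v[, ids, drop = FALSE])
  }
  pcaa <- ann$metabolite_id[ann$subclass == "PC_aa"]
  pcae <- ann$metabolite_id[ann$subclass == "PC_ae"]
  db <- stats::setNames(ann$total_double_bonds, ann$metabolite_id)
  pufaAA <- sumOf(pcaa[db[pcaa] >= 2])
  mufaAA <- sumOf(pcaa[db[pcaa] == 1])
  mufaAE <- sumOf(pcae[db[pcae] == 1])
  sfaAE <- sumOf(pcae[db[pcae] == 0])
  data.frame(
    measurement_id = rownames(v),
    aa_sum = sumOf(aaIds),
    t4_oh_pro = .colOrNA(v, "t4-OH-Pro"),
    spermine_spermidine_ratio = .safeRatio(.colOrNA(v, "Spermine"),
                                           .colOrNA(v, "Spermidine")),
    sm18_sm16_ratio = .safeRatio(.colOrNA(v, "SM C18:0"),
                                 .colOrNA(v, "SM C16:0")),
    sm_oh_22_1 = .colOrNA(v, "SM (OH) C22:1"),
    sm_oh_22_2 = .colOrNA(v, "SM (OH) C22:2"),
    pufa_aa_sum = pufaAA,
    pufa_mufa_aa_ratio = .safeRatio(pufaAA, mufaAA),
    mufa_sfa_ae_ratio = .safeRatio(mufaAE, sfaAE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress an index on the severity score t1
#'
#' Ordinary least squares of per-sample index values on t1, with R2 as the
#' squared Pearson correlation.
#'
#' @param index numeric per-sample index values.
#' @param t1 matching per-sample t1 scores.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
regressVsT1 <- function(index, t1) {
  ok <- is.finite(index) & is.finite(t1)
  if (sum(ok) < 3L)
    metaboError("DegenerateError", "need >= 3 paired finite values")
  if (stats::sd(t1[ok]) == 0)
    metaboError("DegenerateError", "t1 has zero variance")
  fit <- stats::lm(index[ok] ~ t1[ok])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = stats::cor(index[ok], t1[ok])^2, n = sum(ok))
}
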