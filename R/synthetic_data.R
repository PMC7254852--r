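## Synthetic study generator: a p180-like 188-metabolite panel measured on the
## seven-group, two-batch MEF design, with a planted severity gradient acting
## linearly on log-concentration. Ground truth is returned so downstream
## stages (filtering, normalization, latent models, signatures) can be scored.

.acylcarnitines <- c(
  "C0", "C2", "C3", "C3:1", "C3-OH", "C4", "C4:1", "C4-OH",
  "C5", "C5:1", "C5-OH", "C5-DC", "C5-M-DC", "C5:1-DC",
  "C6", "C6:1", "C7-DC", "C8", "C9", "C10", "C10:1", "C10:2",
  "C12", "C12:1", "C12-DC", "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH",
  "C16", "C16-OH", "C16:1", "C16:1-OH", "C16:2", "C16:2-OH",
  "C18", "C18:1", "C18:1-OH", "C18:2")

.aminoAcids <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro",
                 "Ser", "Thr", "Trp", "Tyr", "Val")

.biogenicAmines <- c("Ac-Orn", "ADMA", "alpha-AAA", "Carnosine", "Creatinine",
                     "DOPA", "Dopamine", "Histamine", "Kynurenine", "Met-SO",
                     "Nitro-Tyr", "t4-OH-Pro", "PEA", "Putrescine",
                     "Sarcosine", "SDMA", "Serotonin", "Spermidine",
                     "Spermine", "Taurine", "total DMA")

.lysoPC <- paste("lysoPC a", c("C14:0", "C16:0", "C16:1", "C17:0", "C18:0",
                               "C18:1", "C18:2", "C20:3", "C20:4", "C24:0",
                               "C26:0", "C26:1", "C28:0", "C28:1"))

.pcAA <- paste("PC aa", c(
  "C24:0", "C26:0", "C28:1", "C30:0", "C30:2", "C32:0", "C32:1", "C32:2",
  "C32:3", "C34:1", "C34:2", "C34:3", "C34:4", "C36:0", "C36:1", "C36:2",
  "C36:3", "C36:4", "C36:5", "C36:6", "C38:0", "C38:1", "C38:3", "C38:4",
  "C38:5", "C38:6", "C40:1", "C40:2", "C40:3", "C40:4", "C40:5", "C40:6",
  "C42:0", "C42:1", "C42:2", "C42:4", "C42:5", "C42:6"))

.pcAE <- paste("PC ae", c(
  "C30:0", "C30:1", "C30:2", "C32:1", "C32:2", "C34:0", "C34:1", "C34:2",
  "C34:3", "C36:0", "C36:1", "C36:2", "C36:3", "C36:4", "C36:5", "C38:0",
  "C38:1", "C38:2", "C38:3", "C38:4", "C38:5", "C38:6", "C40:1", "C40:2",
  "C40:3", "C40:4", "C40:5", "C40:6", "C42:0", "C42:1", "C42:2", "C42:3",
  "C42:4", "C42:5", "C44:3", "C44:4", "C44:5", "C44:6"))

.sm <- paste("SM", c("C16:0", "C16:1", "C18:0", "C18:1", "C20:2", "C22:3",
                     "C24:0", "C24:1", "C26:0", "C26:1"))

.smOH <- paste("SM (OH)", c("C14:1", "C16:1", "C22:1", "C22:2", "C24:1"))

#' Default 188-metabolite panel annotation
#'
#' The class partition of a p180-style targeted panel: 40 acylcarnitines,
#' 21 amino acids, 21 biogenic amines, 90 glycerophospholipids (14 lysoPC,
#' 38 diacyl PC, 38 acyl-alkyl PC), 15 sphingomyelins (10 SM, 5 hydroxylated
#' SM) and 1 sugar. Lipid ids follow the `"<subclass> C<carbons>:<bonds>"`
#' shorthand and every lipid id parses with [parseLipidName()].
#'
#' @return annotation data.frame with columns `metabolite_id`, `klass`,
#'   `subclass`, `total_carbons`, `total_double_bonds`, `hydroxylated`.
#' @export
defaultPanel <- function() {
  ids <- c(.acylcarnitines, .aminoAcids, .biogenicAmines,
           .lysoPC, .pcAA, .pcAE, .sm, .smOH, "H1")
  klass <- rep(c("acylcarnitine", "amino_acid", "biogenic_amine",
                 "glycerophospholipid", "sphingolipid", "sugar"),
               c(length(.acylcarnitines), length(.aminoAcids),
                 length(.biogenicAmines),
                 length(.lysoPC) + length(.pcAA) + length(.pcAE),
                 length(.sm) + length(.smOH), 1L))
  parsed <- lapply(ids, parseLipidName)
  df <- data.frame(
    metabolite_id = ids, klass = klass,
    subclass = vapply(parsed, function(p) if (is.null(p)) "none" else p$subclass, ""),
    total_carbons = vapply(parsed, function(p) if (is.null(p)) 0L else p$total_carbons, 0L),
    total_double_bonds = vapply(parsed, function(p) if (is.null(p)) 0L else p$total_double_bonds, 0L),
    hydroxylated = vapply(parsed, function(p) if (is.null(p)) FALSE else p$hydroxylated, TRUE),
    stringsAsFactors = FALSE)
  validatePanel(df)
  df
}

#' Default study design
#'
#' Seven groups in quintuplicate: wild type (`Opa1_WT`), knockout
#' (`Opa1_KO`) and five knockout lines re-expressing a human OPA1 allele
#' (`ISO1` wild-type cDNA, and the `I382M`, `D603H`, `G439V`, `R445H`
#' variants). The five wild-type samples are measured in both batches as
#' bridge samples (40 measurement rows in total); all other samples run in
#' one batch (replicates 1-3 in batch 1, 4-5 in batch 2). Severity ranks:
#' `Opa1_WT` = `ISO1` = 0 < `I382M` = 1 < `D603H` = 2 < `G439V` = 3 <
#' `R445H` = 4 < `Opa1_KO` = 5.
#'
#' @return design data.frame with one row per measurement: `measurement_id`,
#'   `sample_id`, `group`, `batch`, `replicate`, `is_bridge`, `transfected`,
#'   `severity_rank`.
#' @export
defaultDesign <- function() {
  ranks <- c(Opa1_WT = 0L, ISO1 = 0L, I382M = 1L, D603H = 2L,
             G439V = 3L, R445H = 4L, Opa1_KO = 5L)
  transfected <- c("ISO1", "I382M", "D603H", "G439V", "R445H")
  rows <- list()
  for (g in names(ranks)) {
    for (r in 1:5) {
      sid <- paste0(g, "_", r)
      if (g == "Opa1_WT") {
        for (b in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            measurement_id = paste0(sid, "_b", b), sample_id = sid,
            group = g, batch = b, replicate = r, is_bridge = TRUE,
            transfected = FALSE, severity_rank = ranks[[g]],
            stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          measurement_id = sid, sample_id = sid, group = g,
          batch = if (r <= 3) 1L else 2L, replicate = r, is_bridge = FALSE,
          transfected = g %in% transfected, severity_rank = ranks[[g]],
          stringsAsFactors = FALSE)
      }
    }
  }
  validateDesign(do.call(rbind, rows))
}

#' Effect specification for the synthetic generator
#'
#' Parameterises the planted structure: per-class (or per-subclass) severity
#' slopes on log-concentration per severity-rank unit, per-metabolite
#' overrides, a transfection offset shared by the transfected groups, a
#' per-batch per-metabolite effect, replicate noise, the fraction of
#' metabolites given a detection limit near their baseline and the fraction
#' of each sloped class that actually carries the slope.
#'
#' Defaults encode the direction of the published signature: amino acids,
#' biogenic amines and phosphatidylcholines fall with severity,
#' (hydroxylated) sphingomyelins and spermine rise, spermidine/putrescine and
#' the collagen marker t4-OH-Pro fall, glutamine rises.
#'
#' @param class_slopes named numeric, class or subclass -> slope (log-units
#'   per severity rank).
#' @param metabolite_overrides named numeric, metabolite_id -> slope
#'   (takes precedence over the class slope).
#' @param transfection_offset_sd sd of the per-metabolite log-offset shared
#'   by transfected groups (>= 0).
#' @param batch_sd sd of the per-batch, per-metabolite log-effect (>= 0).
#' @param noise_sd replicate log-noise sd (> 0).
#' @param lod_quantile fraction of metabolites whose LOD sits near their
#'   baseline (these fail the 20% rule), in [0, 1).
#' @param signal_fraction fraction of each sloped class carrying the slope,
#'   in (0, 1].
#' @return classed list of generator parameters.
#' @export
effectSpec <- function(class_slopes = c(amino_acid = -0.12,
                                        biogenic_amine = -0.08,
                                        PC_aa = -0.08, PC_ae = -0.08,
                                        lysoPC = -0.05,
                                        SM = 0.06, SM_OH = 0.10),
                       metabolite_overrides = c("Spermine" = 0.15,
                                                "Spermidine" = -0.12,
                                                "Putrescine" = -0.10,
                                                "Taurine" = -0.12,
                                                "Met-SO" = -0.12,
                                                "t4-OH-Pro" = -0.15,
                                                "Gln" = 0.08,
                                                "SM C18:0" = 0.10,
                                                "SM C16:0" = -0.04,
                                                "SM C16:1" = -0.04),
                       transfection_offset_sd = 0.10,
                       batch_sd = 0.10,
                       noise_sd = 0.10,
                       lod_quantile = 59 / 188,
                       signal_fraction = 0.8) {
  spec <- list(class_slopes = class_slopes,
               metabolite_overrides = metabolite_overrides,
               transfection_offset_sd = transfection_offset_sd,
               batch_sd = batch_sd, noise_sd = noise_sd,
               lod_quantile = lod_quantile, signal_fraction = signal_fraction)
  if (transfection_offset_sd < 0 || batch_sd < 0)
    metaboError("SpecError", "sd parameters must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    metaboError("SpecError", "noise_sd must be > 0")
  if (lod_quantile < 0 || lod_quantile >= 1)
    metaboError("SpecError", "lod_quantile must be in [0, 1)")
  if (signal_fraction <= 0 || signal_fraction > 1)
    metaboError("SpecError", "signal_fraction must be in (0, 1]")
  structure(spec, class = "EffectSpec")
}

#' Null effect specification
#'
#' Convenience spec with every slope, transfection and batch effect at zero:
#' group differences are pure replicate noise.
#'
#' @param noise_sd replicate log-noise sd.
#' @param lod_quantile see [effectSpec()].
#' @return an `EffectSpec`.
#' @export
nullEffectSpec <- function(noise_sd = 0.10, lod_quantile = 0) {
  effectSpec(class_slopes = numeric(), metabolite_overrides = numeric(),
             transfection_offset_sd = 0, batch_sd = 0, noise_sd = noise_sd,
             lod_quantile = lod_quantile)
}

#' Simulate a study-like concentration table with known ground truth
#'
#' Concentration of measurement i, metabolite j is
#' `exp(mu_j + slope_j * severity_rank_i + tau_j * transfected_i +
#' beta_(batch_i, j) + eps_ij)` with log-uniform baselines `mu_j` on
#' 0.01-100 uM fixed by `baselineSeed` (a panel-level constant independent of
#' `seed`), `tau_j ~ N(0, transfection_offset_sd)`,
#' `beta ~ N(0, batch_sd)` and `eps ~ N(0, noise_sd)`. Values below the LOD
#' are reported as measured; the returned LOD vector marks the limit and a
#' fraction `lod_quantile` of metabolites receive an LOD sitting above their
#' baseline so they fail the downstream 20% rule. Identical
#' (panel, design, effects, seed) give bit-identical output.
#'
#' @param panel annotation data.frame ([defaultPanel()]).
#' @param design design data.frame ([defaultDesign()]).
#' @param effects an [effectSpec()].
#' @param seed integer seed for every stochastic element.
#' @param baselineSeed panel-level seed fixing the baselines `mu_j`.
#' @return list with `mset` (a [MetaboSet] carrying data, design, panel and
#'   LOD) and `truth` (list: `per_metabolite_slope`, `signal_metabolites`,
#'   `planted_order`).
#' @export
simulateMetabolome <- function(panel = defaultPanel(), design = defaultDesign(),
                               effects = effectSpec(), seed = 1L,
                               baselineSeed = 188L) {
  if (!inherits(effects, "EffectSpec"))
    metaboError("SpecError", "effects must be built with effectSpec()")
  validatePanel(panel)
  validateDesign(design)
  J <- nrow(panel); n <- nrow(design)
  mids <- panel$metabolite_id

  mu <- withSeed(baselineSeed, stats::runif(J, log(0.01), log(100)))

  ## class slope lookup: subclass key wins over class key
  slopeFor <- function() {
    cs <- effects$class_slopes
    s <- ifelse(panel$subclass %in% names(cs), cs[panel$subclass], 0)
    s <- ifelse(panel$subclass == "none" & panel$klass %in% names(cs),
                cs[panel$klass], s)
    unname(s)
  }
  classSlope <- if (length(effects$class_slopes)) slopeFor() else numeric(J)

  withSeed(seed, {
    ## thin the class signal to signal_fraction, keeping overrides intact
    carry <- rep(TRUE, J)
    if (effects$signal_fraction < 1) {
      cand <- which(classSlope != 0)
      keepN <- round(length(cand) * effects$signal_fraction)
      keep <- if (length(cand)) sample(cand, keepN) else integer()
      carry <- seq_len(J) %in% keep | classSlope == 0
    }
    slope <- ifelse(carry, classSlope, 0)
    ov <- effects$metabolite_overrides
    if (length(ov)) {
      hit <- match(names(ov), mids)
      slope[hit[!is.na(hit)]] <- unname(ov[!is.na(hit)])
    }

    tau <- stats::rnorm(J, 0, effects$transfection_offset_sd)
    batches <- sort(unique(design$batch))
    beta <- matrix(stats::rnorm(length(batches) * J, 0, effects$batch_sd),
                   nrow = length(batches), dimnames = list(batches, mids))

    transfected <- if ("transfected" %in% colnames(design))
      design$transfected else rep(FALSE, n)
    rank <- design$severity_rank
    eps <- matrix(stats::rnorm(n * J, 0, effects$noise_sd), nrow = n)
    logc <- outer(rep(1, n), mu) +
      outer(rank, slope) +
      outer(as.numeric(transfected), tau) +
      beta[as.character(design$batch), , drop = FALSE] +
      eps
    values <- exp(logc)
    dimnames(values) <- list(design$measurement_id, mids)

    nFlag <- round(J * effects$lod_quantile)
    flagged <- if (nFlag > 0) sample(J, nFlag) else integer()
    lod <- exp(mu - 1.5)
    lod[flagged] <- exp(mu[flagged] + 0.5 * effects$noise_sd)
    names(lod) <- mids

    truth <- list(
      per_metabolite_slope = stats::setNames(slope, mids),
      signal_metabolites = mids[slope != 0],
      planted_order = unique(design$group[order(design$severity_rank)]))

    list(mset = MetaboSet(values, design, annotations = panel, lod = lod),
         truth = truth)
  })
}
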