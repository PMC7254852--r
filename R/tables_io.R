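## Readers/writers for the tabular formats the pipeline touches. Canonical
## in-memory orientation is samples-as-rows (the multivariate X convention);
## the MetaboSet container transposes internally.

.delimFor <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Validate a concentration matrix
#'
#' Enforces the panel-table invariants: numeric, finite (NA marks a missing
#' measurement, never 0), non-negative, with unique trimmed row (measurement)
#' and column (metabolite) identifiers.
#'
#' @param values a numeric matrix or data.frame.
#' @return the validated numeric matrix.
#' @export
validateConcentrations <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    metaboError("FormatError", "concentration table contains non-numeric cells")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    metaboError("FormatError", "concentration table needs row and column identifiers")
  if (nrow(values)) rownames(values) <- trimws(rownames(values))
  if (ncol(values)) colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    metaboError("DuplicateIdError", "duplicate sample identifiers: %s",
                paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    metaboError("DuplicateIdError", "duplicate metabolite identifiers: %s",
                paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(is.infinite(values)))
    metaboError("FormatError", "concentration table contains non-finite values")
  if (any(values < 0, na.rm = TRUE))
    metaboError("FormatError", "concentrations must be non-negative")
  values
}

#' Read a sample x metabolite concentration table
#'
#' @param path CSV/TSV file with one header row of identifiers; the first
#'   column holds row identifiers. Delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab) unless `delim` is given.
#' @param orientation `"samples_as_rows"` (default) or `"metabolites_as_rows"`;
#'   the result is always returned samples-as-rows.
#' @param missing token marking a missing measurement (default `"NA"`).
#' @param delim optional delimiter override.
#' @return numeric matrix, samples in rows, metabolites in columns.
#' @export
readMetaboTable <- function(path, orientation = c("samples_as_rows", "metabolites_as_rows"),
                            missing = "NA", delim = NULL) {
  orientation <- match.arg(orientation)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = .delimFor(path, delim),
                      na.strings = missing, check.names = FALSE,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) metaboError("FormatError", "cannot parse %s: %s",
                                    path, conditionMessage(e)))
  if (ncol(df) < 1L) metaboError("FormatError", "no identifier column in %s", path)
  ids <- df[[1L]]
  cn <- colnames(df)[-1L]           # before subsetting: [.data.frame dedupes
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  colnames(m) <- cn
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- !is.na(m) & is.na(num)
  if (any(bad))
    metaboError("FormatError", "non-numeric cell(s), e.g. '%s'", m[which(bad)[1]])
  if (orientation == "metabolites_as_rows") num <- t(num)
  validateConcentrations(num)
}

#' Write a concentration table
#'
#' Writes the canonical samples-as-rows CSV (12 significant digits, so that
#' read/write round-trips are identity at that precision); missing values are
#' written as the configured token.
#'
#' @param values concentration matrix (samples as rows) or a [MetaboSet].
#' @param path output file; delimiter inferred from extension.
#' @param missing missing-value token (default `"NA"`).
#' @param idColumn header of the identifier column.
#' @return invisibly, the path.
#' @export
writeMetaboTable <- function(values, path, missing = "NA", idColumn = "sample") {
  if (is(values, "MetaboSet")) values <- concentrations(values)
  values <- validateConcentrations(values)
  sep <- .delimFor(path)
  txt <- format(values, digits = 12, trim = TRUE, scientific = NA)
  txt[is.na(values)] <- missing
  out <- cbind(matrix(if (nrow(values)) rownames(values) else character(),
                      ncol = 1), txt)
  colnames(out) <- c(idColumn, colnames(values))
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) metaboError("IOError", "cannot write %s", path)
  invisible(path)
}

#' Read a study-design table
#'
#' Expected columns: `sample_id`, `group`, `batch`, `replicate`, `is_bridge`
#' and optionally `measurement_id` (defaults to `sample_id`, with `_b<batch>`
#' appended for bridge re-runs) and `severity_rank`.
#'
#' @param path CSV/TSV file.
#' @param groups optional vector of admissible group labels; anything else is
#'   rejected.
#' @param delim optional delimiter override.
#' @return data.frame, one row per measurement.
#' @export
readDesign <- function(path, groups = NULL, delim = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path, delim),
                          check.names = FALSE, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch", "replicate", "is_bridge")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    metaboError("FormatError", "design lacks column(s): %s", paste(miss, collapse = ", "))
  df$batch <- as.integer(df$batch)
  df$replicate <- as.integer(df$replicate)
  df$is_bridge <- as.logical(df$is_bridge)
  if (any(is.na(df$batch)) || any(df$batch < 1L))
    metaboError("FormatError", "batch must be an integer >= 1")
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    metaboError("FormatError", "replicate must be an integer >= 1")
  if (!is.null(groups)) {
    unknown <- setdiff(unique(df$group), groups)
    if (length(unknown))
      metaboError("FormatError", "unknown group label(s): %s",
                  paste(unknown, collapse = ", "))
  }
  if (!"measurement_id" %in% colnames(df)) {
    df$measurement_id <- ifelse(df$is_bridge,
                                paste0(df$sample_id, "_b", df$batch),
                                df$sample_id)
  }
  if (anyDuplicated(df[, c("sample_id", "batch")]))
    metaboError("DuplicateIdError", "a sample may appear at most once per batch")
  if (anyDuplicated(df$measurement_id))
    metaboError("DuplicateIdError", "duplicate measurement ids")
  validateDesign(df)
  df
}

#' Validate a study design
#'
#' Bridge samples must appear (under one `sample_id`) in at least two distinct
#' batches whenever more than one batch is present.
#'
#' @param design design data.frame.
#' @return invisibly, the design.
#' @export
validateDesign <- function(design) {
  br <- design[design$is_bridge, , drop = FALSE]
  if (nrow(br) && length(unique(design$batch)) > 1L) {
    nb <- tapply(br$batch, br$sample_id, function(b) length(unique(b)))
    if (any(nb < 2L))
      metaboError("FormatError",
                  "bridge sample(s) measured in fewer than 2 batches: %s",
                  paste(names(nb)[nb < 2L], collapse = ", "))
  }
  invisible(design)
}

## Lipid shorthand grammar: "<subclass token> C<carbons>:<double bonds>".
.lipidTokens <- c("PC aa" = "PC_aa", "PC ae" = "PC_ae", "lysoPC a" = "lysoPC",
                  "SM (OH)" = "SM_OH", "SM" = "SM")

#' Parse a lipid shorthand identifier
#'
#' Understands the panel notation `"<subclass> C<carbons>:<double bonds>"`
#' with subclass tokens `PC aa`, `PC ae`, `lysoPC a`, `SM`, `SM (OH)`; the
#' number after `C` is the summed length of the acyl/acyl-alkyl chains and the
#' number after `:` the summed double bonds.
#'
#' @param id lipid identifier, e.g. `"PC aa C36:4"` or `"SM (OH) C22:2"`.
#' @return list with `subclass`, `total_carbons`, `total_double_bonds`,
#'   `hydroxylated`, or `NULL` when the id is not lipid shorthand.
#' @export
parseLipidName <- function(id) {
  id <- trimws(id)
  for (tok in names(.lipidTokens)) {
    pat <- paste0("^", gsub("([()])", "\\\\\\1", tok), " C([0-9]+):([0-9]+)$")
    m <- regmatches(id, regexec(pat, id))[[1]]
    if (length(m) == 3L) {
      sub <- .lipidTokens[[tok]]
      return(list(subclass = sub,
                  total_carbons = as.integer(m[2]),
                  total_double_bonds = as.integer(m[3]),
                  hydroxylated = identical(sub, "SM_OH")))
    }
  }
  NULL
}

#' Read a panel-annotation table
#'
#' Expected columns: `metabolite_id`, `klass`; lipid-structure columns
#' (`subclass`, `total_carbons`, `total_double_bonds`, `hydroxylated`) are
#' filled from the lipid shorthand in `metabolite_id` when absent.
#'
#' @param path CSV/TSV file.
#' @param delim optional delimiter override.
#' @return annotation data.frame.
#' @export
readAnnotations <- function(path, delim = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path, delim),
                          check.names = FALSE, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("metabolite_id", "klass")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    metaboError("FormatError", "annotation lacks column(s): %s",
                paste(miss, collapse = ", "))
  df$metabolite_id <- trimws(df$metabolite_id)
  if (anyDuplicated(df$metabolite_id))
    metaboError("DuplicateIdError", "duplicate metabolite ids in annotation")
  known <- c("acylcarnitine", "amino_acid", "biogenic_amine",
             "glycerophospholipid", "sphingolipid", "sugar")
  unknown <- setdiff(unique(df$klass), known)
  if (length(unknown))
    metaboError("FormatError", "unknown metabolite class(es): %s",
                paste(unknown, collapse = ", "))
  if (!"subclass" %in% colnames(df)) {
    parsed <- lapply(df$metabolite_id, parseLipidName)
    df$subclass <- vapply(parsed, function(p) if (is.null(p)) "none" else p$subclass, "")
    df$total_carbons <- vapply(parsed, function(p) if (is.null(p)) 0L else p$total_carbons, 0L)
    df$total_double_bonds <- vapply(parsed, function(p) if (is.null(p)) 0L else p$total_double_bonds, 0L)
    df$hydroxylated <- vapply(parsed, function(p) if (is.null(p)) FALSE else p$hydroxylated, TRUE)
  }
  validatePanel(df)
  df
}

#' Validate a panel annotation
#'
#' @param panel annotation data.frame.
#' @return invisibly, the panel.
#' @export
validatePanel <- function(panel) {
  bad <- (panel$subclass %in% c("PC_aa", "PC_ae", "lysoPC") &
            panel$klass != "glycerophospholipid") |
         (panel$subclass %in% c("SM", "SM_OH") & panel$klass != "sphingolipid")
  if (any(bad))
    metaboError("FormatError", "subclass/class mismatch for: %s",
                paste(head(panel$metabolite_id[bad], 5), collapse = ", "))
  if (any(panel$subclass != "none" & panel$total_carbons <= 0))
    metaboError("FormatError", "lipid ids must carry a positive carbon count")
  invisible(panel)
}

#' Read a limits-of-detection table
#'
#' @param path CSV/TSV with columns `metabolite_id`, `lod` (same unit as the
#'   concentration table; all values strictly positive).
#' @param delim optional delimiter override.
#' @return named numeric vector of LODs.
#' @export
readLOD <- function(path, delim = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path, delim),
                          check.names = FALSE, strip.white = TRUE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("metabolite_id", "lod"), colnames(df))
  if (length(miss))
    metaboError("FormatError", "LOD table lacks column(s): %s",
                paste(miss, collapse = ", "))
  lod <- as.numeric(df$lod)
  if (any(!is.finite(lod)) || any(lod <= 0))
    metaboError("FormatError", "every LOD must be a positive number")
  stats::setNames(lod, trimws(df$metabolite_id))
}

#' Export a domain object as JSON
#'
#' Serialises matrices, data.frames, fitted models and reports into plain
#' JSON for downstream reporting.
#'
#' @param x a matrix, data.frame, [PCAModel], [OPLSModel] or
#'   [ValidationReport].
#' @param path optional file; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
exportJSON <- function(x, path = NULL) {
  obj <- if (is(x, "PCAModel")) {
    list(type = "PCAModel", scores = x@scores, loadings = x@loadings, r2x = x@r2x)
  } else if (is(x, "OPLSModel")) {
    list(type = "OPLSModel", w_pred = x@wPred, t_pred = x@tPred, p_pred = x@pPred,
         W_orth = x@WOrth, T_orth = x@TOrth, P_orth = x@POrth,
         b = x@b, y_center = x@yCenter, r2y = x@r2y,
         r2x_pred = x@r2xPred, r2x_orth = x@r2xOrth,
         y_kind = x@yKind, class_map = as.list(x@classMap))
  } else if (is(x, "ValidationReport")) {
    list(type = "ValidationReport", q2y_cum = x@q2yCum, press = x@press,
         ssy = x@ssy, n_folds = x@nFolds, n_orth_selected = x@nOrthSelected,
         perm_q2 = x@permQ2, q2y_cum_perm = x@q2yCumPerm,
         cv_anova_F = x@cvAnovaF, cv_anova_p = x@cvAnovaP,
         verdict = verdict(x))
  } else x
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
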