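# Dataset curation: parsing raw viscosity tables and the three-stage
# filtration (element/fragment screen, box-and-whisker range screen,
# positive temperature-deviation screen) followed by the log10 transform.

#' Elements admitted by the organic-structure filter
#' @export
VISC_ALLOWED_ELEMENTS <- c("H", "C", "N", "O", "F", "Si", "P", "S",
                           "Cl", "Br", "I")

.as_records <- function(df) {
  need <- c("smiles", "temperature_K", "viscosity_cP", "source")
  for (col in setdiff(need, names(df))) df[[col]] <- NA
  df <- df[, need, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read raw viscosity records from a delimited text file
#'
#' One row per (structure, temperature, viscosity) observation. Column names
#' are configurable through `column_map`; temperatures may be supplied in
#' Celsius and are converted to Kelvin at this boundary, so everything
#' downstream works in K and cP.
#'
#' @param path path to a CSV (or TSV) file.
#' @param column_map named list mapping the roles `structure`, `temperature`,
#'   `viscosity` and optionally `source` to column names in the file, plus an
#'   optional `temperature_unit` of `"K"` (default) or `"C"`.
#' @param sep field separator; defaults to `","`, or `"\t"` for `.tsv` files.
#' @return list with `records` (data.frame: smiles, temperature_K,
#'   viscosity_cP, source) and `parse_report` (data.frame of skipped rows with
#'   line numbers and reasons).
#' @export
read_records <- function(path, column_map = list(), sep = NULL) {
  if (!file.exists(path)) stop_ctx("input file not found: %s", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  cm <- utils::modifyList(
    list(structure = "smiles", temperature = "temperature_K",
         viscosity = "viscosity_cP", source = "source",
         temperature_unit = "K"),
    column_map
  )
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  for (role in c("structure", "temperature", "viscosity")) {
    if (!cm[[role]] %in% names(raw)) {
      stop_ctx("column '%s' (role: %s) not found in %s", cm[[role]], role, path)
    }
  }
  smi <- as.character(raw[[cm$structure]])
  temp <- suppressWarnings(as.numeric(raw[[cm$temperature]]))
  visc <- suppressWarnings(as.numeric(raw[[cm$viscosity]]))
  src <- if (cm$source %in% names(raw)) as.character(raw[[cm$source]]) else ""
  if (identical(cm$temperature_unit, "C")) temp <- temp + 273.15

  bad <- is.na(temp) | is.na(visc) | !nzchar(trimws(smi)) |
    (!is.na(temp) & temp <= 0) | (!is.na(visc) & visc <= 0)
  reason <- rep(NA_character_, length(bad))
  reason[is.na(temp)] <- "unparseable temperature"
  reason[is.na(visc)] <- "unparseable viscosity"
  reason[!is.na(visc) & visc <= 0] <- "non-positive viscosity"
  reason[!is.na(temp) & temp <= 0] <- "non-positive temperature"
  reason[!nzchar(trimws(smi))] <- "empty structure"

  records <- .as_records(data.frame(
    smiles = smi[!bad], temperature_K = temp[!bad],
    viscosity_cP = visc[!bad], source = src[!bad],
    stringsAsFactors = FALSE
  ))
  parse_report <- data.frame(line = which(bad) + 1L, reason = reason[bad],
                             stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop_ctx("no parseable rows in %s", path)
  list(records = records, parse_report = parse_report)
}

#' Keep single-fragment organic structures over an allowed element set
#'
#' A record survives if its SMILES parses, describes a single connected
#' fragment, contains at least one carbon atom ("organic"), and uses only
#' allowed elements.
#'
#' @param records data.frame of raw records (see [read_records()]).
#' @param allowed_elements character vector of element symbols.
#' @param cache optional molecule cache from `molecule_cache()` for reuse.
#' @return list with `records` (kept rows) and `removed` (dropped rows with a
#'   `reason` column).
#' @export
filter_structures <- function(records,
                              allowed_elements = VISC_ALLOWED_ELEMENTS,
                              cache = NULL) {
  records <- .as_records(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = cbind(records, reason = character(0))))
  }
  if (is.null(cache)) cache <- molecule_cache()
  mols <- cache(records$smiles)
  reason <- vapply(mols, function(m) {
    if (!isTRUE(m$ok)) return("parse_failure")
    if (m$n_fragments > 1) return("multiple_fragments")
    els <- names(m$elements)
    if (!("C" %in% els)) return("no_carbon")
    if (length(setdiff(els, allowed_elements)) > 0) {
      return(paste0("disallowed_elements:",
                    paste(setdiff(els, allowed_elements), collapse = ",")))
    }
    NA_character_
  }, character(1))
  keep <- is.na(reason)
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Remove box-and-whisker range outliers in viscosity and temperature
#'
#' Computes Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]` for viscosity and for
#' temperature over the *input* set (single pass; fences are not recomputed
#' after removals) and drops any record falling outside either fence.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param records data.frame of records.
#' @param k fence multiplier (1.5 by default).
#' @return list with `records` and `removed` (with a `reason` column).
#' @export
filter_range_outliers <- function(records, k = 1.5) {
  records <- .as_records(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = cbind(records, reason = character(0))))
  }
  fence <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    c(q[1] - k * iqr, q[2] + k * iqr)
  }
  fv <- fence(records$viscosity_cP)
  ft <- fence(records$temperature_K)
  out_v <- records$viscosity_cP < fv[1] | records$viscosity_cP > fv[2]
  out_t <- records$temperature_K < ft[1] | records$temperature_K > ft[2]
  keep <- !(out_v | out_t)
  removed <- records[!keep, , drop = FALSE]
  removed$reason <- ifelse(out_v[!keep] & out_t[!keep], "viscosity+temperature",
                           ifelse(out_v[!keep], "viscosity_range",
                                  "temperature_range"))
  rownames(removed) <- NULL
  list(records = records[keep, , drop = FALSE], removed = removed)
}

#' Remove points with a positive viscosity deviation along temperature
#'
#' Bulk-liquid viscosity decreases with temperature, so within each compound
#' (records sorted by ascending temperature) a retained point whose viscosity
#' exceeds the previously retained point's viscosity by strictly more than
#' `threshold` cP is an outlier; the higher-temperature point of the violating
#' pair is dropped and scanning continues against the last retained point
#' until no violation remains.
#'
#' @param records data.frame of records.
#' @param threshold allowed positive deviation in cP (default 0.02).
#' @param compound_ids optional compound key per record; computed from
#'   canonical SMILES when missing.
#' @param cache optional molecule cache.
#' @return list with `records` and `removed` (with a `reason` column).
#' @export
filter_positive_temperature_deviation <- function(records, threshold = 0.02,
                                                  compound_ids = NULL,
                                                  cache = NULL) {
  records <- .as_records(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = cbind(records, reason = character(0))))
  }
  if (is.null(compound_ids)) {
    if (is.null(cache)) cache <- molecule_cache()
    mols <- cache(records$smiles)
    compound_ids <- vapply(mols, function(m) m$canonical %||% NA_character_,
                           character(1))
    compound_ids[is.na(compound_ids)] <- records$smiles[is.na(compound_ids)]
  }
  drop <- logical(nrow(records))
  for (cid in unique(compound_ids)) {
    idx <- which(compound_ids == cid)
    ord <- idx[order(records$temperature_K[idx], records$viscosity_cP[idx])]
    last_kept <- ord[1]
    for (i in ord[-1]) {
      dev <- records$viscosity_cP[i] - records$viscosity_cP[last_kept]
      # strict boundary with a guard against binary-float representation
      if (dev > threshold + 1e-12) drop[i] <- TRUE else last_kept <- i
    }
  }
  removed <- records[drop, , drop = FALSE]
  removed$reason <- rep("positive_temperature_deviation", sum(drop))
  rownames(removed) <- NULL
  list(records = records[!drop, , drop = FALSE], removed = removed)
}

#' Log-transform viscosities into a curated dataset
#'
#' Attaches `log10_viscosity = log10(viscosity_cP)` and the canonical-SMILES
#' compound key to each record. Original cP values are retained.
#'
#' @param records data.frame of records (all viscosities must be positive).
#' @param cache optional molecule cache.
#' @return a `curated_dataset`: data.frame with columns smiles,
#'   temperature_K, viscosity_cP, source, log10_viscosity, compound_id.
#' @export
log_transform_viscosity <- function(records, cache = NULL) {
  records <- .as_records(records)
  if (any(records$viscosity_cP <= 0)) {
    stop_ctx("non-positive viscosity cannot be log-transformed")
  }
  if (is.null(cache)) cache <- molecule_cache()
  cid <- records$smiles
  if (nrow(records) > 0) {
    mols <- cache(records$smiles)
    canon <- vapply(mols, function(m) m$canonical %||% NA_character_,
                    character(1))
    cid <- ifelse(is.na(canon), records$smiles, canon)
  }
  records$log10_viscosity <- log10(records$viscosity_cP)
  records$compound_id <- as.character(cid)
  class(records) <- c("curated_dataset", "data.frame")
  records
}

#' Curate a raw viscosity table
#'
#' Applies the three filters in order — structure screen, box-and-whisker
#' range screen, positive temperature-deviation screen — then log-transforms,
#' and returns the curated dataset together with an auditable removal report.
#'
#' @param records data.frame of raw records.
#' @param allowed_elements element symbols admitted by the structure filter.
#' @param range_k fence multiplier for the range filter.
#' @param deviation_threshold_cP threshold for the deviation filter.
#' @return list with `dataset` (a `curated_dataset`), `report` (a
#'   `curation_report` with reconciling counts) and `removed` (data.frame of
#'   all removed rows with filter stage and reason).
#' @export
curate <- function(records, allowed_elements = VISC_ALLOWED_ELEMENTS,
                   range_k = 1.5, deviation_threshold_cP = 0.02) {
  records <- .as_records(records)
  cache <- molecule_cache()
  n_in <- nrow(records)

  s1 <- filter_structures(records, allowed_elements, cache = cache)
  s2 <- filter_range_outliers(s1$records, k = range_k)
  s3 <- filter_positive_temperature_deviation(
    s2$records, threshold = deviation_threshold_cP, cache = cache)
  dataset <- log_transform_viscosity(s3$records, cache = cache)

  stage <- function(df, st) {
    if (nrow(df) == 0) return(cbind(df, stage = character(0)))
    df$stage <- st
    df
  }
  removed <- rbind(stage(s1$removed, "structure"),
                   stage(s2$removed, "range"),
                   stage(s3$removed, "deviation"))
  report <- structure(list(
    counts_in = n_in,
    removed_by_structure_filter = nrow(s1$removed),
    removed_by_range_filter = nrow(s2$removed),
    removed_by_deviation_filter = nrow(s3$removed),
    counts_out = nrow(dataset)
  ), class = "curation_report")
  stopifnot(report$counts_in - report$removed_by_structure_filter -
              report$removed_by_range_filter -
              report$removed_by_deviation_filter == report$counts_out)
  list(dataset = dataset, report = report, removed = removed)
}

#' @method print curation_report
#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  records in:              %d\n", x$counts_in))
  cat(sprintf("  removed (structure):     %d\n", x$removed_by_structure_filter))
  cat(sprintf("  removed (range):         %d\n", x$removed_by_range_filter))
  cat(sprintf("  removed (deviation):     %d\n", x$removed_by_deviation_filter))
  cat(sprintf("  records out:             %d\n", x$counts_out))
  invisible(x)
}

#' Write a curated dataset and its report to disk
#'
#' @param curated result of [curate()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "curated_dataset.csv")
  utils::write.csv(as.data.frame(curated$dataset), csv, row.names = FALSE)
  js <- file.path(dir, "curation_report.json")
  jsonlite::write_json(unclass(curated$report), js, auto_unbox = TRUE)
  invisible(c(csv, js))
}
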