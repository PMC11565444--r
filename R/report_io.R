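# The standardised output container and its readers/writers: RCPath-style
# proforma text and a lossless machine-readable JSON document.

#' Structured report container
#'
#' Holds one report's per-field results in the fixed RCPath proforma
#' order (specimen type first, resection last) together with the schema
#' version and a digest of the pipeline configuration. `generated_at` is
#' optional and unset by default so that repeated runs with the same seed
#' produce byte-identical output.
#'
#' @param report_id Report identifier.
#' @param results Named list of `field_result` objects.
#' @param schema_version Schema document version string.
#' @param config Pipeline configuration list recorded for provenance.
#' @param generated_at Optional timestamp string.
#' @return A `structured_report`.
#' @export
structured_report <- function(report_id, results, schema_version = "1.0",
                              config = list(), generated_at = NA_character_) {
  order <- intersect(list_fields(), names(results))
  extra <- setdiff(names(results), order)
  results <- results[c(order, extra)]
  structure(list(report_id = report_id, results = results,
                 schema_version = schema_version,
                 generated_at = generated_at,
                 config = config,
                 config_digest = config_digest(config)),
            class = "structured_report")
}

#' Digest of a pipeline configuration
#'
#' A short deterministic hash of the resolved configuration, recorded in
#' outputs and run manifests so that results can be traced to settings.
#'
#' @param config A list of configuration values.
#' @return Hex string.
#' @export
config_digest <- function(config) {
  json <- as.character(jsonlite::toJSON(config[order(names(config))],
                                        auto_unbox = TRUE, digits = NA))
  sprintf("%08x", .hash31(json))
}

#' Final values of a structured report
#'
#' @param report A `structured_report`.
#' @return Named character vector, field -> final canonical value.
#' @export
report_values <- function(report) {
  stopifnot(inherits(report, "structured_report"))
  vapply(report$results, `[[`, character(1), "final_value")
}

#' Flat table view of one or more structured reports
#'
#' @param report A `structured_report`.
#' @return Data frame with columns `report_id`, `field`, `value`,
#'   `confidence` (raw, 0-100) and `calibrated` (probability or `NA`).
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "structured_report"))
  if (!length(report$results)) {
    return(data.frame(report_id = character(0), field = character(0),
                      value = character(0), confidence = numeric(0),
                      calibrated = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    report_id = report$report_id,
    field = vapply(report$results, `[[`, character(1), "field"),
    value = vapply(report$results, `[[`, character(1), "final_value"),
    confidence = vapply(report$results, `[[`, numeric(1), "raw_confidence"),
    calibrated = vapply(report$results, `[[`, numeric(1), "calibrated_confidence"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.structured_report <- function(x, ...) {
  cat(render_proforma_text(x), "\n")
  invisible(x)
}

#' Render the human-readable proforma
#'
#' Fixed-order labelled lines, one field per line, value plus (optionally)
#' the confidence as an integer percent -- the calibrated probability when
#' present, the raw score otherwise. NA sentinels are rendered verbatim
#' (pTX etc.). Byte-deterministic for a given report.
#'
#' @param report A `structured_report`.
#' @param show_confidence Include the confidence annotation.
#' @param schema Optional schema list.
#' @return A single string.
#' @export
render_proforma_text <- function(report, show_confidence = TRUE, schema = NULL) {
  stopifnot(inherits(report, "structured_report"))
  header <- sprintf("Standardised colorectal cancer report: %s", report$report_id)
  lines <- vapply(report$results, function(fr) {
    fs <- get_field_schema(fr$field, schema)
    value <- fr$final_value
    if (fs$kind == "numeric" && grepl("^[0-9]+$", value) &&
        identical(fs$unit, "mm")) {
      value <- paste0(value, " mm")
    }
    if (show_confidence) {
      conf <- if (!is.na(fr$calibrated_confidence)) {
        round(100 * fr$calibrated_confidence)
      } else {
        round(fr$raw_confidence)
      }
      sprintf("%s: %s (confidence %d)", fs$label, value, conf)
    } else {
      sprintf("%s: %s", fs$label, value)
    }
  }, character(1))
  paste(c(header, lines), collapse = "\n")
}

.drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]

.field_result_to_list <- function(fr) {
  ex <- fr$extraction; va <- fr$validation
  .drop_nulls(list(
    field = fr$field,
    final_value = fr$final_value,
    raw_confidence = fr$raw_confidence,
    calibrated_confidence = if (is.na(fr$calibrated_confidence)) NULL
                            else fr$calibrated_confidence,
    terms = unclass(fr$terms),
    extraction = list(value = ex$value, e_confidence = ex$e_confidence,
                      vote_counts = as.list(ex$vote_counts),
                      n_requested = ex$n_requested, n_valid = ex$n_valid,
                      tie = ex$tie),
    validation = list(v_correct = va$v_correct, v_confidence = va$v_confidence,
                      v_correction = va$v_correction,
                      v_pct_correct = va$v_pct_correct,
                      corrected_value = va$corrected_value,
                      modal_correctness = va$modal_correctness,
                      modal_confidence = va$modal_confidence,
                      n_requested = va$n_requested, n_valid = va$n_valid,
                      ties = as.list(va$ties))))
}

.field_result_from_list <- function(x, schema = NULL) {
  fs <- get_field_schema(x$field, schema)
  if (!is_canonical_value(x$field, x$final_value, schema)) {
    stop("value '", x$final_value, "' is not canonical for field '",
         x$field, "'", call. = FALSE)
  }
  counts <- vapply(x$extraction$vote_counts, function(v) as.integer(v), integer(1))
  extraction <- structure(list(
    field = x$field, value = x$extraction$value,
    e_confidence = as.numeric(x$extraction$e_confidence),
    vote_counts = counts,
    n_requested = as.integer(x$extraction$n_requested),
    n_valid = as.integer(x$extraction$n_valid),
    tie = isTRUE(x$extraction$tie)), class = "aggregated_extraction")
  validation <- structure(list(
    v_correct = as.numeric(x$validation$v_correct),
    v_confidence = as.numeric(x$validation$v_confidence),
    v_correction = as.numeric(x$validation$v_correction),
    v_pct_correct = as.numeric(x$validation$v_pct_correct),
    corrected_value = x$validation$corrected_value,
    modal_correctness = x$validation$modal_correctness,
    modal_confidence = as.integer(x$validation$modal_confidence),
    n_requested = as.integer(x$validation$n_requested),
    n_valid = as.integer(x$validation$n_valid),
    ties = as.character(unlist(x$validation$ties))), class = "validator_aggregate")
  structure(list(
    field = x$field,
    final_value = x$final_value,
    raw_confidence = as.numeric(x$raw_confidence),
    calibrated_confidence = if (is.null(x$calibrated_confidence)) NA_real_
                            else as.numeric(x$calibrated_confidence),
    terms = structure(lapply(x$terms, as.numeric), class = "confidence_terms"),
    extraction = extraction, validation = validation), class = "field_result")
}

#' Write / read a structured report as JSON
#'
#' The JSON document is lossless: vote counts, all five confidence terms,
#' tie flags and calibration state round-trip exactly, with stable key
#' order. Reading validates the schema version and that every value is
#' canonical; an absent calibrated confidence reads back as absent, not 0.
#'
#' @param report A `structured_report`.
#' @param path File path; `write_report_json` with `path = NULL` returns
#'   the JSON string instead.
#' @return `read_report_json` returns the `structured_report`.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "structured_report"))
  payload <- .drop_nulls(list(
    format = "pathstruct-report",
    schema_version = report$schema_version,
    report_id = report$report_id,
    generated_at = if (is.na(report$generated_at)) NULL else report$generated_at,
    config = report$config,
    config_digest = report$config_digest,
    results = lapply(unname(report$results), .field_result_to_list)))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @param doc JSON string or path to a JSON file.
#' @param schema Optional schema list used for validation.
#' @export
read_report_json <- function(doc, schema = NULL) {
  x <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (!identical(x$format, "pathstruct-report")) {
    stop("not a pathstruct report document", call. = FALSE)
  }
  schema_full <- schema %||% .default_schema()
  current <- attr(schema_full, "schema_version")
  if (!identical(x$schema_version, current)) {
    stop("schema version mismatch: document has '", x$schema_version,
         "', installed schema is '", current, "'", call. = FALSE)
  }
  results <- lapply(x$results, .field_result_from_list, schema = schema)
  names(results) <- vapply(results, `[[`, character(1), "field")
  rep <- structured_report(
    report_id = x$report_id, results = results,
    schema_version = x$schema_version,
    config = lapply(x$config, function(v) v),
    generated_at = if (is.null(x$generated_at)) NA_character_ else x$generated_at)
  rep
}

#' Read free-text reports
#'
#' Accepts a directory of plain-text files (one report each; the file
#' name without extension is the report id), a single text file, or a
#' two-column delimited table (`report_id`, `text`; tab- or
#' comma-separated by extension). Text is passed through unmodified --
#' no cleaning that could alter extraction -- and read as UTF-8.
#'
#' @param path Directory, text file or table path.
#' @return Named character vector, report id -> report text.
#' @export
read_report_text <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  read_one <- function(f) {
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) {
      warning("report file '", f, "' is empty", call. = FALSE)
    }
    txt
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    out <- vapply(files, read_one, character(1))
    names(out) <- sub("\\.txt$", "", basename(files))
    return(out)
  }
  if (grepl("\\.(tsv|csv)$", path)) {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, quote = "\"",
                             encoding = "UTF-8", comment.char = "")
    stopifnot(ncol(tab) >= 2L)
    return(stats::setNames(as.character(tab[[2]]), as.character(tab[[1]])))
  }
  out <- read_one(path)
  stats::setNames(out, sub("\\.[^.]*$", "", basename(path)))
}

#' Export a synthetic cohort to disk
#'
#' Writes exactly the formats the pipeline and evaluation consume: one
#' plain-text report per case under `reports/`, a truth table
#' (`truth.tsv`) and a survival table (`survival.tsv`).
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "reports"), recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) {
    writeLines(cs$report_text, file.path(dir, "reports",
                                         paste0(cs$report_id, ".txt")),
               useBytes = TRUE)
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = TRUE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
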