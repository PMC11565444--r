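# Field vocabulary for the RCPath colorectal dataset.
#
# The controlled vocabulary ships as a versioned JSON document under
# inst/extdata/schema/ so that schemas for other tumour streams can be
# dropped in without code changes. Canonical casing follows the RCPath
# conventions: title-case category labels ("High", "Ascending colon") and
# lower-case "p"-prefixed TNM codes ("pT4a"). Numeric fields are stored as
# integers (millimetres for diameter, counts for nodes).

.pathstruct_env <- new.env(parent = emptyenv())

# surface forms that mean "not available" for any field
.global_na_forms <- c(
  "na", "n/a", "not available", "not reported", "not stated", "unknown",
  "missing", "cannot be assessed", "not assessable", "none available"
)

#' Load a field-schema document
#'
#' Reads a JSON schema document (by default the RCPath colorectal schema
#' shipped with the package), expands systematic TNM aliases (stripped "p"
#' prefix) and builds case-insensitive lookup tables.
#'
#' @param path Path to a schema JSON document. `NULL` (default) loads the
#'   built-in RCPath colorectal schema.
#' @return A named list of `field_schema` objects, in proforma order, with
#'   attributes `schema_name` and `schema_version`.
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "schema", "colorectal_rcpath.json",
                        package = "pathstruct", mustWork = TRUE)
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fields <- lapply(doc$fields, function(row) {
    fs <- list(
      name          = row$name,
      label         = row$label,
      query_key     = row$query_key,
      kind          = row$kind,
      values        = if (identical(row$kind, "categorical")) unlist(row$values) else character(0),
      numeric_range = if (identical(row$kind, "numeric")) unlist(row$numeric_range) else NULL,
      unit          = if (identical(row$kind, "numeric")) row$unit else NULL,
      na_sentinel   = row$na_sentinel,
      aliases       = if (length(row$aliases)) unlist(row$aliases) else character(0),
      broad_map     = if (length(row$broad_map)) unlist(row$broad_map) else character(0)
    )
    fs <- .expand_systematic_aliases(fs)
    fs$lookup <- .build_lookup(fs)
    class(fs) <- "field_schema"
    fs
  })
  names(fields) <- vapply(fields, `[[`, character(1), "name")
  attr(fields, "schema_name") <- doc$schema_name
  attr(fields, "schema_version") <- doc$schema_version
  fields
}

# TNM codes are routinely written without the "p" prefix ("T4A", "N1a");
# generate those aliases rather than enumerating them in the document.
.expand_systematic_aliases <- function(fs) {
  if (fs$kind != "categorical") return(fs)
  extra <- character(0)
  for (v in fs$values[grepl("^p[TNM]", fs$values)]) {
    extra[tolower(sub("^p", "", v))] <- v
  }
  fs$aliases <- c(fs$aliases, extra[!names(extra) %in% names(fs$aliases)])
  fs
}

.build_lookup <- function(fs) {
  lk <- character(0)
  if (fs$kind == "categorical") {
    lk[tolower(fs$values)] <- fs$values
  } else {
    lk[tolower(fs$na_sentinel)] <- fs$na_sentinel
  }
  al <- fs$aliases
  if (length(al)) {
    keep <- !(tolower(names(al)) %in% names(lk))
    lk[tolower(names(al))[keep]] <- unname(al[keep])
  }
  lk
}

.default_schema <- function() {
  if (is.null(.pathstruct_env$schema)) {
    .pathstruct_env$schema <- load_schema()
  }
  .pathstruct_env$schema
}

#' Supported field names in proforma order
#'
#' @param schema A schema list from [load_schema()]; default built-in.
#' @return Character vector of field identifiers, in the fixed RCPath
#'   proforma order (specimen type first, resection last).
#' @export
list_fields <- function(schema = NULL) {
  schema <- schema %||% .default_schema()
  names(schema)
}

#' Retrieve the schema for one field
#'
#' @param name Field identifier, e.g. `"histologic_grade"`.
#' @param schema Optional schema list; default built-in RCPath colorectal.
#' @return A `field_schema` object: `name`, `label`, `kind`
#'   (`"categorical"` or `"numeric"`), `values`, `numeric_range` + `unit`,
#'   `aliases`, `broad_map`, `na_sentinel`.
#' @export
get_field_schema <- function(name, schema = NULL) {
  schema <- schema %||% .default_schema()
  fs <- schema[[name]]
  if (is.null(fs)) {
    stop("schema not found for field '", name, "'; supported fields: ",
         paste(names(schema), collapse = ", "), call. = FALSE)
  }
  fs
}

#' @export
print.field_schema <- function(x, ...) {
  cat("<field_schema> ", x$name, " (", x$kind, ")\n", sep = "")
  if (x$kind == "categorical") {
    cat("  values: ", paste(x$values, collapse = ", "), "\n", sep = "")
  } else {
    cat("  range: [", x$numeric_range[1], ", ", x$numeric_range[2], "] ",
        x$unit, " or ", x$na_sentinel, "\n", sep = "")
  }
  cat("  na sentinel: ", x$na_sentinel, "\n", sep = "")
  invisible(x)
}

#' All canonical values of a field
#'
#' For categorical fields the ordered value set; for numeric fields the
#' in-range integers as strings plus the NA sentinel (used by round-trip
#' property tests and ordinal encoding).
#'
#' @inheritParams get_field_schema
#' @return Character vector of canonical values.
#' @export
canonical_values <- function(name, schema = NULL) {
  fs <- get_field_schema(name, schema)
  if (fs$kind == "categorical") {
    fs$values
  } else {
    c(as.character(seq(fs$numeric_range[1], fs$numeric_range[2])), fs$na_sentinel)
  }
}

#' Normalise a surface form to a canonical value
#'
#' Case-insensitive, whitespace-trimmed matching against canonical values
#' and aliases. Numeric fields strip units ("45 mm" -> "45"), convert
#' centimetres to millimetres, and reject out-of-range values. Unmatched
#' input returns `NA_character_` (the invalid marker) -- never a guess and
#' never an error, so vote counting can treat unparseable replies
#' uniformly.
#'
#' @param field Field identifier.
#' @param raw Character vector of surface forms.
#' @inheritParams get_field_schema
#' @return Character vector of canonical values; `NA_character_` marks an
#'   invalid (unmatchable) input. Note the NA *sentinel* (e.g. `"pTX"`,
#'   `"NA"`) is a valid canonical string, distinct from the invalid marker.
#' @export
normalize_value <- function(field, raw, schema = NULL) {
  fs <- get_field_schema(field, schema)
  vapply(as.character(raw), function(s) .normalize_one(fs, s),
         character(1), USE.NAMES = FALSE)
}

.normalize_one <- function(fs, s) {
  if (is.na(s)) return(NA_character_)
  s <- trimws(gsub("\\s+", " ", s))
  if (!nzchar(s)) return(NA_character_)
  low <- tolower(s)
  if (low %in% .global_na_forms) return(fs$na_sentinel)
  hit <- unname(fs$lookup[low])
  if (!is.na(hit) && length(hit)) return(hit)
  if (fs$kind == "numeric") return(.normalize_numeric(fs, low))
  NA_character_
}

.normalize_numeric <- function(fs, low) {
  num_re <- "[0-9]+(\\.[0-9]+)?"
  val <- NA_real_
  if (grepl(paste0("^", num_re, "$"), low)) {
    val <- as.numeric(low)
  } else if (grepl(paste0("^", num_re, " ?(mm|millimetres?|millimeters?)$"), low)) {
    val <- as.numeric(sub(" ?(mm|millimetres?|millimeters?)$", "", low))
  } else if (grepl(paste0("^", num_re, " ?(cm|centimetres?|centimeters?)$"), low) &&
             identical(fs$unit, "mm")) {
    val <- 10 * as.numeric(sub(" ?(cm|centimetres?|centimeters?)$", "", low))
  } else if (grepl(paste0("^", num_re, " ?(positive |involved )?(lymph )?nodes?( examined| involved| positive)?$"),
                   low) && identical(fs$unit, "count")) {
    val <- as.numeric(regmatches(low, regexpr(num_re, low)))
  }
  if (is.na(val)) return(NA_character_)
  val <- round(val)
  if (val < fs$numeric_range[1] || val > fs$numeric_range[2]) return(NA_character_)
  as.character(as.integer(val))
}

#' Is a canonical value the field's not-available sentinel?
#'
#' All field-specific sentinels (`NA`, `pTX`, `pNX`, `pMX`, `RX`) are
#' treated as "missing" by abstention and consistency logic.
#'
#' @inheritParams normalize_value
#' @param value Character vector of canonical values.
#' @return Logical vector.
#' @export
is_na_value <- function(field, value, schema = NULL) {
  fs <- get_field_schema(field, schema)
  !is.na(value) & value == fs$na_sentinel
}

#' Is a string a canonical value of a field?
#'
#' @inheritParams is_na_value
#' @return Logical vector.
#' @export
is_canonical_value <- function(field, value, schema = NULL) {
  fs <- get_field_schema(field, schema)
  vapply(as.character(value), function(v) {
    if (is.na(v)) return(FALSE)
    if (fs$kind == "categorical") return(v %in% fs$values)
    if (v == fs$na_sentinel) return(TRUE)
    grepl("^[0-9]+$", v) &&
      as.integer(v) >= fs$numeric_range[1] &&
      as.integer(v) <= fs$numeric_range[2]
  }, logical(1), USE.NAMES = FALSE)
}

#' Map a canonical value to its broad category
#'
#' Sub-staged TNM values collapse to their broad stage (pT4a/pT4b -> pT4,
#' pN1a/b/c -> pN1, pM1a/b/c -> pM1); fields without a granularity split
#' and NA sentinels map to themselves. Idempotent.
#'
#' @inheritParams is_na_value
#' @return Character vector of broad canonical values.
#' @export
to_broad <- function(field, value, schema = NULL) {
  fs <- get_field_schema(field, schema)
  ok <- is_canonical_value(field, value, schema)
  if (any(!ok)) {
    stop("non-canonical value(s) for field '", field, "': ",
         paste(unique(value[!ok]), collapse = ", "), call. = FALSE)
  }
  vapply(as.character(value), function(v) {
    b <- unname(fs$broad_map[v])
    if (length(b) && !is.na(b)) b else v
  }, character(1), USE.NAMES = FALSE)
}

#' Cross-field consistency findings for one report
#'
#' Sanity checks across the RCPath fields of a structured report; returns
#' findings, never mutates. Checked: metastatic node count exceeding the
#' examined count; lymph node status inconsistent with the metastatic count
#' under the standard TNM bins (0 -> pN0, 1-3 -> pN1, >= 4 -> pN2); distant
#' metastasis pM1 together with a complete (R0) resection, which implies no
#' residual disease anywhere.
#'
#' @param report A [structured_report] object, or a named character vector
#'   of canonical values keyed by field name.
#' @inheritParams get_field_schema
#' @return A data frame with columns `code`, `fields`, `message`; zero rows
#'   when the report is consistent.
#' @export
check_report_consistency <- function(report, schema = NULL) {
  values <- if (inherits(report, "structured_report")) {
    report_values(report)
  } else {
    report
  }
  schema <- schema %||% .default_schema()
  findings <- list()
  add <- function(code, fields, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      code = code, fields = paste(fields, collapse = "+"),
      message = message, stringsAsFactors = FALSE)
  }
  num <- function(field) {
    v <- values[[field]]
    if (is.null(v) || is.na(v) || is_na_value(field, v, schema) ||
        !grepl("^[0-9]+$", v)) NA_integer_ else as.integer(v)
  }
  ex <- num("examined_nodes"); met <- num("metastatic_nodes")
  if (!is.na(ex) && !is.na(met) && met > ex) {
    add("node_count_inversion", c("metastatic_nodes", "examined_nodes"),
        sprintf("metastatic node count (%d) exceeds examined count (%d)", met, ex))
  }
  status <- values[["lymph_node_status"]]
  if (!is.na(met) && !is.null(status) && !is.na(status) &&
      !is_na_value("lymph_node_status", status, schema) &&
      is_canonical_value("lymph_node_status", status, schema)) {
    expected <- if (met == 0) "pN0" else if (met <= 3) "pN1" else "pN2"
    if (to_broad("lymph_node_status", status, schema) != expected) {
      add("node_status_mismatch", c("lymph_node_status", "metastatic_nodes"),
          sprintf("%d metastatic nodes bins to %s but status is %s",
                  met, expected, status))
    }
  }
  dm <- values[["distant_metastasis"]]; rs <- values[["resection"]]
  if (!is.null(dm) && !is.na(dm) &&
      is_canonical_value("distant_metastasis", dm, schema) &&
      !is_na_value("distant_metastasis", dm, schema) &&
      to_broad("distant_metastasis", dm, schema) == "pM1" &&
      !is.null(rs) && identical(unname(rs), "R0")) {
    add("m1_with_complete_resection", c("distant_metastasis", "resection"),
        "distant metastasis (pM1) contradicts complete resection (R0)")
  }
  if (length(findings)) {
    do.call(rbind, findings)
  } else {
    data.frame(code = character(0), fields = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
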