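# Prompt construction and reply parsing for the two agents, plus the
# backend contract that isolates model-specific behaviour.
#
# Prompt wording lives in template files under inst/prompts/ (one per agent
# variant) with per-field content (category descriptions, worked examples)
# in field_content.json; code only assembles them. Every prompt has the
# five components role, task, format constraints, examples and uncertainty
# handling; the Extractor has two variants per field (differing in ordering
# and phrasing, not semantics), the Validator one.

.section_keys <- c(ROLE = "role", TASK = "task", FORMAT = "format_constraints",
                   EXAMPLES = "examples", UNCERTAINTY = "uncertainty_handling")

.prompt_assets <- function() {
  if (is.null(.pathstruct_env$prompts)) {
    dir <- system.file("prompts", package = "pathstruct", mustWork = TRUE)
    templates <- list(
      extractor_1 = .read_template(file.path(dir, "extractor_v1.txt")),
      extractor_2 = .read_template(file.path(dir, "extractor_v2.txt")),
      validator   = .read_template(file.path(dir, "validator.txt"))
    )
    content <- jsonlite::fromJSON(file.path(dir, "field_content.json"),
                                  simplifyVector = FALSE)
    .pathstruct_env$prompts <- list(templates = templates, content = content)
  }
  .pathstruct_env$prompts
}

# split a template file into its named sections, preserving file order
.read_template <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  heads <- grep("^## ", lines)
  stopifnot(length(heads) == 5L)
  sections <- character(0)
  for (i in seq_along(heads)) {
    key <- .section_keys[[sub("^## ", "", lines[heads[i]])]]
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    sections[[key]] <- trimws(paste(lines[from:to], collapse = "\n"))
  }
  sections
}

.categories_block <- function(fs, content) {
  notes <- content[[fs$name]]$category_notes
  if (fs$kind == "numeric") {
    return(sprintf(
      "- An integer between %d and %d (%s).\n- \"%s\" if not available.",
      fs$numeric_range[1], fs$numeric_range[2], fs$unit, fs$na_sentinel))
  }
  lines <- vapply(fs$values, function(v) {
    note <- notes[[v]]
    if (v == fs$na_sentinel) {
      sprintf("- %s: if the report does not state this field", v)
    } else if (!is.null(note)) {
      sprintf("- %s: %s", v, note)
    } else {
      sprintf("- %s", v)
    }
  }, character(1))
  paste(lines, collapse = "\n")
}

.extractor_examples_block <- function(fs, content) {
  exs <- content[[fs$name]]$examples
  lines <- vapply(exs, function(ex) {
    sprintf("Report segment: \"%s\" -> {\"%s\": \"%s\"}",
            ex$report, fs$query_key, ex$value)
  }, character(1))
  paste(lines, collapse = "\n")
}

.validator_examples_block <- function(fs, content) {
  ex <- content[[fs$name]]$examples[[1]]
  paste0(
    sprintf("Report segment: \"%s\"; recorded value \"%s\" ->\n", ex$report, ex$value),
    sprintf("{\"Correctness\": \"Correct\", \"Confidence\": 95, \"Corrected\": \"%s\"}",
            ex$value))
}

.fill <- function(text, subs) {
  for (k in names(subs)) {
    text <- gsub(paste0("{{", k, "}}"), subs[[k]], text, fixed = TRUE)
  }
  text
}

.case_marker <- function(report_id, agent, field, value = NULL) {
  m <- sprintf("[[case:%s|agent:%s|field:%s", report_id, agent, field)
  if (!is.null(value)) m <- sprintf("%s|value:%s", m, value)
  paste0(m, "]]")
}

.parse_case_marker <- function(prompt) {
  m <- regmatches(prompt,
    regexec("\\[\\[case:([^|]+)\\|agent:([^|]+)\\|field:([^]|]+)(\\|value:([^]]*))?\\]\\]",
            prompt))[[1]]
  if (!length(m)) return(NULL)
  list(report_id = m[2], agent = m[3], field = m[4],
       value = if (nzchar(m[5])) m[6] else NULL)
}

#' Build an Extractor prompt
#'
#' Assembles one of the two Extractor prompt variants for a query field:
#' a pathologist role statement, a task block enumerating every canonical
#' category with its description and common aliases, a JSON
#' response-format instruction naming the query field, worked examples,
#' and the uncertainty clause permitting "Not Available". Rendering is
#' deterministic: the same (field, variant, report) yields byte-identical
#' text.
#'
#' @param field Field identifier.
#' @param variant Extractor prompt variant, 1 or 2.
#' @param report_text The free-text report (non-empty).
#' @param schema Optional schema list; default built-in.
#' @param report_id Optional report identifier. When supplied (test mode) a
#'   machine-readable case marker is appended so the simulated backend can
#'   resolve the ground truth; production prompts omit it.
#' @return A `prompt_spec` object with `agent`, `field`, `variant`,
#'   `sections` (named list of the five components, in rendered order) and
#'   `rendered` (the final prompt string).
#' @export
build_extractor_prompt <- function(field, variant, report_text, schema = NULL,
                                   report_id = NULL) {
  stopifnot(variant %in% c(1L, 2L))
  if (!is.character(report_text) || !nzchar(trimws(report_text))) {
    stop("report_text must be a non-empty string", call. = FALSE)
  }
  fs <- get_field_schema(field, schema)
  assets <- .prompt_assets()
  template <- assets$templates[[paste0("extractor_", variant)]]
  subs <- list(
    field_label      = fs$label,
    query_key        = fs$query_key,
    categories_block = .categories_block(fs, assets$content),
    examples_block   = .extractor_examples_block(fs, assets$content),
    report_text      = report_text
  )
  sections <- vapply(template, .fill, character(1), subs = subs)
  rendered <- paste(sections, collapse = "\n\n")
  if (!is.null(report_id)) {
    rendered <- paste0(rendered, "\n", .case_marker(report_id, "extractor", field))
  }
  structure(list(agent = "extractor", field = field, variant = as.integer(variant),
                 sections = as.list(sections), rendered = rendered),
            class = "prompt_spec")
}

#' Build the Validator prompt
#'
#' Embeds the report text and the Extractor's value and instructs a JSON
#' reply with exactly the keys `Correctness`, `Confidence` (0-100) and
#' `Corrected`.
#'
#' @inheritParams build_extractor_prompt
#' @param extractor_value The Extractor's canonical value (may be the NA
#'   sentinel); must be canonical for the field.
#' @return A `prompt_spec` object (validator has a single variant).
#' @export
build_validator_prompt <- function(field, report_text, extractor_value,
                                   schema = NULL, report_id = NULL) {
  if (!is.character(report_text) || !nzchar(trimws(report_text))) {
    stop("report_text must be a non-empty string", call. = FALSE)
  }
  if (length(extractor_value) != 1L || is.na(extractor_value) ||
      !nzchar(extractor_value) ||
      !is_canonical_value(field, extractor_value, schema)) {
    stop("extractor_value must be a canonical value (or NA sentinel) for field '",
         field, "'", call. = FALSE)
  }
  fs <- get_field_schema(field, schema)
  assets <- .prompt_assets()
  template <- assets$templates$validator
  subs <- list(
    field_label      = fs$label,
    query_key        = fs$query_key,
    categories_block = .categories_block(fs, assets$content),
    examples_block   = .validator_examples_block(fs, assets$content),
    report_text      = report_text,
    extractor_value  = extractor_value
  )
  sections <- vapply(template, .fill, character(1), subs = subs)
  rendered <- paste(sections, collapse = "\n\n")
  if (!is.null(report_id)) {
    rendered <- paste0(rendered,
                       "\n", .case_marker(report_id, "validator", field,
                                          value = extractor_value))
  }
  structure(list(agent = "validator", field = field, variant = 1L,
                 sections = as.list(sections), rendered = rendered),
            class = "prompt_spec")
}

#' @export
print.prompt_spec <- function(x, ...) {
  cat("<prompt_spec> ", x$agent, " / ", x$field,
      if (x$agent == "extractor") paste0(" (variant ", x$variant, ")"),
      ": ", nchar(x$rendered), " chars\n", sep = "")
  invisible(x)
}

# first JSON object embedded in a reply, tolerating code fences and prose;
# replies are flat objects so a non-nested brace match suffices
.first_json_object <- function(text) {
  m <- regmatches(text, regexpr("\\{[^{}]*\\}", text))
  if (!length(m)) return(NULL)
  tryCatch(jsonlite::fromJSON(m, simplifyVector = FALSE), error = function(e) NULL)
}

# lenient query-key matching: exact (case-insensitive) against the field's
# query key / label / name, or a trailing word of them ("Grade" for
# "Histologic Grade")
.key_matches_field <- function(key, fs) {
  cands <- tolower(unique(c(fs$query_key, fs$label, gsub("_", " ", fs$name))))
  k <- tolower(trimws(key))
  if (!nzchar(k)) return(FALSE)
  k %in% cands || any(endsWith(cands, paste0(" ", k)))
}

#' Parse one Extractor reply
#'
#' Extracts the first JSON object in the raw model output (tolerating code
#' fences and surrounding prose), reads the query-field key
#' case-insensitively and normalises the value through [normalize_value()].
#' Any failure -- no JSON, missing key, unparseable value -- yields
#' `parse_ok = FALSE`; parsing never raises, so malformed output is data.
#'
#' @param raw Verbatim model output (single string).
#' @param field Field identifier.
#' @param schema Optional schema list.
#' @return A `raw_reply` object: `text`, `parse_ok`, `payload` (named list
#'   with the canonical value under the query key when `parse_ok`), and
#'   `value` (canonical value or `NA_character_`).
#' @export
parse_extraction_reply <- function(raw, field, schema = NULL) {
  fs <- get_field_schema(field, schema)
  fail <- structure(list(text = raw, parse_ok = FALSE, payload = NULL,
                         value = NA_character_), class = "raw_reply")
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(fail)
  obj <- .first_json_object(raw)
  if (is.null(obj) || is.null(names(obj))) return(fail)
  idx <- which(vapply(names(obj), .key_matches_field, logical(1), fs = fs))
  if (!length(idx)) return(fail)
  v <- obj[[idx[1]]]
  if (is.null(v) || length(v) != 1L) return(fail)
  canon <- normalize_value(field, as.character(v), schema)
  if (is.na(canon)) return(fail)
  payload <- stats::setNames(list(canon), fs$query_key)
  structure(list(text = raw, parse_ok = TRUE, payload = payload, value = canon),
            class = "raw_reply")
}

#' Parse one Validator reply
#'
#' Requires a JSON object holding `Correctness` (case-folded to
#' `"correct"`/`"incorrect"`), `Confidence` (integer in 0-100) and
#' `Corrected` (any string; normalised later during aggregation). A
#' missing or invalid key yields `parse_ok = FALSE`.
#'
#' @param raw Verbatim model output (single string).
#' @return A `raw_reply` object with payload keys `correctness`,
#'   `confidence`, `corrected` when `parse_ok`.
#' @export
parse_validator_reply <- function(raw) {
  fail <- structure(list(text = raw, parse_ok = FALSE, payload = NULL),
                    class = "raw_reply")
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(fail)
  obj <- .first_json_object(raw)
  if (is.null(obj) || is.null(names(obj))) return(fail)
  keys <- tolower(names(obj))
  get <- function(k) if (k %in% keys) obj[[which(keys == k)[1]]] else NULL
  correctness <- get("correctness")
  confidence <- get("confidence")
  corrected <- get("corrected")
  if (is.null(correctness) || is.null(confidence) || is.null(corrected)) return(fail)
  correctness <- tolower(as.character(correctness))
  if (length(correctness) != 1L || !correctness %in% c("correct", "incorrect")) return(fail)
  confidence <- suppressWarnings(as.numeric(confidence))
  if (length(confidence) != 1L || is.na(confidence) ||
      confidence < 0 || confidence > 100 || confidence != round(confidence)) return(fail)
  corrected <- as.character(corrected)
  if (length(corrected) != 1L || is.na(corrected)) return(fail)
  structure(list(text = raw, parse_ok = TRUE,
                 payload = list(correctness = correctness,
                                confidence = as.integer(confidence),
                                corrected = corrected)),
            class = "raw_reply")
}

#' Sample replies from a backend
#'
#' The backend contract: given a rendered prompt, a number of samples and a
#' seed, return exactly `n_samples` verbatim reply strings. Implementations
#' are side-effect-free with respect to pipeline state; the simulated
#' backend is fully reproducible from the seed. Malformed model output is
#' returned as-is (parsers flag it), never raised.
#'
#' @param backend A backend object ([simulated_backend()] or
#'   [live_backend()]).
#' @param prompt Rendered prompt string.
#' @param n_samples Number of replies to draw.
#' @param seed Integer seed for this call.
#' @return Character vector of length `n_samples`.
#' @export
backend_sample <- function(backend, prompt, n_samples, seed) {
  UseMethod("backend_sample")
}

#' @export
backend_sample.default <- function(backend, prompt, n_samples, seed) {
  stop("no backend_sample method for class ", paste(class(backend), collapse = "/"),
       call. = FALSE)
}

#' Live model backend (optional)
#'
#' A thin configuration object for a hosted model API. The transport is
#' injected as `request_fn(prompt, n_samples)` so the package itself
#' carries no HTTP code and the test suite never touches the network; model
#' name and sampling temperature are configuration, not code.
#'
#' @param model Model name string.
#' @param temperature Sampling temperature.
#' @param request_fn Function `(prompt, n_samples) -> character` performing
#'   the API call. Required for actual use.
#' @param max_retries Bounded retry count on transport errors.
#' @return A `live_backend` object.
#' @export
live_backend <- function(model = "unset", temperature = 1, request_fn = NULL,
                         max_retries = 2L) {
  structure(list(model = model, temperature = temperature,
                 request_fn = request_fn, max_retries = as.integer(max_retries)),
            class = c("live_backend", "pathstruct_backend"))
}

#' @export
backend_sample.live_backend <- function(backend, prompt, n_samples, seed) {
  if (is.null(backend$request_fn)) {
    stop("live backend has no request_fn configured; supply one or use ",
         "simulated_backend()", call. = FALSE)
  }
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    out <- tryCatch(backend$request_fn(prompt, n_samples), error = identity)
    if (!inherits(out, "error")) {
      if (length(out) != n_samples) {
        stop("live backend returned ", length(out), " replies, expected ",
             n_samples, call. = FALSE)
      }
      return(as.character(out))
    }
    if (attempt > backend$max_retries) stop(out)
  }
}
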