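# Extractor and Validator aggregation: repeated sampling, majority voting,
# the documented tie policy, and the per-label consistency terms that feed
# the confidence score.
#
# Tie policy (applies to both agents): among tied modal values the NA
# sentinel wins (a tie signals insufficient evidence); among tied non-NA
# values the lexicographically smallest canonical value wins (radix order,
# locale-independent). The tie flag is always set and surfaced. Invalid
# (parse-failed) replies are not re-requested; they count against the
# denominator, so malformed output depresses confidence.

# deterministic 31-bit string hash (also used for config digests)
.hash31 <- function(s) {
  h <- 7
  for (b in utf8ToInt(enc2utf8(s))) h <- (h * 31 + b) %% 2147483647
  h
}

# derive a reproducible sub-seed below 2^31 from a base seed and keys
.subseed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  mixed <- ((as.numeric(seed) %% 2147483647) * 69069) %% 2147483647
  as.integer((mixed + .hash31(key)) %% 2147483647)
}

.modal_value <- function(counts, na_sentinel = NULL) {
  if (!length(counts)) return(list(value = NA_character_, count = 0, tie = FALSE))
  mx <- max(counts)
  cands <- sort(names(counts)[counts == mx], method = "radix")
  tie <- length(cands) > 1L
  value <- if (!is.null(na_sentinel) && na_sentinel %in% cands) na_sentinel else cands[1]
  list(value = value, count = unname(mx), tie = tie)
}

.as_extraction_replies <- function(replies, field, schema) {
  if (is.character(replies)) {
    replies <- lapply(replies, parse_extraction_reply, field = field, schema = schema)
  }
  replies
}

#' Aggregate Extractor replies by majority vote
#'
#' Counts only successfully parsed replies after normalisation (so "T4A"
#' and "pT4a" pool into one bucket); the modal value wins, ties resolve by
#' the documented policy (NA sentinel preferred, then lexicographically
#' smallest). The Extractor confidence is the modal count over
#' `n_requested`, so invalid replies depress confidence. With zero valid
#' replies the NA sentinel is returned with confidence 0.
#'
#' @param replies List of `raw_reply` objects from
#'   [parse_extraction_reply()], or a character vector of verbatim reply
#'   texts (parsed internally).
#' @param field Field identifier.
#' @param schema Optional schema list.
#' @param n_requested Total replies requested (the confidence
#'   denominator); defaults to `length(replies)`.
#' @return An `aggregated_extraction` object: `field`, `value`,
#'   `e_confidence`, `vote_counts`, `n_requested`, `n_valid`, `tie`.
#' @export
aggregate_votes <- function(replies, field, schema = NULL,
                            n_requested = length(replies)) {
  stopifnot(n_requested >= 1L, length(replies) == n_requested)
  fs <- get_field_schema(field, schema)
  replies <- .as_extraction_replies(replies, field, schema)
  values <- vapply(replies, function(r) {
    if (isTRUE(r$parse_ok)) r$value else NA_character_
  }, character(1))
  valid <- values[!is.na(values)]
  n_valid <- length(valid)
  if (n_valid == 0L) {
    return(structure(list(field = field, value = fs$na_sentinel,
                          e_confidence = 0, vote_counts = integer(0),
                          n_requested = as.integer(n_requested),
                          n_valid = 0L, tie = FALSE),
                     class = "aggregated_extraction"))
  }
  counts <- table(valid)
  counts <- stats::setNames(as.integer(counts), names(counts))
  modal <- .modal_value(counts, fs$na_sentinel)
  structure(list(field = field, value = modal$value,
                 e_confidence = modal$count / n_requested,
                 vote_counts = counts,
                 n_requested = as.integer(n_requested),
                 n_valid = n_valid, tie = modal$tie),
            class = "aggregated_extraction")
}

#' @export
print.aggregated_extraction <- function(x, ...) {
  cat("<aggregated_extraction> ", x$field, " = ", x$value,
      " (EConfidence ", signif(x$e_confidence, 3),
      ", ", x$n_valid, "/", x$n_requested, " valid",
      if (x$tie) ", tie", ")\n", sep = "")
  invisible(x)
}

#' Run the Extractor agent for one field
#'
#' Requests `n_total` replies split evenly across the two prompt variants
#' (the default 20 means 10 per variant), pools all replies and aggregates
#' them with [aggregate_votes()].
#'
#' @inheritParams build_extractor_prompt
#' @param backend Backend object (see [backend_sample()]).
#' @param n_total Total replies to request; must be even.
#' @param seed Integer seed; per-variant sub-seeds are derived from it.
#' @return An `aggregated_extraction`.
#' @export
run_extractor <- function(report_text, field, backend, n_total = 20L, seed = 1L,
                          schema = NULL, report_id = NULL) {
  stopifnot(n_total >= 2L, n_total %% 2L == 0L)
  per_variant <- n_total %/% 2L
  raw <- character(0)
  for (variant in 1:2) {
    prompt <- build_extractor_prompt(field, variant, report_text, schema, report_id)
    out <- tryCatch(
      backend_sample(backend, prompt$rendered, per_variant,
                     .subseed(seed, field, "extractor", variant)),
      error = function(e) {
        stop("extractor backend failed for field '", field, "' (variant ",
             variant, "): ", conditionMessage(e), call. = FALSE)
      })
    raw <- c(raw, out)
  }
  aggregate_votes(raw, field, schema, n_requested = n_total)
}

#' Aggregate Validator replies
#'
#' Per output label (Correctness, Confidence, Corrected) the modal value's
#' frequency over `n_requested` becomes that label's consistency term.
#' Self-reported Confidence values are bucketed to the nearest multiple of
#' `bucket_width` (default 5) before modal voting so 89 vs 90 does not
#' break unanimity. Corrected values are normalised before voting;
#' non-schema values map to the NA sentinel with a warning. `v_pct_correct`
#' is the share of replies asserting the Extractor is correct, over
#' `n_requested`. Ties: Correctness ties resolve to "incorrect" and
#' Confidence ties to the lower bucket (both conservative); Corrected ties
#' follow the Extractor tie policy.
#'
#' @param replies List of `raw_reply` objects from
#'   [parse_validator_reply()], or a character vector of reply texts.
#' @param extractor_value The Extractor's canonical value being validated.
#' @param field Field identifier.
#' @param schema Optional schema list.
#' @param n_requested Total replies requested; defaults to
#'   `length(replies)`.
#' @param bucket_width Width of Confidence buckets before modal voting.
#' @return A `validator_aggregate`: `v_correct`, `v_confidence`,
#'   `v_correction`, `v_pct_correct`, `corrected_value`,
#'   `modal_correctness`, `modal_confidence`, `n_requested`, `n_valid`,
#'   `ties`.
#' @export
aggregate_validator <- function(replies, extractor_value, field, schema = NULL,
                                n_requested = length(replies), bucket_width = 5) {
  stopifnot(length(replies) == n_requested)
  fs <- get_field_schema(field, schema)
  if (is.character(replies)) replies <- lapply(replies, parse_validator_reply)
  ok <- vapply(replies, function(r) isTRUE(r$parse_ok), logical(1))
  n_valid <- sum(ok)
  if (n_valid == 0L) {
    return(structure(list(v_correct = 0, v_confidence = 0, v_correction = 0,
                          v_pct_correct = 0, corrected_value = fs$na_sentinel,
                          modal_correctness = "incorrect", modal_confidence = 0L,
                          n_requested = as.integer(n_requested), n_valid = 0L,
                          ties = character(0)),
                     class = "validator_aggregate"))
  }
  payloads <- lapply(replies[ok], `[[`, "payload")
  correctness <- vapply(payloads, `[[`, character(1), "correctness")
  confidence <- vapply(payloads, `[[`, integer(1), "confidence")
  corrected_raw <- vapply(payloads, `[[`, character(1), "corrected")

  corrected <- normalize_value(field, corrected_raw, schema)
  if (anyNA(corrected)) {
    warning("validator Corrected value(s) outside the '", field,
            "' schema mapped to ", fs$na_sentinel, call. = FALSE)
    corrected[is.na(corrected)] <- fs$na_sentinel
  }

  ties <- character(0)
  cc <- table(correctness)
  m_correct <- .modal_value(stats::setNames(as.integer(cc), names(cc)))
  if (m_correct$tie) {
    m_correct$value <- "incorrect"
    ties <- c(ties, "correctness")
  }
  buckets <- as.integer(round(confidence / bucket_width) * bucket_width)
  bc <- table(buckets)
  m_conf <- .modal_value(stats::setNames(as.integer(bc), names(bc)))
  if (m_conf$tie) {
    m_conf$value <- as.character(min(as.integer(names(bc)[bc == max(bc)])))
    ties <- c(ties, "confidence")
  }
  kc <- table(corrected)
  m_corr <- .modal_value(stats::setNames(as.integer(kc), names(kc)), fs$na_sentinel)
  if (m_corr$tie) ties <- c(ties, "corrected")

  structure(list(
    v_correct = sum(correctness == m_correct$value) / n_requested,
    v_confidence = sum(buckets == as.integer(m_conf$value)) / n_requested,
    v_correction = sum(corrected == m_corr$value) / n_requested,
    v_pct_correct = sum(correctness == "correct") / n_requested,
    corrected_value = m_corr$value,
    modal_correctness = m_correct$value,
    modal_confidence = as.integer(m_conf$value),
    n_requested = as.integer(n_requested), n_valid = as.integer(n_valid),
    ties = ties),
    class = "validator_aggregate")
}

#' @export
print.validator_aggregate <- function(x, ...) {
  cat("<validator_aggregate> ", x$modal_correctness,
      " (V%Correct ", signif(x$v_pct_correct, 3),
      ", corrected -> ", x$corrected_value, ")\n", sep = "")
  invisible(x)
}

#' Run the Validator agent for one field
#'
#' Builds the validator prompt around the Extractor's value, samples
#' `n_total` replies (the study default is 10) and aggregates them with
#' [aggregate_validator()].
#'
#' @inheritParams build_validator_prompt
#' @inheritParams run_extractor
#' @param n_total Total validator replies to request.
#' @return A `validator_aggregate`.
#' @export
run_validator <- function(report_text, field, extractor_value, backend,
                          n_total = 10L, seed = 1L, schema = NULL,
                          report_id = NULL, bucket_width = 5) {
  stopifnot(n_total >= 1L)
  prompt <- build_validator_prompt(field, report_text, extractor_value,
                                   schema, report_id)
  raw <- tryCatch(
    backend_sample(backend, prompt$rendered, n_total,
                   .subseed(seed, field, "validator")),
    error = function(e) {
      stop("validator backend failed for field '", field, "': ",
           conditionMessage(e), call. = FALSE)
    })
  aggregate_validator(raw, extractor_value, field, schema,
                      n_requested = n_total, bucket_width = bucket_width)
}

#' Resolve the final value from both agents
#'
#' If the Validator majority says the extraction is incorrect
#' (`v_pct_correct` strictly below `threshold`, default 0.5) the
#' Validator's modal Corrected value replaces the Extractor's; otherwise
#' the Extractor's value stands. An exact 50/50 split keeps the
#' Extractor's value (the tie favours no correction).
#'
#' @param extraction An `aggregated_extraction`.
#' @param validation A `validator_aggregate` for the same field.
#' @param threshold Correction threshold on `v_pct_correct`.
#' @return The final canonical value (character scalar).
#' @export
resolve_final_value <- function(extraction, validation, threshold = 0.5) {
  stopifnot(inherits(extraction, "aggregated_extraction"),
            inherits(validation, "validator_aggregate"))
  if (validation$v_pct_correct < threshold) validation$corrected_value
  else extraction$value
}

#' Extract all query fields from one report
#'
#' Runs the full two-stage pipeline -- Extractor majority vote, Validator
#' judgement, five-term raw confidence, optional Platt calibration, final
#' value resolution -- for each requested field independently (one query
#' field per prompt) and assembles a [structured_report].
#'
#' @inheritParams run_extractor
#' @param fields Character vector of field identifiers (default: all 11
#'   RCPath fields).
#' @param calibration Optional calibration set: a named list of
#'   `platt_model` objects keyed by field (see [fit_platt()]).
#' @param n_extractor Extractor replies per field (study default 20, split
#'   over the two prompt variants).
#' @param n_validator Validator replies per field (study default 10).
#' @param vconfidence_mode How the VConfidence term is read:
#'   `"consistency"` (the modal Confidence label's reply consistency; the
#'   default) or `"self_report"` (the modal self-reported confidence /
#'   100).
#' @param correction_threshold Passed to [resolve_final_value()].
#' @param report_id Report identifier recorded in the output (and, when
#'   the backend is simulated, used to resolve ground truth).
#' @return A `structured_report`.
#' @export
extract_report <- function(report_text, fields = NULL, backend,
                           calibration = NULL, seed = 1L, schema = NULL,
                           report_id = "report", n_extractor = 20L,
                           n_validator = 10L,
                           vconfidence_mode = c("consistency", "self_report"),
                           correction_threshold = 0.5) {
  vconfidence_mode <- match.arg(vconfidence_mode)
  schema_full <- schema %||% .default_schema()
  if (is.null(fields)) fields <- names(schema_full)
  unknown <- setdiff(fields, names(schema_full))
  if (length(unknown)) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  results <- list()
  for (field in fields) {
    extraction <- run_extractor(report_text, field, backend,
                                n_total = n_extractor,
                                seed = .subseed(seed, report_id, field),
                                schema = schema, report_id = report_id)
    validation <- run_validator(report_text, field, extraction$value, backend,
                                n_total = n_validator,
                                seed = .subseed(seed, report_id, field),
                                schema = schema, report_id = report_id)
    terms <- confidence_terms(extraction, validation,
                              vconfidence_mode = vconfidence_mode)
    raw_conf <- compute_raw_confidence(terms)
    calibrated <- NA_real_
    if (!is.null(calibration) && !is.null(calibration[[field]])) {
      calibrated <- apply_platt(calibration[[field]], raw_conf)
    }
    results[[field]] <- structure(list(
      field = field,
      final_value = resolve_final_value(extraction, validation,
                                        correction_threshold),
      raw_confidence = raw_conf,
      calibrated_confidence = calibrated,
      terms = terms,
      extraction = extraction,
      validation = validation), class = "field_result")
  }
  structured_report(report_id = report_id, results = results,
                    schema_version = attr(schema_full, "schema_version"),
                    config = list(n_extractor = n_extractor,
                                  n_validator = n_validator,
                                  vconfidence_mode = vconfidence_mode,
                                  correction_threshold = correction_threshold))
}
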