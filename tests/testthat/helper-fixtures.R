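# Fixture builders shared across test files.

perfect_profile <- function() {
  responder_profile(accuracy = 1, concentration = 0.5, malformed_rate = 0,
                    validator_informativeness = 1, self_report_noise = 0)
}

# a structured report with randomised but internally consistent contents,
# for round-trip and rendering properties
make_random_report <- function(seed, calibrated = NA) {
  withr::with_seed(seed, {
    fields <- list_fields()
    results <- lapply(fields, function(f) {
      vals <- canonical_values(f)
      value <- sample(vals, 1)
      n_req <- 20L
      k <- sample.int(n_req, 1)
      counts <- stats::setNames(k, value)
      other <- sample(setdiff(vals, value), 1)
      if (k < n_req && stats::runif(1) < 0.7) {
        counts <- c(counts, stats::setNames(sample.int(n_req - k, 1), other))
      }
      extraction <- structure(list(
        field = f, value = value,
        e_confidence = unname(counts[1] / n_req),
        vote_counts = stats::setNames(as.integer(counts), names(counts)),
        n_requested = n_req, n_valid = as.integer(sum(counts)),
        tie = FALSE), class = "aggregated_extraction")
      validation <- structure(list(
        v_correct = stats::runif(1), v_confidence = stats::runif(1),
        v_correction = stats::runif(1), v_pct_correct = stats::runif(1),
        corrected_value = sample(vals, 1),
        modal_correctness = sample(c("correct", "incorrect"), 1),
        modal_confidence = as.integer(5 * sample.int(20, 1)),
        n_requested = 10L, n_valid = sample.int(10, 1),
        ties = character(0)), class = "validator_aggregate")
      terms <- confidence_terms(extraction, validation)
      structure(list(
        field = f, final_value = value,
        raw_confidence = compute_raw_confidence(terms),
        calibrated_confidence = if (is.na(calibrated) && stats::runif(1) < 0.5)
          stats::runif(1) else as.numeric(calibrated),
        terms = terms, extraction = extraction, validation = validation),
        class = "field_result")
    })
    names(results) <- fields
    structured_report(sprintf("rnd_%04d", seed), results,
                      config = list(n_extractor = 20L, n_validator = 10L))
  })
}
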