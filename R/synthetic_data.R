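# Offline test substrate: synthetic colorectal pathology reports with known
# ground truth, survival outcomes driven by the staging fields, and a fully
# seeded simulated model backend with controllable per-field accuracy,
# reply concentration and validator informativeness.
#
# The generator emulates the structure of multi-centre free-text reports
# (macroscopic/microscopic narrative, semi-tabular and terse styles, alias
# usage like "T4A" or sizes quoted in cm) with internally consistent
# values: metastatic nodes never exceed examined nodes and the pN status
# is derived from the metastatic count via the standard TNM bins.

#' Cohort generation configuration
#'
#' @param missingness Probability a field is omitted from the report text
#'   (its truth becomes the NA sentinel).
#' @param alias_rate Probability a field is written as an alias/variant
#'   surface form rather than its canonical spelling.
#' @param templates Report styles to draw from.
#' @param base_rate Baseline exponential hazard (per time unit; the
#'   package treats time as months).
#' @param coef_t,coef_n,coef_m Log-hazard increments per ordinal step of
#'   pT, pN and pM.
#' @param censor_rate Rate of the independent exponential censoring time
#'   (0 = no censoring).
#' @return A validated config list.
#' @export
cohort_config <- function(missingness = 0.15, alias_rate = 0.5,
                          templates = c("narrative", "semi_tabular", "terse"),
                          base_rate = 0.0005, coef_t = 0.5, coef_n = 0.6,
                          coef_m = 0.9, censor_rate = 0.01) {
  rates <- c(missingness = missingness, alias_rate = alias_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("missingness and alias_rate must lie in [0, 1]", call. = FALSE)
  }
  if (base_rate <= 0 || censor_rate < 0) {
    stop("base_rate must be positive and censor_rate non-negative", call. = FALSE)
  }
  if (!length(templates) || !all(templates %in% c("narrative", "semi_tabular", "terse"))) {
    stop("unknown template style", call. = FALSE)
  }
  list(missingness = missingness, alias_rate = alias_rate,
       templates = templates, base_rate = base_rate,
       coef_t = coef_t, coef_n = coef_n, coef_m = coef_m,
       censor_rate = censor_rate)
}

.sample_true_values <- function(schema) {
  v <- character(0)
  pick <- function(x, p) sample(x, 1L, prob = p)
  v["specimen_type"] <- pick(
    c("Right hemicolectomy", "Left hemicolectomy", "Sigmoid colectomy",
      "Anterior resection", "Total colectomy", "Subtotal colectomy",
      "Transverse colectomy", "Hartmann's procedure", "Abdominoperineal excision"),
    c(0.28, 0.12, 0.16, 0.2, 0.05, 0.04, 0.04, 0.06, 0.05))
  v["tumour_type"] <- pick(c("Adenocarcinoma", "Mucinous adenocarcinoma"),
                           c(0.85, 0.15))
  v["tumour_site"] <- pick(
    c("Caecum", "Ascending colon", "Hepatic flexure", "Transverse colon",
      "Splenic flexure", "Descending colon", "Sigmoid colon", "Rectosigmoid",
      "Rectum"),
    c(0.15, 0.12, 0.04, 0.07, 0.04, 0.06, 0.25, 0.08, 0.19))
  v["maximum_diameter"] <- as.character(
    max(3L, min(160L, as.integer(round(stats::rlnorm(1, log(40), 0.4))))))
  v["local_invasion"] <- pick(
    c("pTIS", "pT1", "pT2", "pT3", "pT4a", "pT4b"),
    c(0.02, 0.08, 0.15, 0.5, 0.17, 0.08))
  v["histologic_grade"] <- pick(c("Low", "High"), c(0.8, 0.2))
  examined <- max(1L, min(116L, as.integer(stats::rpois(1, 18))))
  v["examined_nodes"] <- as.character(examined)
  met <- if (stats::runif(1) < 0.45) 0L else {
    as.integer(stats::rbinom(1, examined, stats::runif(1, 0.05, 0.4)))
  }
  met <- min(met, examined, 50L)
  v["metastatic_nodes"] <- as.character(met)
  v["lymph_node_status"] <-
    if (met == 0L) "pN0" else if (met == 1L) "pN1a" else if (met <= 3L) "pN1b" else if (met <= 6L) "pN2a" else "pN2b"
  v["distant_metastasis"] <- pick(c("pM0", "pM1", "pM1a", "pM1b", "pM1c"),
                                  c(0.8, 0.03, 0.08, 0.05, 0.04))
  v["resection"] <- pick(c("R0", "R1", "R2"), c(0.85, 0.12, 0.03))
  v
}

# pick a surface form for a value; must normalise back to the value
.surface_form <- function(field, value, alias_rate, schema) {
  fs <- get_field_schema(field, schema)
  if (fs$kind == "numeric") {
    n <- as.integer(value)
    if (stats::runif(1) < alias_rate) {
      if (identical(fs$unit, "mm")) return(sprintf("%.1f cm", n / 10))
      return(sprintf("%d lymph nodes", n))
    }
    return(if (identical(fs$unit, "mm")) sprintf("%d mm", n) else as.character(n))
  }
  alt <- names(fs$aliases)[fs$aliases == value]
  if (length(alt) && stats::runif(1) < alias_rate) {
    form <- sample(alt, 1L)
    if (grepl("^p?[tnm][0-9]", form)) toupper(form) else form
  } else {
    value
  }
}

.render_report <- function(surface, missing_fields, style, report_id) {
  sf <- function(f) surface[[f]]
  have <- function(f) !f %in% missing_fields
  if (style == "semi_tabular") {
    labels <- c(specimen_type = "Specimen", tumour_type = "Tumour type",
                tumour_site = "Site", maximum_diameter = "Maximum tumour diameter",
                local_invasion = "Local invasion", histologic_grade = "Grade",
                examined_nodes = "Lymph nodes examined",
                metastatic_nodes = "Lymph nodes positive",
                lymph_node_status = "pN stage",
                distant_metastasis = "pM stage", resection = "Resection status")
    lines <- c(sprintf("PATHOLOGY REPORT %s", report_id),
               vapply(names(labels)[vapply(names(labels), have, logical(1))],
                      function(f) sprintf("%s: %s", labels[[f]], sf(f)),
                      character(1)))
    return(paste(lines, collapse = "\n"))
  }
  if (style == "terse") {
    bits <- c(
      if (have("specimen_type")) sprintf("%s.", sf("specimen_type")),
      if (have("maximum_diameter")) sprintf("%s", sf("maximum_diameter")),
      if (have("tumour_type")) sf("tumour_type"),
      if (have("tumour_site")) sprintf("of the %s.", sf("tumour_site")),
      if (have("histologic_grade")) sprintf("Grade: %s.", sf("histologic_grade")),
      if (have("examined_nodes")) sprintf("Nodes: %s examined,", sf("examined_nodes")),
      if (have("metastatic_nodes")) sprintf("%s positive.", sf("metastatic_nodes")),
      if (have("local_invasion")) sprintf("%s", sf("local_invasion")),
      if (have("lymph_node_status")) sprintf("%s", sf("lymph_node_status")),
      if (have("distant_metastasis")) sprintf("%s.", sf("distant_metastasis")),
      if (have("resection")) sprintf("Margins: %s.", sf("resection")))
    return(paste(bits, collapse = " "))
  }
  paras <- c(
    if (have("specimen_type"))
      sprintf("The specimen received is from a procedure recorded as %s.",
              sf("specimen_type")),
    if (have("tumour_site") && have("maximum_diameter"))
      sprintf("There is an ulcerating tumour in the %s measuring %s in maximum diameter.",
              sf("tumour_site"), sf("maximum_diameter"))
    else c(if (have("tumour_site"))
             sprintf("The tumour is centred in the %s.", sf("tumour_site")),
           if (have("maximum_diameter"))
             sprintf("The tumour measures %s in maximum diameter.", sf("maximum_diameter"))),
    if (have("tumour_type") && have("histologic_grade"))
      sprintf("Microscopy shows %s of histologic grade %s.",
              sf("tumour_type"), sf("histologic_grade"))
    else c(if (have("tumour_type"))
             sprintf("Microscopy shows %s.", sf("tumour_type")),
           if (have("histologic_grade"))
             sprintf("The histologic grade is %s.", sf("histologic_grade"))),
    if (have("local_invasion"))
      sprintf("Local invasion is staged as %s.", sf("local_invasion")),
    if (have("examined_nodes"))
      sprintf("A total of %s lymph nodes were examined.", sub(" .*$", "", sf("examined_nodes"))),
    if (have("metastatic_nodes"))
      sprintf("Metastatic carcinoma is present in %s of the sampled nodes.", sf("metastatic_nodes")),
    if (have("lymph_node_status"))
      sprintf("The nodal stage is %s.", sf("lymph_node_status")),
    if (have("distant_metastasis"))
      sprintf("Distant metastatic disease: %s.", sf("distant_metastasis")),
    if (have("resection"))
      sprintf("Resection status is %s.", sf("resection")))
  paste(paras, collapse = " ")
}

#' Generate one synthetic report with ground truth
#'
#' Samples internally consistent field values, renders one of three report
#' styles substituting surface forms (aliases like "T4A" or sizes in cm,
#' per `alias_rate`), and masks fields at the configured missingness rate
#' (their truth becomes the NA sentinel and the text omits them).
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param config A [cohort_config()] list.
#' @param report_id Identifier recorded in the case.
#' @param schema Optional schema list.
#' @return A `ground_truth_case`: `report_id`, `true_values` (named
#'   canonical values), `report_text`, `missing_fields`, `style`,
#'   `surface_forms`, and `latent_values` (the pre-masking values that
#'   drive survival).
#' @export
generate_case <- function(seed, config = cohort_config(), report_id = NULL,
                          schema = NULL) {
  if (is.null(report_id)) report_id <- sprintf("case_%d", seed)
  withr::with_seed(seed, {
    latent <- .sample_true_values(schema)
    fields <- names(latent)
    missing_fields <- fields[stats::runif(length(fields)) < config$missingness]
    truth <- latent
    for (f in missing_fields) truth[f] <- get_field_schema(f, schema)$na_sentinel
    surface <- lapply(stats::setNames(fields, fields), function(f) {
      if (f %in% missing_fields) NA_character_
      else .surface_form(f, latent[[f]], config$alias_rate, schema)
    })
    style <- sample(config$templates, 1L)
    text <- .render_report(surface, missing_fields, style, report_id)
    structure(list(report_id = report_id, true_values = truth,
                   report_text = text, missing_fields = missing_fields,
                   style = style, surface_forms = surface,
                   latent_values = latent),
              class = "ground_truth_case")
  })
}

#' @export
print.ground_truth_case <- function(x, ...) {
  cat("<ground_truth_case> ", x$report_id, " (", x$style, ", ",
      length(x$missing_fields), " missing field(s))\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cohort with survival outcomes
#'
#' Survival times are exponential with log-hazard linear in the ordinal
#' codes of the latent pT, pN and pM stages (coefficients from the
#' config, defaults 0.5/0.6/0.9 per step); censoring is an independent
#' exponential time at `censor_rate` (0 means every record is an event).
#' Reproducible per seed.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param config A [cohort_config()].
#' @param schema Optional schema list.
#' @return A list: `cases` (list of `ground_truth_case`), `truth` (long
#'   data frame `report_id`, `field`, `value`), `survival` (data frame
#'   `report_id`, `time`, `event`), `config`.
#' @export
generate_cohort <- function(n, seed, config = cohort_config(), schema = NULL) {
  stopifnot(n >= 1L)
  ids <- sprintf("case_%04d", seq_len(n))
  cases <- lapply(seq_len(n), function(i) {
    generate_case(.subseed(seed, "case", i), config, report_id = ids[i],
                  schema = schema)
  })
  t_code <- encode_ordinal("local_invasion",
                           vapply(cases, function(cs) cs$latent_values[["local_invasion"]],
                                  character(1)), schema)
  n_code <- encode_ordinal("lymph_node_status",
                           vapply(cases, function(cs) cs$latent_values[["lymph_node_status"]],
                                  character(1)), schema)
  m_code <- encode_ordinal("distant_metastasis",
                           vapply(cases, function(cs) cs$latent_values[["distant_metastasis"]],
                                  character(1)), schema)
  lp <- config$coef_t * t_code + config$coef_n * n_code + config$coef_m * m_code
  survival <- withr::with_seed(.subseed(seed, "survival"), {
    t_event <- stats::rexp(n, rate = config$base_rate * exp(lp))
    if (config$censor_rate > 0) {
      t_cens <- stats::rexp(n, rate = config$censor_rate)
      data.frame(report_id = ids, time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens))
    } else {
      data.frame(report_id = ids, time = t_event, event = 1L)
    }
  })
  truth <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(report_id = cs$report_id, field = names(cs$true_values),
               value = unname(cs$true_values), stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(cases = cases, truth = truth, survival = survival, config = config)
}

#' Simulated responder profile
#'
#' Parameters of the simulated backend: `accuracy` is the probability the
#' simulated model reads a field correctly for a given report (errors are
#' report-level: when the model errs it errs consistently across replies,
#' as a model misreading a report does, so a single reply -- and the
#' majority-voted extraction -- is correct with this probability; a
#' scalar, or a named vector with a `.default` fallback for per-field
#' control);
#' `concentration` is how wrong replies mass on a single alternative
#' (1 = every wrong reply is the same wrong value); `malformed_rate` is
#' the chance a reply is non-JSON prose; `validator_informativeness` the
#' probability a Validator reply judges the Extractor's correctness
#' truthfully; `self_report_noise` the SD of the clipped Gaussian around
#' the informativeness-scaled centre of the 0-100 Confidence label.
#'
#' @param accuracy Scalar or named per-field vector in `[0, 1]`.
#' @param concentration Fraction in `[0, 1]`.
#' @param malformed_rate Fraction in `[0, 1]`.
#' @param validator_informativeness Fraction in `[0, 1]`.
#' @param self_report_noise Non-negative SD on the Confidence label.
#' @return A `responder_profile`.
#' @export
responder_profile <- function(accuracy = 0.9, concentration = 0.5,
                              malformed_rate = 0.02,
                              validator_informativeness = 0.9,
                              self_report_noise = 8) {
  rates <- c(unname(accuracy), concentration, malformed_rate,
             validator_informativeness)
  if (any(rates < 0 | rates > 1)) {
    stop("profile rates must lie in [0, 1]", call. = FALSE)
  }
  if (self_report_noise < 0) stop("self_report_noise must be >= 0", call. = FALSE)
  structure(list(accuracy = accuracy, concentration = concentration,
                 malformed_rate = malformed_rate,
                 validator_informativeness = validator_informativeness,
                 self_report_noise = self_report_noise),
            class = "responder_profile")
}

.field_accuracy <- function(profile, field) {
  acc <- profile$accuracy
  if (length(acc) == 1L && is.null(names(acc))) return(unname(acc))
  if (!is.null(names(acc)) && field %in% names(acc)) return(unname(acc[[field]]))
  if (!is.null(names(acc)) && ".default" %in% names(acc)) return(unname(acc[[".default"]]))
  stop("no accuracy configured for field '", field, "'", call. = FALSE)
}

#' Simulated model backend
#'
#' A [backend_sample()] implementation that resolves the ground truth of
#' the report named in the prompt's case marker and emits stochastic
#' replies per a [responder_profile()]: Extractor replies state the truth
#' with the per-field accuracy (in a random surface form) or a wrong value
#' whose spread is set by `concentration` (numeric fields get near-miss
#' perturbations); Validator replies judge correctness truthfully with the
#' configured informativeness and correct to the truth when they rightly
#' judge "incorrect". Fully reproducible from the seed.
#'
#' @param profile A `responder_profile`.
#' @param cases A list of `ground_truth_case` objects, a cohort from
#'   [generate_cohort()], or a long truth table (`report_id`, `field`,
#'   `value`).
#' @return A `simulated_backend` object.
#' @export
simulated_backend <- function(profile, cases) {
  stopifnot(inherits(profile, "responder_profile"))
  lookup <- new.env(parent = emptyenv())
  if (is.data.frame(cases)) {
    for (id in unique(cases$report_id)) {
      sub <- cases[cases$report_id == id, ]
      assign(id, stats::setNames(as.character(sub$value), sub$field),
             envir = lookup)
    }
    return(structure(list(profile = profile, lookup = lookup),
                     class = c("simulated_backend", "pathstruct_backend")))
  }
  if (!is.null(cases$cases)) cases <- cases$cases
  for (cs in cases) assign(cs$report_id, cs$true_values, envir = lookup)
  structure(list(profile = profile, lookup = lookup),
            class = c("simulated_backend", "pathstruct_backend"))
}

#' @export
backend_sample.simulated_backend <- function(backend, prompt, n_samples, seed) {
  marker <- .parse_case_marker(prompt)
  if (is.null(marker)) {
    stop("simulated backend received a prompt without a case marker",
         call. = FALSE)
  }
  if (!exists(marker$report_id, envir = backend$lookup, inherits = FALSE)) {
    stop("unresolvable report marker '", marker$report_id, "'", call. = FALSE)
  }
  tv <- get(marker$report_id, envir = backend$lookup)
  if (!marker$field %in% names(tv)) {
    stop("no ground truth for field '", marker$field, "'", call. = FALSE)
  }
  truth <- tv[[marker$field]]
  # latent per-(report, field) correctness state: the simulated model either
  # "knows" this field for this report (every reply states the truth) or
  # consistently errs, so a single reply -- and hence the aggregated
  # extraction -- is correct with the configured per-field accuracy. The
  # state is derived from the case content, not the call seed, so the two
  # prompt-variant calls see the same state.
  p <- .field_accuracy(backend$profile, marker$field)
  salt <- .hash31(paste(marker$report_id, paste(tv, collapse = "|")))
  knows <- withr::with_seed(.subseed(salt, marker$field, "latent"),
                            stats::runif(1)) < p
  withr::with_seed(seed, {
    if (marker$agent == "extractor") {
      .simulate_extractor_replies(backend$profile, marker, truth, n_samples, knows)
    } else {
      .simulate_validator_replies(backend$profile, marker, truth, n_samples)
    }
  })
}

.wrong_value <- function(field, truth, profile, marker, schema = NULL) {
  fs <- get_field_schema(field, schema)
  if (fs$kind == "numeric" && truth != fs$na_sentinel) {
    k <- stats::rgeom(1, 0.5) + 1L
    sgn <- sample(c(-1L, 1L), 1L)
    alt <- max(fs$numeric_range[1],
               min(fs$numeric_range[2], as.integer(truth) + sgn * k))
    if (alt == as.integer(truth)) alt <- alt + if (alt < fs$numeric_range[2]) 1L else -1L
    return(as.character(alt))
  }
  pool <- if (fs$kind == "numeric") {
    as.character(seq(fs$numeric_range[1], min(fs$numeric_range[2], 60L)))
  } else {
    fs$values
  }
  pool <- setdiff(pool, truth)
  # the "preferred" wrong value is deterministic per (report, field) so that
  # concentration = 1 yields consistently wrong replies
  preferred <- pool[(.hash31(paste(marker$report_id, field)) %% length(pool)) + 1L]
  if (stats::runif(1) < profile$concentration) preferred else sample(pool, 1L)
}

.reply_surface <- function(field, value, schema = NULL) {
  fs <- get_field_schema(field, schema)
  if (value == fs$na_sentinel && stats::runif(1) < 0.5) return("Not Available")
  alt <- names(fs$aliases)[fs$aliases == value]
  if (length(alt) && stats::runif(1) < 0.3) {
    form <- sample(alt, 1L)
    if (grepl("^p?[tnm][0-9]", form)) toupper(form) else form
  } else {
    value
  }
}

.simulate_extractor_replies <- function(profile, marker, truth, n, knows) {
  fs <- get_field_schema(marker$field)
  vapply(seq_len(n), function(i) {
    if (stats::runif(1) < profile$malformed_rate) {
      return("The report does not state this clearly, I cannot answer.")
    }
    value <- if (knows) truth
    else .wrong_value(marker$field, truth, profile, marker)
    surface <- .reply_surface(marker$field, value)
    body <- sprintf("{\"%s\": \"%s\"}", fs$query_key, surface)
    if (stats::runif(1) < 0.2) sprintf("```json\n%s\n```", body) else body
  }, character(1))
}

.simulate_validator_replies <- function(profile, marker, truth, n) {
  extracted <- marker$value
  actually_correct <- identical(extracted, truth)
  centre <- 50 + 45 * profile$validator_informativeness
  vapply(seq_len(n), function(i) {
    if (stats::runif(1) < profile$malformed_rate) {
      return("Unable to validate this field.")
    }
    truthful <- stats::runif(1) < profile$validator_informativeness
    judged_correct <- if (truthful) actually_correct else !actually_correct
    corrected <- if (judged_correct) {
      extracted
    } else if (!actually_correct && truthful) {
      truth
    } else {
      .wrong_value(marker$field, extracted, profile, marker)
    }
    conf <- as.integer(max(0, min(100, round(
      stats::rnorm(1, centre, profile$self_report_noise)))))
    sprintf("{\"Correctness\": \"%s\", \"Confidence\": %d, \"Corrected\": \"%s\"}",
            if (judged_correct) "Correct" else "Incorrect", conf, corrected)
  }, character(1))
}
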