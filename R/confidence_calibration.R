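# The five-term raw confidence score and its per-field Platt rescaling.
#
# Raw confidence for a query field is the arithmetic mean of five
# consistency fractions -- the Extractor's reply consistency plus the
# Validator's three per-label consistencies and its rate of confirming the
# Extractor -- scaled to 0-100. Because sampled model replies tend to be
# consistent even when wrong, the raw score is overconfident; Platt's
# two-coefficient sigmoid is fitted per field against correctness labels
# to turn it into a probability that reflects observed error rates.

#' Assemble the five confidence terms
#'
#' @param extraction An `aggregated_extraction`.
#' @param validation A `validator_aggregate` for the same field.
#' @param vconfidence_mode `"consistency"` reads the VConfidence term as
#'   the Confidence label's reply consistency (default); `"self_report"`
#'   reads it as the modal self-reported confidence divided by 100.
#' @return A `confidence_terms` object (named list of five fractions).
#' @export
confidence_terms <- function(extraction, validation,
                             vconfidence_mode = c("consistency", "self_report")) {
  vconfidence_mode <- match.arg(vconfidence_mode)
  v_conf <- switch(vconfidence_mode,
                   consistency = validation$v_confidence,
                   self_report = validation$modal_confidence / 100)
  structure(list(e_confidence = extraction$e_confidence,
                 v_correct = validation$v_correct,
                 v_confidence = v_conf,
                 v_correction = validation$v_correction,
                 v_pct_correct = validation$v_pct_correct),
            class = "confidence_terms")
}

#' Raw confidence score for one field
#'
#' The arithmetic mean of the five terms (Extractor consistency, the three
#' Validator label consistencies, and the Validator agreement rate) scaled
#' to 0-100. 100 means every reply of both agents agreed; 0 means no
#' valid agreement at all. Pure and deterministic.
#'
#' @param terms A `confidence_terms` object or numeric vector of the five
#'   fractions, each in `[0, 1]`.
#' @return Numeric scalar in `[0, 100]`.
#' @export
compute_raw_confidence <- function(terms) {
  v <- unlist(terms, use.names = FALSE)
  if (length(v) != 5L || anyNA(v) || !is.numeric(v)) {
    stop("expected five numeric confidence terms", call. = FALSE)
  }
  if (any(v < 0 | v > 1)) {
    stop("confidence terms must lie in [0, 1]", call. = FALSE)
  }
  mean(v) * 100
}

.platt_nll_parts <- function(par, conf, target) {
  p <- 1 / (1 + exp(par[1] * conf + par[2]))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(p = p,
       nll = -sum(target * log(p) + (1 - target) * log(1 - p)),
       grad = c(sum(conf * (target - p)), sum(target - p)))
}

#' Fit Platt scaling for one field
#'
#' Maximum-likelihood fit of the two-coefficient sigmoid
#' `P(correct | c) = 1 / (1 + exp(a c + b))` to raw confidences and 0/1
#' correctness labels, using Platt's smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)` and `t- = 1/(N- + 2)`. Optimised by BFGS
#' followed by Newton polishing to a gradient norm below 1e-8 (at most 200
#' iterations); the negative log-likelihood is convex in (a, b).
#'
#' @param raw_confidences Numeric vector of raw scores in `[0, 100]`.
#' @param labels Integer vector of correctness labels (1 = correct).
#' @param field Field identifier recorded in the model (default
#'   `"pooled"`).
#' @return A `platt_model`: `field`, `a_coef`, `b_coef`, `n_fit`.
#' @export
fit_platt <- function(raw_confidences, labels, field = "pooled") {
  conf <- as.numeric(raw_confidences)
  lab <- as.integer(labels)
  stopifnot(length(conf) == length(lab))
  if (length(conf) < 2L) stop("need at least 2 points to fit", call. = FALSE)
  if (anyNA(conf) || anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    stop("labels must be 0/1 and confidences non-missing", call. = FALSE)
  }
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate fit: labels contain a single class; fall back to ",
         "identity scaling for field '", field, "'", call. = FALSE)
  }
  target <- ifelse(lab == 1L, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  par <- c(0, log((n_neg + 1) / (n_pos + 1)))
  fit <- stats::optim(par,
                      fn = function(p) .platt_nll_parts(p, conf, target)$nll,
                      gr = function(p) .platt_nll_parts(p, conf, target)$grad,
                      method = "BFGS",
                      control = list(maxit = 200L, reltol = 1e-12))
  par <- fit$par
  for (i in seq_len(200L)) {
    parts <- .platt_nll_parts(par, conf, target)
    if (sqrt(sum(parts$grad^2)) < 1e-8) break
    w <- parts$p * (1 - parts$p)
    hess <- matrix(c(sum(conf^2 * w), sum(conf * w),
                     sum(conf * w), sum(w)), 2L, 2L)
    step <- tryCatch(solve(hess, parts$grad), error = function(e) NULL)
    if (is.null(step)) break
    par <- par - step
  }
  structure(list(field = field, a_coef = unname(par[1]),
                 b_coef = unname(par[2]), n_fit = length(conf)),
            class = "platt_model")
}

#' @export
print.platt_model <- function(x, ...) {
  cat("<platt_model> ", x$field, ": a = ", signif(x$a_coef, 4),
      ", b = ", signif(x$b_coef, 4), " (n = ", x$n_fit, ")\n", sep = "")
  invisible(x)
}

#' Apply a fitted Platt model
#'
#' Sigmoid transform `1 / (1 + exp(a c + b))`; strictly monotone in the
#' raw score (increasing when `a < 0`). Calibrated values are probabilities
#' in `(0, 1)`; multiply by 100 for display.
#'
#' @param model A `platt_model` from [fit_platt()].
#' @param raw Numeric vector of raw scores in `[0, 100]`.
#' @return Numeric vector of calibrated probabilities.
#' @export
apply_platt <- function(model, raw) {
  stopifnot(inherits(model, "platt_model"))
  raw <- as.numeric(raw)
  if (anyNA(raw) || any(raw < 0 | raw > 100)) {
    stop("raw confidence must lie in [0, 100]", call. = FALSE)
  }
  1 / (1 + exp(model$a_coef * raw + model$b_coef))
}

#' Fit per-field Platt models from a validation table
#'
#' @param records Data frame with columns `field`, `confidence` (raw score)
#'   and `label` (0/1 correctness).
#' @param pooled If `TRUE`, fields with a single-class label set borrow a
#'   pooled fit over all records instead of erroring; off by default.
#' @return Named list of `platt_model` objects keyed by field.
#' @export
calibrate_fields <- function(records, pooled = FALSE) {
  stopifnot(all(c("field", "confidence", "label") %in% names(records)))
  pooled_model <- NULL
  models <- list()
  for (f in unique(records$field)) {
    sub <- records[records$field == f, ]
    models[[f]] <- tryCatch(
      fit_platt(sub$confidence, sub$label, field = f),
      error = function(e) {
        if (!pooled) stop(e)
        if (is.null(pooled_model)) {
          pooled_model <<- fit_platt(records$confidence, records$label,
                                     field = "pooled")
        }
        m <- pooled_model; m$field <- f; m
      })
  }
  models
}

#' Serialise / load Platt models as JSON
#'
#' @param models Named list of `platt_model` objects.
#' @param path File path.
#' @return `read_calibration` returns the named list of models.
#' @export
write_calibration <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(field = m$field, a_coef = m$a_coef, b_coef = m$b_coef, n_fit = m$n_fit)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  models <- lapply(payload, function(m) {
    structure(list(field = m$field, a_coef = m$a_coef, b_coef = m$b_coef,
                   n_fit = m$n_fit), class = "platt_model")
  })
  stats::setNames(models, vapply(models, `[[`, character(1), "field"))
}
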