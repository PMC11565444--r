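# Evaluation battery: exact-match scoring against manual truth, accuracy,
# Cohen's kappa, AUROC of confidence vs correctness, and abstention
# (rejection) curves.

#' Score extractions against a manual truth table
#'
#' Exact string/integer match after normalisation; at `"broad"`
#' granularity both sides are first collapsed with [to_broad()] (so pT4a
#' vs pT4b agree at the broad level and differ at the specific level).
#' Truth entries missing for an extraction are skipped with a message
#' giving the count. Numeric matching is exact integer equality by
#' default; `diameter_tolerance` admits +/- that many millimetres for the
#' maximum-diameter field.
#'
#' @param extractions Data frame with columns `report_id`, `field`,
#'   `value` and optionally `confidence`, or a list of
#'   [structured_report] objects (converted via [report_table()]).
#' @param truth_table Data frame with columns `report_id`, `field`,
#'   `value` (surface forms allowed; normalised internally).
#' @param granularity `"specific"` (default) or `"broad"`.
#' @param na_matches Whether an NA-sentinel extraction counts as correct
#'   when the truth is also the NA sentinel (default `TRUE`).
#' @param diameter_tolerance Absolute tolerance in mm for
#'   `maximum_diameter` (default 0 = exact).
#' @param schema Optional schema list.
#' @return Data frame of validation records: `report_id`, `field`,
#'   `extracted`, `truth`, `label` (1 = correct), `confidence`.
#' @export
score_extractions <- function(extractions, truth_table,
                              granularity = c("specific", "broad"),
                              na_matches = TRUE, diameter_tolerance = 0,
                              schema = NULL) {
  granularity <- match.arg(granularity)
  if (is.list(extractions) && !is.data.frame(extractions)) {
    extractions <- do.call(rbind, lapply(extractions, report_table))
  }
  stopifnot(all(c("report_id", "field", "value") %in% names(extractions)),
            all(c("report_id", "field", "value") %in% names(truth_table)))
  supported <- list_fields(schema)
  bad <- setdiff(unique(extractions$field), supported)
  if (length(bad)) {
    stop("extraction field(s) absent from schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"confidence" %in% names(extractions)) extractions$confidence <- NA_real_
  key <- function(d) paste(d$report_id, d$field, sep = "\r")
  truth_idx <- stats::setNames(seq_len(nrow(truth_table)), key(truth_table))
  hit <- truth_idx[key(extractions)]
  n_skipped <- sum(is.na(hit))
  if (n_skipped > 0) {
    message(n_skipped, " extraction(s) without a truth entry skipped")
  }
  ext <- extractions[!is.na(hit), , drop = FALSE]
  tru <- truth_table[hit[!is.na(hit)], , drop = FALSE]
  out <- lapply(unique(ext$field), function(f) {
    fs <- get_field_schema(f, schema)
    i <- ext$field == f
    e <- normalize_value(f, ext$value[i], schema)
    t <- normalize_value(f, tru$value[i], schema)
    if (granularity == "broad") {
      e[!is.na(e)] <- to_broad(f, e[!is.na(e)], schema)
      t[!is.na(t)] <- to_broad(f, t[!is.na(t)], schema)
    }
    match_ok <- !is.na(e) & !is.na(t) & e == t
    if (f == "maximum_diameter" && diameter_tolerance > 0) {
      num <- !is.na(e) & !is.na(t) & grepl("^[0-9]+$", e) & grepl("^[0-9]+$", t)
      match_ok[num] <- abs(as.integer(e[num]) - as.integer(t[num])) <=
        diameter_tolerance
    }
    if (!na_matches) {
      both_na <- !is.na(e) & !is.na(t) & e == fs$na_sentinel & t == fs$na_sentinel
      match_ok[both_na] <- FALSE
    }
    data.frame(report_id = ext$report_id[i], field = f,
               extracted = e, truth = t,
               label = as.integer(match_ok),
               confidence = ext$confidence[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(report_id = character(0), field = character(0),
                      extracted = character(0), truth = character(0),
                      label = integer(0), confidence = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extraction accuracy
#'
#' The mean of the 0/1 correctness labels.
#'
#' @param records Data frame of validation records (with a `label`
#'   column) or a vector of 0/1 labels.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(records) {
  labels <- if (is.data.frame(records)) records$label else records
  if (length(labels) < 1L) stop("no records to score", call. = FALSE)
  mean(labels)
}

#' Cohen's kappa on extracted vs truth categories
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products over the union of observed
#' categories. When both raters are constant and equal (`p_e = 1`) kappa
#' is 1 by convention.
#'
#' @param records Data frame with `extracted` and `truth` columns, or a
#'   2-column matrix/data.frame of category pairs.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(records) {
  if (is.data.frame(records) && all(c("extracted", "truth") %in% names(records))) {
    a <- records$extracted; b <- records$truth
  } else {
    a <- records[[1]]; b <- records[[2]]
  }
  if (length(a) < 2L) stop("need at least 2 records", call. = FALSE)
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- "<invalid>"; b[is.na(b)] <- "<invalid>"
  cats <- union(a, b)
  n <- length(a)
  p_o <- mean(a == b)
  p_a <- table(factor(a, cats)) / n
  p_b <- table(factor(b, cats)) / n
  p_e <- sum(as.numeric(p_a) * as.numeric(p_b))
  if (p_e >= 1 - 1e-15) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' AUROC of confidence against correctness
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic:
#' the mean over all (correct, incorrect) pairs of 1 if the correct
#' extraction has the higher confidence, 0.5 on a tie, 0 otherwise.
#' Implemented with midranks.
#'
#' @param confidences Numeric scores used to rank.
#' @param labels 0/1 correctness labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(confidences, labels) {
  conf <- as.numeric(confidences)
  lab <- as.integer(labels)
  stopifnot(length(conf) == length(lab))
  if (anyNA(conf) || anyNA(lab)) stop("missing values in input", call. = FALSE)
  n_pos <- sum(lab == 1L); n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(conf, ties.method = "average")
  (sum(r[lab == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Abstention (rejection) curve
#'
#' At each confidence threshold `t`, extractions with confidence strictly
#' below `t` are rejected; the curve reports the rejected fraction and the
#' accuracy over accepted extractions. Threshold 0 therefore rejects
#' nothing and reproduces the full-coverage accuracy. When everything is
#' rejected the accepted accuracy is `NA` (undefined), never a fabricated
#' number.
#'
#' @param records Data frame with `confidence` and `label` columns.
#' @param thresholds Numeric thresholds; default is 0 plus the sorted
#'   unique confidence values.
#' @return Data frame with columns `threshold`, `rejected_fraction`,
#'   `accepted_accuracy`.
#' @export
abstention_curve <- function(records, thresholds = NULL) {
  stopifnot(all(c("confidence", "label") %in% names(records)))
  conf <- records$confidence; lab <- records$label
  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(0, conf)))
  }
  n <- length(conf)
  rows <- lapply(thresholds, function(t) {
    accept <- conf >= t
    data.frame(threshold = t,
               rejected_fraction = 1 - sum(accept) / n,
               accepted_accuracy = if (any(accept)) mean(lab[accept]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Per-field evaluation summary
#'
#' Accuracy, Cohen's kappa and (where both classes occur) the AUROC of
#' confidence against correctness, per field.
#'
#' @param records Data frame of validation records from
#'   [score_extractions()].
#' @return Data frame with one row per field: `field`, `n`, `accuracy`,
#'   `kappa`, `auroc` (`NA` when undefined).
#' @export
evaluation_summary <- function(records) {
  fields <- unique(records$field)
  rows <- lapply(fields, function(f) {
    sub <- records[records$field == f, ]
    auc <- if (length(unique(sub$label)) == 2L && !anyNA(sub$confidence)) {
      auroc(sub$confidence, sub$label)
    } else NA_real_
    data.frame(field = f, n = nrow(sub),
               accuracy = accuracy(sub),
               kappa = cohen_kappa(sub),
               auroc = auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
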