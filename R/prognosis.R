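# Survival utilities for the prognostic analysis of structured reports:
# Kaplan-Meier estimation, two-group log-rank comparison, Harrell's
# concordance index, and a simple linear ordinal risk score over extracted
# fields with median-split stratification.
#
# The risk score is deliberately plain -- an ordinal coding of the staging
# fields under user-supplied weights -- so that the survival utilities and
# the "extracted fields are prognostic" property are exercisable without
# any learned survival model. Kaplan-Meier and log-rank are delegated to
# the survival package; the concordance index is computed here because its
# tie and permissibility policy is part of this package's contract.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over one group: a step function starting at
#' S = 1; censored times reduce the risk set without a step.
#'
#' @param records Data frame with numeric `time` (>= 0) and `event`
#'   (1 = event observed, 0 = censored) columns.
#' @return Data frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct observed time.
#' @export
km_curve <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)), nrow(records) >= 1L)
  if (any(records$time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(records$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison on the pooled event times of two groups.
#'
#' @param group_a,group_b Data frames with `time` and `event` columns.
#' @return List with `statistic` (chi-square, 1 df) and `p_value`.
#' @export
logrank_test <- function(group_a, group_b) {
  stopifnot(nrow(group_a) >= 1L, nrow(group_b) >= 1L)
  pooled <- rbind(
    data.frame(time = group_a$time, event = group_a$event, grp = "a"),
    data.frame(time = group_b$time, event = group_b$event, grp = "b"))
  if (sum(pooled$event) < 1) {
    stop("log-rank test undefined with zero events", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = pooled)
  stat <- sd$chisq
  list(statistic = unname(stat),
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of censoring-permissible patient pairs whose risk-score order
#' matches their survival-time order. Permissible pairs are those where
#' the earlier time is an event (Harrell), plus pairs tied on time with
#' both events. A pair is concordant when the shorter survival carries the
#' higher risk score; score ties count 0.5. Time-tied event pairs count
#' 0.5 when the scores differ and 1 when the scores tie as well. 1 is
#' perfect concordance; 0.5 the random baseline.
#'
#' @param records Data frame with `time`, `event` and `risk_score`
#'   columns.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(records) {
  stopifnot(all(c("time", "event", "risk_score") %in% names(records)))
  t <- as.numeric(records$time); e <- as.integer(records$event)
  s <- as.numeric(records$risk_score)
  n <- length(t)
  if (n < 2L) stop("no permissible pairs", call. = FALSE)
  # vectorised over the upper triangle of all pairs
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  ti <- t[i]; tj <- t[j]; ei <- e[i]; ej <- e[j]; si <- s[i]; sj <- s[j]
  # orient so "first" is the earlier time for untied pairs
  swap <- tj < ti
  tmp <- ti[swap]; ti[swap] <- tj[swap]; tj[swap] <- tmp
  tmp <- ei[swap]; ei[swap] <- ej[swap]; ej[swap] <- tmp
  tmp <- si[swap]; si[swap] <- sj[swap]; sj[swap] <- tmp
  untied <- ti < tj & ei == 1L
  tied <- ti == tj & ei == 1L & ej == 1L
  num <- sum(ifelse(si[untied] > sj[untied], 1, ifelse(si[untied] == sj[untied], 0.5, 0))) +
    sum(ifelse(si[tied] == sj[tied], 1, 0.5))
  den <- sum(untied) + sum(tied)
  if (den == 0) stop("no permissible pairs under censoring", call. = FALSE)
  num / den
}

#' Ordinal code of a field value
#'
#' Categorical values are coded by their position in the broad category
#' ladder of the schema (pTIS < pT0 < pT1 < pT2 < pT3 < pT4, and
#' analogously for pN and pM); sub-staged values take their broad stage's
#' code. Numeric fields code as the integer value itself. The NA sentinel
#' and invalid values code as `NA` (imputed downstream).
#'
#' @param field Field identifier.
#' @param values Character vector of canonical values.
#' @param schema Optional schema list.
#' @return Numeric vector of ordinal codes.
#' @export
encode_ordinal <- function(field, values, schema = NULL) {
  fs <- get_field_schema(field, schema)
  values <- as.character(values)
  if (fs$kind == "numeric") {
    out <- suppressWarnings(as.numeric(values))
    out[!is.na(values) & values == fs$na_sentinel] <- NA_real_
    return(out)
  }
  non_na <- setdiff(fs$values, fs$na_sentinel)
  ladder <- unique(to_broad(field, non_na, schema))
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & values %in% non_na
  out[ok] <- match(to_broad(field, values[ok], schema), ladder)
  out
}

#' Linear ordinal risk score over extracted fields
#'
#' Weighted sum of ordinal field codes. Missing values (NA sentinels)
#' take the cohort median code of their field, so a missing stage neither
#' inflates nor deflates risk. Deterministic.
#'
#' @param values A data frame with one row per report and one column per
#'   field (canonical values), or a single [structured_report].
#' @param weights Named numeric vector of per-field weights; every name
#'   must be a supported field.
#' @param schema Optional schema list.
#' @return Numeric vector of risk scores (one per row).
#' @export
linear_risk_score <- function(values, weights, schema = NULL) {
  if (inherits(values, "structured_report")) {
    values <- as.data.frame(as.list(report_values(values)),
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  unknown <- setdiff(names(weights), list_fields(schema))
  if (length(unknown)) {
    stop("weight(s) for unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  score <- numeric(nrow(values))
  for (f in names(weights)) {
    if (!f %in% names(values)) {
      stop("field '", f, "' absent from values table", call. = FALSE)
    }
    code <- encode_ordinal(f, values[[f]], schema)
    if (anyNA(code)) {
      med <- stats::median(code, na.rm = TRUE)
      if (is.na(med)) med <- 0
      code[is.na(code)] <- med
    }
    score <- score + weights[[f]] * code
  }
  score
}

#' Median-split risk stratification
#'
#' Splits records into high- and low-risk groups at the median risk
#' score. Scores at or below the median go to the low-risk group (so with
#' odd n the low group gets the extra member); if all scores are equal
#' everything is low-risk, with a warning.
#'
#' @param records Data frame with a `risk_score` column.
#' @return The records with an added `group` column (`"high"`/`"low"`).
#' @export
stratify_by_score <- function(records) {
  stopifnot("risk_score" %in% names(records), nrow(records) >= 2L)
  med <- stats::median(records$risk_score)
  group <- ifelse(records$risk_score > med, "high", "low")
  if (all(group == "low")) {
    warning("all risk scores at or below the median; every record low-risk",
            call. = FALSE)
  }
  records$group <- group
  records
}

#' Default TNM staging weights
#'
#' Equal unit weights on the three staging fields (local invasion, lymph
#' node status, distant metastasis) -- the plain "stage sum" score used by
#' the prognostic sanity checks.
#'
#' @return Named numeric vector.
#' @export
tnm_weights <- function() {
  c(local_invasion = 1, lymph_node_status = 1, distant_metastasis = 1)
}
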