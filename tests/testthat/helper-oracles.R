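# Independent brute-force oracles. These re-state the definitions from
# first principles (explicit pair enumeration, explicit counting) and are
# kept deliberately separate from the package's vectorised/rank-based
# implementations.

# majority vote with the documented tie policy, by explicit counting
oracle_vote <- function(values, na_sentinel) {
  if (!length(values)) return(list(value = na_sentinel, count = 0L, tie = FALSE))
  uv <- unique(values)
  cnt <- vapply(uv, function(v) sum(values == v), integer(1))
  mx <- max(cnt)
  cand <- uv[cnt == mx]
  tie <- length(cand) > 1L
  value <- if (na_sentinel %in% cand) na_sentinel else sort(cand, method = "radix")[1]
  list(value = value, count = mx, tie = tie)
}

# Mann-Whitney by explicit enumeration of all (positive, negative) pairs
oracle_auroc <- function(conf, lab) {
  pos <- conf[lab == 1]
  neg <- conf[lab == 0]
  wins <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  wins / (length(pos) * length(neg))
}

# Harrell's c by explicit double loop over all pairs
oracle_cindex <- function(time, event, score) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (time[i] == time[j]) {
        if (event[i] == 1 && event[j] == 1) {
          den <- den + 1
          num <- num + if (score[i] == score[j]) 1 else 0.5
        }
      } else {
        a <- if (time[i] < time[j]) i else j
        b <- if (time[i] < time[j]) j else i
        if (event[a] == 1) {
          den <- den + 1
          num <- num + if (score[a] > score[b]) 1 else if (score[a] == score[b]) 0.5 else 0
        }
      }
    }
  }
  if (den == 0) stop("no permissible pairs")
  num / den
}

# abstention point by direct filtering
oracle_abstention_point <- function(conf, lab, t) {
  keep <- conf >= t
  list(rejected_fraction = mean(!keep),
       accepted_accuracy = if (any(keep)) mean(lab[keep]) else NA_real_)
}

# wrap canonical values as pre-parsed replies for aggregate_votes
as_replies <- function(values, parse_ok = rep(TRUE, length(values))) {
  mapply(function(v, ok) {
    structure(list(text = v, parse_ok = ok,
                   payload = if (ok) list(value = v) else NULL,
                   value = if (ok) v else NA_character_),
             class = "raw_reply")
  }, values, parse_ok, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
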