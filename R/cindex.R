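# Harrell's concordance index for right-censored data.
#
# Risk convention: HIGHER risk score = expected EARLIER event. Model
# predictions are on the log-time scale (anti-risk), so pass
# `predict(fit, ..., type = "risk")` or negate log-time predictions
# yourself; a sign error silently reports 1 - c.

#' Harrell concordance index
#'
#' A pair (i, j) is comparable when `t_i < t_j` and sample i had an event,
#' or when `t_i == t_j` and exactly one of the two had an event (the event
#' sample must then carry the higher risk). Pairs of tied event times where
#' both had events are not comparable. Concordant pairs have
#' `risk_i > risk_j`; tied risks count 1/2.
#'
#' @param times observed times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param risk_scores risk scores; higher = earlier expected event.
#' @return object of class `cindex_result` with fields `concordant`,
#'   `discordant`, `tied_risk`, `comparable`, and `value` =
#'   `(concordant + 0.5 * tied_risk) / comparable`.
#' @export
harrell_cindex <- function(times, events, risk_scores) {
  n <- length(times)
  if (length(events) != n || length(risk_scores) != n) {
    stop_invalid("times, events, risk_scores must have equal length")
  }
  events <- as.numeric(events)
  conc <- disc <- tied <- 0
  for (i in which(events == 1)) {
    # partners j against which sample i is the earlier, comparable member
    cmp <- times[i] < times | (times[i] == times & events == 0)
    cmp[i] <- FALSE
    if (!any(cmp)) next
    dr <- risk_scores[i] - risk_scores[cmp]
    conc <- conc + sum(dr > 0)
    disc <- disc + sum(dr < 0)
    tied <- tied + sum(dr == 0)
  }
  comparable <- conc + disc + tied
  if (comparable == 0) {
    stop_undefined("no comparable pairs (e.g. all samples censored); ",
                   "the concordance index is undefined")
  }
  structure(list(concordant = conc, discordant = disc, tied_risk = tied,
                 comparable = comparable,
                 value = (conc + 0.5 * tied) / comparable),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("Harrell c-index: %.4f (%d concordant, %d discordant, %d tied of %d comparable pairs)\n",
              x$value, x$concordant, x$discordant, x$tied_risk, x$comparable))
  invisible(x)
}

#' Federated (mean-of-sites) concordance index
#'
#' The unweighted arithmetic mean of per-site c-index values. Note this is
#' deliberately NOT the pooled-data c-index: sites never exchange
#' per-sample risks, only their local statistic, so the federated value can
#' differ from what a central computation on merged data would give.
#'
#' @param local_results list of [harrell_cindex()] results (or bare
#'   numbers); `NULL`/`NA` entries mark sites whose local c-index was
#'   undefined and are excluded with a message.
#' @param weights `"none"` (default, the literal mean of site values) or
#'   `"samples"` to weight sites by their number of comparable pairs.
#' @return scalar c-index.
#' @export
federated_cindex <- function(local_results, weights = c("none", "samples")) {
  weights <- match.arg(weights)
  vals <- vapply(local_results, function(r) {
    if (is.null(r) || (is.atomic(r) && is.na(r))) NA_real_
    else if (inherits(r, "cindex_result")) r$value
    else as.numeric(r)
  }, 0)
  wts <- vapply(local_results, function(r) {
    if (inherits(r, "cindex_result")) r$comparable else 1
  }, 0)
  drop <- is.na(vals)
  if (any(drop)) {
    message(sum(drop), " site(s) with undefined c-index excluded from the mean")
  }
  vals <- vals[!drop]
  wts <- wts[!drop]
  if (length(vals) == 0L) {
    stop_undefined("c-index undefined at every site")
  }
  if (weights == "none") mean(vals) else sum(vals * wts) / sum(wts)
}

#' Divergence between two weight vectors
#'
#' @param model_a,model_b `survsvm` fits or `list(weights=, intercept=)`;
#'   intercepts are included in the comparison.
#' @return list with `max_abs_diff` and `mean_abs_diff`.
#' @export
weight_divergence <- function(model_a, model_b) {
  a <- as_model_params(model_a)
  b <- as_model_params(model_b)
  if (length(a$weights) != length(b$weights)) {
    stop_invalid("models have different numbers of weights")
  }
  d <- abs(c(a$intercept, a$weights) - c(b$intercept, b$weights))
  list(max_abs_diff = max(d), mean_abs_diff = mean(d))
}
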