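# Behavioral accuracy analysis: adjusted logits and the mixed ANOVA.

#' Aggregate trial-level responses into per-dimension accuracies
#'
#' @param events Event table with `position`, `is_target`, `correct`.
#' @return Data frame with one row per target dimension: `k` correct of `n`
#'   targets.
#' @export
aggregate_behavior <- function(events) {
  do.call(rbind, lapply(c("azimuth", "distance"), function(d) {
    sel <- events$position %in% dimension_positions(d)
    data.frame(dimension = d, k = sum(events$correct[sel]), n = sum(sel),
               stringsAsFactors = FALSE)
  }))
}

#' Adjusted logit of an accuracy proportion
#'
#' Uses `p* = (k + 0.5) / (n + 1)` so perfect and zero scores stay finite.
#'
#' @param k Number of correct responses.
#' @param n Number of trials (positive).
#' @return `log(p* / (1 - p*))`.
#' @export
adjusted_logit <- function(k, n) {
  if (any(n <= 0)) stop("zero-trial cells are not allowed", call. = FALSE)
  p <- (k + 0.5) / (n + 1)
  log(p / (1 - p))
}

#' Behavioral accuracy analysis
#'
#' Logit-transforms per-participant accuracies (azimuth and distance
#' dimensions per environment) and runs the mixed age x environment x
#' dimension ANOVA on the logits (conventional, not jackknifed).
#'
#' @param scores Data frame with `participant`, `age`, `environment`,
#'   `dimension`, `k`, `n`.
#' @return List with `scores` (input plus `accuracy` and `logit` columns)
#'   and `anova` (see [mixed_anova_222()]).
#' @export
behavior_analysis <- function(scores) {
  scores$accuracy <- scores$k / scores$n
  scores$logit <- adjusted_logit(scores$k, scores$n)
  list(scores = scores,
       anova = mixed_anova_222(scores, value = "logit"))
}
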