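#' Rank-based ROC-AUC
#'
#' Mann-Whitney formulation: the probability that a random presence scores
#' above a random absence, with ties counted half (midranks). Equivalent to
#' the area under the empirical ROC curve.
#'
#' @param obs 0/1 observed labels (both classes present).
#' @param scores numeric prediction scores.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(obs, scores) {
  obs <- as.integer(obs)
  if (length(obs) != length(scores)) stopf("obs and scores differ in length")
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[obs == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximize the true skill statistic over cutoffs
#'
#' TSS(c) = sensitivity(c) + specificity(c) - 1 with prediction = 1 when
#' score >= c. Scans every midpoint between consecutive sorted unique scores
#' plus the endpoints 0 and 1, and returns the smallest cutoff attaining the
#' maximum.
#'
#' @param obs 0/1 observed labels (both classes present).
#' @param scores numeric prediction scores.
#' @return list of class `evaluation_result` with `auc`, `tss`,
#'   `tss_threshold`, `sensitivity`, `specificity`.
#' @export
tss_optimize <- function(obs, scores) {
  obs <- as.integer(obs)
  if (length(obs) != length(scores)) stopf("obs and scores differ in length")
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)))
  # sens(c) = P(score >= c | y=1), spec(c) = P(score < c | y=0)
  s1 <- sort(scores[obs == 1L]); s0 <- sort(scores[obs == 0L])
  sens <- 1 - findInterval(cand, s1, left.open = TRUE) / n1
  spec <- findInterval(cand, s0, left.open = TRUE) / n0
  tss <- sens + spec - 1
  best <- which.max(tss)            # which.max returns the first (smallest cutoff)
  structure(list(auc = roc_auc(obs, scores), tss = tss[best],
                 tss_threshold = cand[best], sensitivity = sens[best],
                 specificity = spec[best]),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation: AUC %.3f | TSS %.3f at cutoff %.3f (sens %.3f, spec %.3f)\n",
              x$auc, x$tss, x$tss_threshold, x$sensitivity, x$specificity))
  invisible(x)
}
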