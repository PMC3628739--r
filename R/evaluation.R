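## Evaluation module: precision, recall and F-score of an inferred
## network against the ground truth, and aggregation of replicate
## ensembles into per-time-point medians and steady-state ratios.
##
## Scoring convention: all five inference methods produce undirected,
## unsigned edges, so the truth is symmetrized and sign-stripped and the
## confusion counts are taken over unordered gene pairs i < j. (Counting
## ordered pairs doubles TP, FP and FN identically and leaves precision,
## recall and F unchanged.)

#' Confusion counts of an inferred network against the truth
#'
#' Compares the binary adjacency of an estimate with the symmetrized,
#' sign-stripped true network over unordered gene pairs, returning the
#' numbers of true positives, false positives and false negatives. True
#' negatives are never needed by precision, recall or F and are not
#' computed.
#'
#' @param est An \linkS4class{InferredNetwork}.
#' @param truth A \linkS4class{SignedNetwork} with identical gene ids in
#'   identical order (anything else is an error).
#' @return Named list with integer elements \code{TP}, \code{FP},
#'   \code{FN}.
#' @examples
#' truth <- erdosRenyiNetwork(10, p = 0.2, seed = 1)
#' A <- 1 * (adjacencyMatrix(truth) != 0); A <- 1 * ((A + t(A)) > 0)
#' perfect <- new("InferredNetwork", geneIds = geneIds(truth),
#'                adjacency = A, method = "oracle", params = list())
#' confusionCounts(perfect, truth)  # FP = FN = 0
#' @export
confusionCounts <- function(est, truth) {
  if (!identical(geneIds(est), geneIds(truth)))
    stop("gene ids of the estimate and the truth must match (same order)")
  Ae <- adjacencyMatrix(est)
  At <- adjacencyMatrix(truth)
  Atu <- 1 * ((abs(At) + t(abs(At))) > 0)  # symmetrized, sign-stripped
  up <- upper.tri(Ae)
  e <- Ae[up] == 1
  t_ <- Atu[up] == 1
  list(TP = sum(e & t_), FP = sum(e & !t_), FN = sum(!e & t_))
}

#' Precision and recall from confusion counts
#'
#' P = TP / (TP + FP) and R = TP / (TP + FN), each defined as 0 when its
#' denominator is 0 (empty prediction, or an edgeless true network).
#'
#' @param counts List with elements TP, FP, FN (as returned by
#'   [confusionCounts()]).
#' @return Named numeric vector \code{c(precision = , recall = )}.
#' @export
precisionRecall <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  c(precision = P, recall = R)
}

#' F-score from precision and recall
#'
#' The harmonic mean F = 2PR / (P + R), with F = 0 when P + R = 0; F lies
#' in [0, 1], 0 the worst and 1 the best performance.
#'
#' @param precision,recall Values in [0, 1].
#' @return F-score in [0, 1].
#' @examples
#' fScore(2 / 3, 1 / 2)  # 4/7
#' @export
fScore <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Score one inferred network against the truth
#'
#' Convenience wrapper chaining [confusionCounts()], [precisionRecall()]
#' and [fScore()].
#'
#' @inheritParams confusionCounts
#' @return One-row data frame with TP, FP, FN, precision, recall, fscore.
#' @export
scoreNetwork <- function(est, truth) {
  cc <- confusionCounts(est, truth)
  pr <- precisionRecall(cc)
  data.frame(TP = cc$TP, FP = cc$FP, FN = cc$FN,
             precision = pr[["precision"]], recall = pr[["recall"]],
             fscore = fScore(pr[["precision"]], pr[["recall"]]))
}

#' Summarize per-replicate F-scores into a time series
#'
#' Computes, per observational time point, the median F-score over the E
#' replicates and its ratio to the steady-state median (the final time
#' point by default). The ratio is NA (undefined, not 0) when the
#' steady-state median is 0.
#'
#' @param scores Data frame with columns \code{timeIndex},
#'   \code{time}, \code{replicate} and \code{fscore} (one row per (time,
#'   replicate) pair).
#' @param steadyIndex Time index designated as steady state; defaults to
#'   the largest.
#' @return An \linkS4class{FScoreSeries}.
#' @examples
#' df <- expand.grid(timeIndex = 1:3, replicate = 1:5)
#' df$time <- c(0, 1, 50)[df$timeIndex]
#' df$fscore <- 0.3
#' summarizeFScores(df)  # all ratios 1
#' @export
summarizeFScores <- function(scores, steadyIndex = max(scores$timeIndex)) {
  need <- c("timeIndex", "time", "replicate", "fscore")
  if (nrow(scores) == 0) stop("'scores' must be nonempty")
  if (!all(need %in% names(scores)))
    stop("'scores' must have columns ", paste(need, collapse = ", "))
  if (any(scores$fscore < 0 | scores$fscore > 1))
    stop("F-scores must lie in [0, 1]")
  med <- vapply(split(scores$fscore, scores$timeIndex), median, 0)
  ti <- as.integer(names(med))
  ord <- order(ti)
  ti <- ti[ord]; med <- med[ord]
  tv <- vapply(split(scores$time, scores$timeIndex), function(x) x[1], 0)[ord]
  if (!steadyIndex %in% ti) stop("'steadyIndex' has no F-scores")
  fT <- med[ti == steadyIndex]
  ratio <- if (fT > 0) med / fT else rep(NA_real_, length(med))
  new("FScoreSeries",
      scores = scores[, need],
      summary = data.frame(timeIndex = ti, time = tv, median = unname(med),
                           ratio = unname(ratio)),
      steadyIndex = as.integer(steadyIndex))
}

setMethod("show", "FScoreSeries", function(object) {
  cat(sprintf("FScoreSeries: %d time points, %d scores; steady state at index %d\n",
              nrow(object@summary), nrow(object@scores), object@steadyIndex))
  print(object@summary, row.names = FALSE)
})

#' Median/ratio summary table of an FScoreSeries
#' @param series An \linkS4class{FScoreSeries}.
#' @return Data frame with columns timeIndex, time, median, ratio.
#' @export
fscoreSummary <- function(series) series@summary
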