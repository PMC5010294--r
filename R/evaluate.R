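#' Confusion counts for binary disorder calls
#'
#' Disordered (\code{"D"}) is the positive class: TP = correctly called
#' disordered, TN = correctly called ordered.
#'
#' @param predicted,truth character vectors of \code{"O"}/\code{"D"},
#'   equal length, with unavailable positions already excluded
#' @return named integer vector \code{c(tp, tn, fp, fn)}
#' @examples
#' confusionCounts(c("D", "D", "O", "D"), c("D", "O", "O", "D"))
#' @export
confusionCounts <- function(predicted, truth) {
    predicted <- as.character(predicted); truth <- as.character(truth)
    if (length(predicted) != length(truth))
        .stopf("predicted (%d) and truth (%d) lengths differ",
               length(predicted), length(truth))
    bad <- setdiff(unique(c(predicted, truth)), c("O", "D"))
    if (length(bad))
        .stopf("labels must be 'O'/'D'; found: %s", paste(bad, collapse = ", "))
    c(tp = sum(predicted == "D" & truth == "D"),
      tn = sum(predicted == "O" & truth == "O"),
      fp = sum(predicted == "D" & truth == "O"),
      fn = sum(predicted == "O" & truth == "D"))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity:
#' (TP/(TP+FN) + TN/(TN+FP)) / 2.
#'
#' @param counts confusion counts from \code{\link{confusionCounts}}
#' @return balanced accuracy in [0,1]
#' @export
balancedAccuracy <- function(counts) {
    counts <- .asCounts(counts)
    if (counts["tp"] + counts["fn"] == 0)
        .stopf("balanced accuracy undefined: no positive (disordered) residues")
    if (counts["tn"] + counts["fp"] == 0)
        .stopf("balanced accuracy undefined: no negative (ordered) residues")
    unname((counts["tp"] / (counts["tp"] + counts["fn"]) +
            counts["tn"] / (counts["tn"] + counts["fp"])) / 2)
}

#' Precision (positive predictive value)
#'
#' TP / (TP + FP).
#'
#' @inheritParams balancedAccuracy
#' @return precision in [0,1]
#' @export
precisionPPV <- function(counts) {
    counts <- .asCounts(counts)
    if (counts["tp"] + counts["fp"] == 0)
        .stopf("precision undefined: no residues were called disordered")
    unname(counts["tp"] / (counts["tp"] + counts["fp"]))
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any factor
#' of the denominator is zero the coefficient is undefined; by the usual
#' convention 0 is returned.
#'
#' @inheritParams balancedAccuracy
#' @return MCC in [-1, 1]
#' @export
mcc <- function(counts) {
    counts <- .asCounts(counts)
    tp <- counts["tp"]; tn <- counts["tn"]
    fp <- counts["fp"]; fn <- counts["fn"]
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(0)
    unname((tp * tn - fp * fn) / sqrt(den))
}

.asCounts <- function(counts) {
    counts <- unlist(counts)
    if (!all(c("tp", "tn", "fp", "fn") %in% names(counts)))
        .stopf("counts must carry tp, tn, fp, fn")
    if (any(counts < 0)) .stopf("confusion counts must be non-negative")
    as.numeric(counts[c("tp", "tn", "fp", "fn")]) |>
        stats::setNames(c("tp", "tn", "fp", "fn"))
}

#' ROC curve points
#'
#' Sweeps every distinct score as a threshold (call positive when score
#' >= threshold) and returns the (FPR, TPR) operating points from (0,0)
#' to (1,1), in ascending FPR order. Trapezoidal integration of these
#' points (\code{\link{aucTrapezoid}}) equals the pairwise rank
#' statistic: the probability that a random positive outscores a random
#' negative, counting ties as one half.
#'
#' @param probabilities per-residue scores
#' @param truth per-residue labels \code{"O"}/\code{"D"}
#' @return data.frame with columns \code{fpr}, \code{tpr}
#' @export
rocPoints <- function(probabilities, truth) {
    truth <- as.character(truth)
    npos <- sum(truth == "D"); nneg <- sum(truth == "O")
    if (npos == 0L || nneg == 0L)
        .stopf("ROC undefined: both classes must be present")
    thr <- sort(unique(probabilities), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(probabilities >= t & truth == "D"),
                  0) / npos
    fpr <- vapply(thr, function(t) sum(probabilities >= t & truth == "O"),
                  0) / nneg
    data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Trapezoidal area under a ROC curve
#'
#' @param points data.frame from \code{\link{rocPoints}}
#' @return AUC in [0,1]
#' @export
aucTrapezoid <- function(points) {
    o <- order(points$fpr, points$tpr)
    x <- points$fpr[o]; y <- points$tpr[o]
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area under the ROC curve
#'
#' Convenience wrapper: \code{aucTrapezoid(rocPoints(...))}.
#'
#' @inheritParams rocPoints
#' @return AUC in [0,1]
#' @export
auc <- function(probabilities, truth) {
    aucTrapezoid(rocPoints(probabilities, truth))
}

#' Precision-recall curve points
#'
#' Precision and recall at each distinct score threshold (call positive
#' when score >= threshold), in descending threshold order. The sweep
#' stops at the first threshold reaching full recall: lowering it further
#' only adds false positives without recovering more positives.
#'
#' @inheritParams rocPoints
#' @return data.frame with columns \code{threshold}, \code{recall},
#'   \code{precision}
#' @export
precisionRecallPoints <- function(probabilities, truth) {
    truth <- as.character(truth)
    npos <- sum(truth == "D")
    if (npos == 0L)
        .stopf("precision-recall undefined: no positive residues")
    thr <- sort(unique(probabilities), decreasing = TRUE)
    rows <- lapply(thr, function(t) {
        called <- probabilities >= t
        data.frame(threshold = t, recall = sum(called & truth == "D") / npos,
                   precision = sum(called & truth == "D") / sum(called))
    })
    out <- do.call(rbind, rows)
    out[seq_len(which(out$recall >= 1)[1L]), , drop = FALSE]
}

#' Tie-aware competition ranking of disorder predictors
#'
#' Ranks each predictor on each of the four metrics (higher is better)
#' with competition ranking: tied values share the best rank and the
#' following rank is skipped (1,2,2,4). The cumulative score S_c is the
#' sum of the four per-metric ranks, and the final rank orders ascending
#' S_c. Published comparisons are not consistent in how they rank tied
#' cumulative scores, so the final-rank tie policy is selectable:
#' \code{"competition"} (default) or \code{"dense"} (tied values share a
#' rank and the next distinct value takes the next integer: 1,2,2,3).
#'
#' @param metricTable data.frame with a \code{predictor} column (or row
#'   names) and numeric columns \code{acc}, \code{ppv}, \code{mcc},
#'   \code{auc}; ties are detected by exact equality on the values as
#'   given
#' @param finalTies tie policy for the final rank on S_c
#' @return the input with appended integer columns \code{rank_acc},
#'   \code{rank_ppv}, \code{rank_mcc}, \code{rank_auc}, \code{s_c},
#'   \code{final_rank}
#' @export
rankPredictors <- function(metricTable,
                           finalTies = c("competition", "dense")) {
    finalTies <- match.arg(finalTies)
    stopifnot(is.data.frame(metricTable))
    if (is.null(metricTable$predictor))
        metricTable$predictor <- rownames(metricTable)
    need <- c("acc", "ppv", "mcc", "auc")
    miss <- setdiff(need, names(metricTable))
    if (length(miss))
        .stopf("missing metric column(s): %s", paste(miss, collapse = ", "))
    if (nrow(metricTable) < 2L)
        .stopf("ranking needs at least 2 predictors")
    if (any(is.na(metricTable[need])))
        .stopf("metric values must not be missing")
    out <- metricTable
    for (m in need)
        out[[paste0("rank_", m)]] <- .competitionRank(-out[[m]])
    out$s_c <- out$rank_acc + out$rank_ppv + out$rank_mcc + out$rank_auc
    out$final_rank <- switch(finalTies,
        competition = .competitionRank(out$s_c),
        dense = match(out$s_c, sort(unique(out$s_c))))
    out
}

# competition ("1224") ranks, ascending in x
.competitionRank <- function(x) as.integer(rank(x, ties.method = "min"))
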