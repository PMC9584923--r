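# Evaluation machinery: ROC AUC in its rank (Mann-Whitney) form, cumulative
# rank-recovery curves against baselines, and fold enrichment of known
# peptides among top predictions.

#' ROC AUC (Mann-Whitney form)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counted one half — exact under ties, equivalent
#' to the area under the ROC curve.
#'
#' @param labels logical (TRUE = positive) or factor with level "positive".
#' @param scores numeric scores, higher = more positive.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(labels, scores) {
    y <- asPositive(labels)
    if (length(y) != length(scores)) stopf("labels and scores must align")
    nP <- sum(y); nN <- sum(!y)
    if (nP == 0L || nN == 0L)
        stopf("both classes are required to compute an AUC")
    r <- rank(scores, ties.method = "average")
    (sum(r[y]) - nP * (nP + 1) / 2) / (nP * nN)
}

asPositive <- function(labels) {
    if (is.logical(labels)) return(labels)
    if (is.factor(labels) || is.character(labels))
        return(as.character(labels) == "positive")
    as.logical(labels)
}

#' Cumulative rank-recovery curve
#'
#' Number of known (positive) peptides among the top-r predictions, for
#' r = 1..maxRank, under the package's deterministic tie-break (score
#' descending, then abundance descending, then accession/start ascending).
#'
#' @param labels positives as in \code{\link{rocAUC}}.
#' @param scores numeric scores.
#' @param maxRank deepest rank of the curve; must not exceed the number of
#'   rows.
#' @param totalAbundance,protein,start optional tie-break columns (see
#'   \code{\link{rankOrder}}).
#' @param baselineName label stored with the curve.
#' @return data.frame with columns `rank`, `cumulative_known`,
#'   `baseline_name`.
#' @export
rankRecovery <- function(labels, scores, maxRank, totalAbundance = NULL,
                         protein = NULL, start = NULL,
                         baselineName = "model") {
    y <- asPositive(labels)
    if (any(!is.finite(scores))) stopf("scores must be finite")
    if (maxRank > length(y))
        stopf("maxRank (%d) exceeds the number of rows (%d)", maxRank,
              length(y))
    ord <- rankOrder(scores, totalAbundance, protein, start)
    data.frame(rank = seq_len(maxRank),
               cumulative_known = cumsum(y[ord])[seq_len(maxRank)],
               baseline_name = baselineName,
               stringsAsFactors = FALSE)
}

#' Abundance-only null-model scores
#'
#' The baseline model scores each candidate by log10 total abundance alone.
#'
#' @param design design matrix with a `total_abundance` column.
#' @return numeric scores.
#' @export
nullModelScores <- function(design) {
    log10(design$total_abundance)
}

#' Fold enrichment of hits among a selection
#'
#' (hits/k) / (positives/universe): how many times more frequent the
#' positives are among the k selected items than in the whole universe.
#'
#' @param hits positives among the selected k.
#' @param k selection size.
#' @param positives total positives in the universe.
#' @param universe universe size (all scored candidates).
#' @return enrichment factor.
#' @export
foldEnrichment <- function(hits, k, positives, universe) {
    if (universe <= 0L || positives <= 0L)
        stopf("universe and positives must be positive")
    if (hits < 0L || hits > k || k > universe)
        stopf("require 0 <= hits <= k <= universe")
    (hits / k) / (positives / universe)
}
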