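# Classification and integration scoring conventions.

#' Per-class, weighted and macro F1 scores
#'
#' Per-class precision, recall and F1 from the confusion matrix. The
#' weighted F1 averages per-class F1 with class-support weights; the macro
#' F1 averages without weights over classes that occur in the truth.
#' Classes with undefined precision or recall score 0.
#'
#' @param truth,predicted Equal-length label vectors.
#' @return List with `perClass` (data.frame: class, support, precision,
#'   recall, f1), `weightedF1`, `macroF1` and `accuracy`.
#' @export
f1Scores <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    .stopf("truth and predicted must have equal length")
  if (!length(truth)) .stopf("empty label vectors")
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, support = tp + fn, precision = prec,
               recall = rec, f1 = f1)
  }))
  inTruth <- per$support > 0
  list(perClass = per,
       weightedF1 = sum(per$support * per$f1) / sum(per$support),
       macroF1 = mean(per$f1[inTruth]),
       accuracy = mean(truth == predicted))
}

#' Overall integration score
#'
#' Weighted average of the mean batch-mixing score and the mean biological
#' conservation score, with weights 0.4 and 0.6 respectively. Individual
#' component scores (for example from an external integration-metric suite)
#' are supplied as plain numeric vectors in `[0, 1]`.
#'
#' @param batchScores,bioScores Non-empty numeric vectors in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
overallIntegrationScore <- function(batchScores, bioScores) {
  if (!length(batchScores) || !length(bioScores))
    .stopf("both score lists must be non-empty")
  if (any(c(batchScores, bioScores) < 0) || any(c(batchScores, bioScores) > 1))
    .stopf("component scores must lie in [0, 1]")
  0.4 * mean(batchScores) + 0.6 * mean(bioScores)
}

#' kNN batch-mixing score
#'
#' Desk-scale surrogate for graph-based batch-mixing metrics: for each cell,
#' the fraction of same-batch cells among its `k` Euclidean nearest
#' neighbours is compared with the chance rate implied by batch sizes, and
#' the per-cell excess over chance (clamped to `[0, 1]`) is averaged.
#' The score is 1 minus that average: 1 means perfect mixing, 0 means
#' complete batch separation. Invariant under isometries of the latent
#' space.
#'
#' @param latents Cells-by-dimensions matrix.
#' @param batch Per-cell batch labels (at least two batches).
#' @param k Neighbours (`k <` number of cells).
#' @return Scalar in `[0, 1]`.
#' @export
batchMixingKnn <- function(latents, batch, k = 15L) {
  latents <- as.matrix(latents)
  batch <- as.character(batch)
  n <- nrow(latents)
  if (length(batch) != n) .stopf("batch must have one label per cell")
  if (length(unique(batch)) < 2L)
    .stopf("batch mixing undefined for a single batch")
  nn <- .knnIndices(latents, k)
  same <- rowMeans(matrix(batch[nn] == batch, n, k))
  sizes <- table(batch)[batch]
  chance <- (as.vector(sizes) - 1) / (n - 1)
  excess <- pmin(pmax((same - chance) / (1 - chance), 0), 1)
  1 - mean(excess)
}
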