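# Multi-scale analytics on the learned condition (sample) embeddings.

#' PCA of a sample-embedding matrix
#'
#' Centered principal component analysis of per-condition embedding vectors
#' (rows). Signs follow a deterministic convention: within each component
#' the loading of largest magnitude is made positive.
#'
#' @param M Conditions-by-dimensions matrix, e.g. from
#'   [embeddingMatrix()].
#' @param nPcs Number of components to keep; at most
#'   `min(nrow(M) - 1, ncol(M))`.
#' @return List with `scores` (conditions x nPcs), `rotation`, and
#'   `varianceExplained` (fractions of total variance, non-increasing).
#' @export
embeddingPCA <- function(M, nPcs = 2L) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) .stopf("PCA needs at least two conditions")
  maxPcs <- min(nrow(M) - 1L, ncol(M))
  if (nPcs > maxPcs) .stopf("nPcs (%d) exceeds min(n - 1, dims) = %d", nPcs, maxPcs)
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(nPcs), drop = FALSE]
  rot <- pc$rotation[, seq_len(nPcs), drop = FALSE]
  for (j in seq_len(nPcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, rotation = rot, varianceExplained = ve[seq_len(nPcs)])
}

#' Association between a principal component and a covariate
#'
#' Ordinary least squares of the PC scores on the covariate (categorical
#' covariates are dummy-encoded, ordinal ones passed as integer codes), with
#' the adjusted coefficient of determination
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)` reported to account for the
#' number of predictors.
#'
#' @param scores Per-sample scores of one PC (named or aligned with
#'   `covariate`).
#' @param covariate Per-sample categorical (character/factor) or numeric
#'   vector.
#' @param name Covariate name recorded in the result.
#' @param pc PC index recorded in the result.
#' @return data.frame with `covariate`, `pc`, `r.squared`, `adj.r.squared`,
#'   `n`, `p`.
#' @export
pcCovariateAssociation <- function(scores, covariate, name = "covariate",
                                   pc = 1L) {
  n <- length(scores)
  if (length(covariate) != n)
    .stopf("scores and covariate must have equal length")
  if (is.character(covariate)) covariate <- factor(covariate)
  if (is.factor(covariate) && nlevels(droplevels(covariate)) < 2L)
    .stopf("association undefined for a single-level covariate")
  fit <- stats::lm(scores ~ covariate)
  p <- fit$rank - 1L
  if (n - p - 1L < 1L)
    .stopf("association undefined: n - p - 1 = %d", n - p - 1L)
  tss <- sum((scores - mean(scores))^2)
  if (tss == 0) .stopf("association undefined: the scores are constant")
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  data.frame(covariate = name, pc = pc, r.squared = r2, adj.r.squared = adj,
             n = n, p = p)
}

# Deterministic majority vote; ties towards the alphabetically first label.
.majorityVote <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]         # table names are sorted
}

#' k-nearest-neighbour sample classifier on embedding vectors
#'
#' Majority vote over the `k` Euclidean nearest training embeddings, plus a
#' stratified cross-validation summary (accuracy and weighted F1 per fold,
#' mean and standard error) for gauging how well a phenotype can be read
#' off the sample embedding space.
#'
#' @param train Samples-by-dimensions embedding matrix.
#' @param labels Per-sample labels for `train`.
#' @param test Optional matrix of samples to classify.
#' @param k Neighbours.
#' @param folds Cross-validation folds (stratified by label, deterministic
#'   assignment).
#' @return List with `predictions` (for `test`, or `NULL`), `cv`
#'   (per-fold data.frame) and `summary` (mean and standard error of
#'   accuracy and weighted F1).
#' @export
knnSampleClassifier <- function(train, labels, test = NULL, k = 5L,
                                folds = 5L) {
  train <- as.matrix(train)
  labels <- as.character(labels)
  if (k > nrow(train)) .stopf("k (%d) exceeds the number of training samples", k)
  if (any(table(labels) < folds))
    .stopf("every label needs at least %d samples for %d-fold stratified CV",
           folds, folds)
  predict1 <- function(tr, trLab, te, kk) {
    sq <- rowSums(tr^2)
    apply(te, 1L, function(x) {
      d <- sq - 2 * drop(tr %*% x) + sum(x^2)
      .majorityVote(trLab[order(d, method = "radix")[seq_len(kk)]])
    })
  }
  fold <- integer(length(labels))
  for (lb in unique(labels)) {
    i <- which(labels == lb)
    fold[i] <- ((seq_along(i) - 1L) %% folds) + 1L
  }
  cv <- do.call(rbind, lapply(seq_len(folds), function(f) {
    tr <- fold != f
    kk <- min(k, sum(tr))
    pred <- predict1(train[tr, , drop = FALSE], labels[tr],
                     train[!tr, , drop = FALSE], kk)
    sc <- f1Scores(labels[!tr], pred)
    data.frame(fold = f, accuracy = sc$accuracy, weightedF1 = sc$weightedF1)
  }))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(
    predictions = if (!is.null(test))
      predict1(train, labels, as.matrix(test), k) else NULL,
    cv = cv,
    summary = data.frame(
      accuracy = mean(cv$accuracy), accuracy.se = se(cv$accuracy),
      weightedF1 = mean(cv$weightedF1), weightedF1.se = se(cv$weightedF1)))
  out
}

#' Per-condition pseudobulk expression
#'
#' Mean log1p counts per feature within each level of a covariate — the
#' classic sample-level baseline representation.
#'
#' @param ds An [ExpressionDataset-class].
#' @param by Covariate name.
#' @return Conditions-by-features matrix (rows sorted by condition name).
#' @export
pseudobulkBaseline <- function(ds, by) {
  groups <- covariateValues(ds, by)
  L <- log1p(t(.denseMatrix(assay(ds, "counts"))))   # cells x features
  m <- rowsum(L, group = groups)
  m <- m / as.vector(table(groups)[rownames(m)])
  m[order(rownames(m)), , drop = FALSE]
}

#' Gene-PC correlation screen
#'
#' Pearson correlation between each gene's per-sample mean expression
#' (log1p pseudobulk over the covariate whose conditions the scores index)
#' and the scores of one sample-embedding PC. Genes pass the screen when
#' the two-sided p-value is below `pCutoff` and `|r|` exceeds `rCutoff`.
#' Zero-variance genes are excluded with a message.
#'
#' @param ds An [ExpressionDataset-class].
#' @param scores Named per-condition PC scores (names = condition levels).
#' @param by Covariate whose levels the scores are indexed by.
#' @param pCutoff,rCutoff The screen's cutoffs.
#' @return data.frame (`gene`, `r`, `p`, `pass`) sorted by decreasing `r`;
#'   excluded genes are listed in `attr(, "excluded")`.
#' @export
genePCCorrelation <- function(ds, scores, by = "sample",
                              pCutoff = 0.01, rCutoff = 0.3) {
  pb <- pseudobulkBaseline(ds, by)
  if (is.null(names(scores)))
    .stopf("scores must be named by condition level")
  common <- intersect(rownames(pb), names(scores))
  if (length(common) < 3L) .stopf("need at least 3 samples with scores")
  pb <- pb[common, , drop = FALSE]
  s <- scores[common]
  v <- apply(pb, 2L, stats::var)
  excluded <- colnames(pb)[v == 0]
  if (length(excluded))
    message(length(excluded), " zero-variance gene(s) excluded from the screen")
  genes <- colnames(pb)[v > 0]
  res <- do.call(rbind, lapply(genes, function(g) {
    ct <- stats::cor.test(pb[, g], s, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value)
  }))
  res$pass <- res$p < pCutoff & abs(res$r) > rCutoff
  res <- res[order(-res$r), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}
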