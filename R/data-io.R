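#' Read an ExpressionDataset from disk
#'
#' Two plain-text layouts are supported. `"mtx_dir"` is a directory holding
#' `matrix.mtx` (MatrixMarket, features x cells, the usual orientation for
#' sparse single-cell exports), `features.tsv` (one feature id per line) and
#' `cells.tsv` (tab-separated, `cell_id` column plus any covariate and
#' annotation columns). `"delimited"` is a single TSV/CSV table of counts,
#' cells x features with a header row of feature names and cell ids in the
#' first column; per-cell metadata, when present, live in a sidecar
#' `<path>.meta.tsv`. AnnData (`.h5ad`) input is recognized but requires an
#' HDF5 interface that this package does not ship; requesting it raises an
#' informative error.
#'
#' @param path Directory (`mtx_dir`) or file (`delimited`).
#' @param format One of `"mtx_dir"`, `"delimited"`, `"anndata"`.
#' @param covariateKeys,annotationKeys Metadata columns to attach, in
#'   declaration order. Missing columns raise an error naming the key.
#' @param unlabeled Sentinel string for missing annotations.
#' @return A validated [ExpressionDataset-class]; counts stay sparse when
#'   the input matrix is sparse.
#' @seealso [writeExpressionDataset()]
#' @export
readExpressionDataset <- function(path,
                                  format = c("mtx_dir", "delimited", "anndata"),
                                  covariateKeys = character(),
                                  annotationKeys = character(),
                                  unlabeled = .UNLABELED) {
  format <- match.arg(format)
  if (format == "anndata")
    .stopf(paste("AnnData (.h5ad) input requires an HDF5 interface, which is",
                 "not available; export the object as an mtx directory or a",
                 "delimited table instead"))
  if (!file.exists(path)) .stopf("path '%s' does not exist", path)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    cells <- file.path(path, "cells.tsv")
    for (f in c(mtx, feat, cells))
      if (!file.exists(f)) .stopf("expected file '%s' in mtx directory", f)
    m <- Matrix::readMM(mtx)                       # features x cells
    featureIds <- readLines(feat)
    meta <- utils::read.delim(cells, sep = "\t", stringsAsFactors = FALSE,
                              check.names = FALSE, colClasses = "character")
    if (!"cell_id" %in% colnames(meta))
      .stopf("cells.tsv must contain a 'cell_id' column")
    counts <- Matrix::t(m)                         # cells x features
    rownames(counts) <- meta$cell_id
    colnames(counts) <- featureIds
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.delim(path, sep = sep, check.names = FALSE,
                             stringsAsFactors = FALSE, row.names = 1L)
    counts <- as.matrix(tab)
    meta <- NULL
    metaPath <- paste0(path, ".meta.tsv")
    if (file.exists(metaPath)) {
      meta <- utils::read.delim(metaPath, sep = "\t", stringsAsFactors = FALSE,
                                check.names = FALSE, colClasses = "character")
    } else if (length(covariateKeys) || length(annotationKeys)) {
      .stopf("metadata keys requested but sidecar '%s' not found", metaPath)
    } else {
      meta <- data.frame(cell_id = rownames(counts), check.names = FALSE)
    }
  }
  for (key in c(covariateKeys, annotationKeys))
    if (!key %in% colnames(meta))
      .stopf("metadata key '%s' not found in %s", key,
             if (format == "mtx_dir") "cells.tsv" else "metadata sidecar")
  bad <- .checkCounts(counts)
  if (!is.null(bad)) .stopf("invalid counts in '%s': %s", path, bad)
  ExpressionDataset(
    counts,
    covariates = stats::setNames(lapply(covariateKeys, function(k) meta[[k]]),
                                 covariateKeys),
    annotations = stats::setNames(lapply(annotationKeys, function(k) meta[[k]]),
                                  annotationKeys),
    cellIds = if (!is.null(meta$cell_id)) meta$cell_id else rownames(counts),
    unlabeled = unlabeled)
}

#' Write an ExpressionDataset to disk
#'
#' Inverse of [readExpressionDataset()]: `load(save(ds))` reproduces counts,
#' covariates and annotations exactly (sparse matrices are canonicalized by
#' dropping explicit zeros).
#'
#' @param ds An [ExpressionDataset-class].
#' @param path Output directory (`mtx_dir`) or file (`delimited`).
#' @param format One of `"mtx_dir"`, `"delimited"`.
#' @return Invisibly, `path`.
#' @export
writeExpressionDataset <- function(ds, path, format = c("mtx_dir", "delimited")) {
  format <- match.arg(format)
  meta <- data.frame(cell_id = colnames(ds), check.names = FALSE,
                     stringsAsFactors = FALSE)
  for (key in c(covariateKeys(ds), annotationKeys(ds)))
    meta[[key]] <- as.character(colData(ds)[[key]])
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(path)) .stopf("cannot create directory '%s'", path)
    m <- assay(ds, "counts")
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    m <- Matrix::drop0(m)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(rownames(ds), file.path(path, "features.tsv"))
    utils::write.table(meta, file.path(path, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    counts <- t(.denseMatrix(assay(ds, "counts")))   # cells x features
    tab <- data.frame(cell_id = rownames(counts), counts, check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) .stopf("cannot write to '%s'", path)
    if (ncol(meta) > 1L)
      utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Select highly variable features
#'
#' Dispersion-based ranking in the style popularized for scRNA-seq feature
#' selection: counts are library-normalized (scaled to 10,000 per cell) and
#' log1p-transformed, the per-feature mean and variance-to-mean ratio of the
#' de-logged values are computed, features are binned into 20
#' equal-frequency bins by mean, and the log dispersion is z-scored within
#' each bin. The top `nTop` features by normalized dispersion are kept (ties
#' broken by feature order, so the ranking is deterministic). With
#' `perBatch`, the normalized dispersion is computed within each level of a
#' covariate and averaged, favouring features variable in every batch.
#'
#' @param ds An [ExpressionDataset-class].
#' @param nTop Number of features to keep; must not exceed the feature count.
#' @param perBatch Optional covariate name; default is global selection.
#' @return `ds` restricted to the selected features (original feature order
#'   preserved).
#' @export
selectHVGs <- function(ds, nTop, perBatch = NULL) {
  G <- nrow(ds)
  if (nTop > G) .stopf("nTop (%d) exceeds the number of features (%d)", nTop, G)
  if (is.null(perBatch)) {
    z <- .normalizedDispersion(ds, seq_len(ncol(ds)))
  } else {
    groups <- covariateValues(ds, perBatch)
    zs <- vapply(sort(unique(groups)), function(g)
      .normalizedDispersion(ds, which(groups == g)), numeric(G))
    z <- rowMeans(zs)
  }
  keep <- sort(order(-z, seq_along(z), method = "radix")[seq_len(nTop)])
  ds[keep, ]
}

# Seurat-flavour normalized dispersion for a subset of cells.
.normalizedDispersion <- function(ds, cells, nBins = 20L) {
  X <- .denseMatrix(assay(ds, "counts")[, cells, drop = FALSE]) # G x n
  lib <- pmax(colSums(X), 1)
  norm <- log1p(sweep(X, 2L, 1e4 / lib, "*"))
  e <- expm1(norm)
  mu <- rowMeans(e)
  v <- apply(e, 1L, stats::var)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), -Inf)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, seq(0, 1, length.out = nBins + 1L))),
              include.lowest = TRUE)
  z <- numeric(length(mu))
  for (b in levels(bins)) {
    i <- which(bins == b & is.finite(disp))
    if (!length(i)) next
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[!is.finite(disp)] <- -Inf
  z
}
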