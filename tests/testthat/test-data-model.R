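test_that("ExpressionDataset validates counts and metadata lengths", {
  m <- matrix(c(1, 2, 0, 3, 4, 5), nrow = 2)
  ds <- ExpressionDataset(m, covariates = list(sample = c("a", "b")),
                          annotations = list(cell_type = c("T", "unlabeled")))
  expect_s4_class(ds, "ExpressionDataset")
  expect_identical(librarySize(ds), c(cell0001 = 5, cell0002 = 10))
  expect_error(ExpressionDataset(m, covariates = list(sample = "a")),
               "length 2")
  expect_error(ExpressionDataset(matrix(c(1.5, 2, 3, 4), 2)),
               "non-negative integers")
  expect_error(ExpressionDataset(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative integers")
  expect_error(covariateValues(ds, "nope"), "unknown covariate 'nope'")
})

test_that("delimited read matches hand-parsed values and round-trips", {
  tab <- rbind(c(0, 3, 1, 2, 7), c(5, 0, 0, 1, 1), c(2, 2, 2, 2, 2),
               c(9, 0, 4, 0, 1))
  dimnames(tab) <- list(paste0("c", 1:4), paste0("g", 1:5))
  path <- file.path(tempdir(), "toy.tsv")
  writeLines(c(paste(c("cell_id", colnames(tab)), collapse = "\t"),
               vapply(1:4, function(i)
                 paste(c(rownames(tab)[i], tab[i, ]), collapse = "\t"), "")),
             path)
  ds <- readExpressionDataset(path, "delimited")
  expect_equal(unname(rawCells(ds)), unname(tab))
  expect_identical(colnames(ds), rownames(tab))

  ds2 <- ExpressionDataset(tab, covariates = list(sample = c("a", "a", "b", "b")),
                           annotations = list(ct = c("x", "unlabeled", "y", "x")))
  out <- file.path(tempdir(), "rt.tsv")
  writeExpressionDataset(ds2, out, "delimited")
  back <- readExpressionDataset(out, "delimited", covariateKeys = "sample",
                                annotationKeys = "ct")
  expect_equal(rawCells(back), rawCells(ds2))
  expect_identical(covariateValues(back, "sample"), covariateValues(ds2, "sample"))
  expect_identical(annotationValues(back, "ct"), annotationValues(ds2, "ct"))
})

test_that("mtx directory round-trip preserves everything incl. sentinels", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 2L, cellsPerBatch = 20L,
                                           nFeatures = 15L))
  ds <- atlas$reference
  dir <- file.path(tempdir(), "mtxdir")
  writeExpressionDataset(ds, dir, "mtx_dir")
  back <- readExpressionDataset(dir, "mtx_dir", covariateKeys = "sample",
                                annotationKeys = "cell_type")
  expect_equal(as.matrix(rawCells(back)), as.matrix(rawCells(ds)))
  expect_true(is(SummarizedExperiment::assay(back, "counts"), "sparseMatrix"))
  expect_identical(covariateValues(back, "sample"), covariateValues(ds, "sample"))
  expect_identical(annotationValues(back, "cell_type"),
                   annotationValues(ds, "cell_type"))
  expect_true(any(annotationValues(back, "cell_type") == unlabeledToken(back)))
  expect_error(readExpressionDataset(dir, "mtx_dir", covariateKeys = "donor"),
               "donor")
})

test_that("sparse matrices with explicit zeros canonicalize on write", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(1, 1, 3), x = c(2, 0, 5),
                            dims = c(2, 4))
  ds <- ExpressionDataset(m)
  dir <- file.path(tempdir(), "mtxzero")
  writeExpressionDataset(ds, dir, "mtx_dir")
  back <- readExpressionDataset(dir, "mtx_dir")
  expect_equal(as.matrix(rawCells(back)), as.matrix(as.matrix(m)),
               ignore_attr = TRUE)
})

test_that("anndata format raises an informative unsupported error", {
  expect_error(readExpressionDataset("x.h5ad", "anndata"), "HDF5")
})

test_that("HVG selection is deterministic and ranks by dispersion", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 3L, cellsPerBatch = 40L))
  ds <- atlas$reference
  expect_identical(rownames(selectHVGs(ds, nrow(ds))), rownames(ds))
  expect_error(selectHVGs(ds, nrow(ds) + 1L), "exceeds")

  # a constant feature never outranks a variable one
  m <- rawCells(ds)
  m[, 1] <- 5L
  ds2 <- ExpressionDataset(m, covariates = list(sample = covariateValues(ds, "sample")))
  top <- selectHVGs(ds2, 10L)
  expect_false(rownames(ds2)[1] %in% rownames(top))

  # direct recomputation of the binned-dispersion criterion reproduces the
  # selected feature set
  set.seed(4)
  base <- matrix(rpois(150 * 60, 8), 150, 60)
  hot <- seq(5, 60, by = 12)
  base[, hot] <- matrix(rnbinom(150 * length(hot), mu = 8, size = 0.4),
                        150)   # same mean, much higher dispersion
  ds3 <- ExpressionDataset(base)
  lib <- pmax(rowSums(base), 1)
  e <- expm1(log1p(base / lib * 1e4))
  mu <- colMeans(e)
  v <- apply(e, 2, var)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), -Inf)
  bins <- cut(mu, breaks = unique(quantile(mu, seq(0, 1, length.out = 21))),
              include.lowest = TRUE)
  z <- numeric(60)
  for (b in levels(bins)) {
    i <- which(bins == b & is.finite(disp))
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  want <- sort(order(-z, seq_along(z))[1:10])
  expect_identical(rownames(selectHVGs(ds3, 10L)), rownames(ds3)[want])
  # binning perturbs the raw dispersion order, but most of the genuinely
  # overdispersed features must surface
  expect_gte(sum(hot %in% want), 3L)

  # per-batch selection runs and returns the requested number
  expect_equal(nrow(selectHVGs(ds, 20L, perBatch = "sample")), 20L)
})

test_that("synthetic atlas generation is a pure function of its spec", {
  s <- tinySpec(seed = 9L, cellsPerBatch = 25L)
  a1 <- generateSyntheticAtlas(s)
  a2 <- generateSyntheticAtlas(s)
  expect_identical(as.matrix(rawCells(a1$reference)), as.matrix(rawCells(a2$reference)))
  expect_identical(as.matrix(rawCells(a1$query)), as.matrix(rawCells(a2$query)))
  expect_identical(a1$truth, a2$truth)
  expect_identical(librarySize(a1$reference),
                   Matrix::colSums(SummarizedExperiment::assay(a1$reference, "counts")))
})

test_that("zero batch effect gives identical per-type means across batches", {
  a <- generateSyntheticAtlas(tinySpec(seed = 12L, batchEffectScale = 0,
                                       cellsPerBatch = 400L, nFeatures = 30L,
                                       fractionUnlabeled = 0))
  m <- rawCells(a$reference)
  type <- a$truth$reference
  batch <- covariateValues(a$reference, "sample")
  for (tp in unique(type)) {
    g <- 1L  # compare first feature's mean across the two largest batches
    bs <- names(sort(table(batch[type == tp]), decreasing = TRUE))[1:2]
    x1 <- m[type == tp & batch == bs[1], g]
    x2 <- m[type == tp & batch == bs[2], g]
    se <- sqrt(var(x1) / length(x1) + var(x2) / length(x2))
    expect_lt(abs(mean(x1) - mean(x2)), 4 * se + 1e-9)
  }
})

test_that("synthetic counts match negative-binomial moments", {
  # one (type, batch) group with ~2000 cells; mean/variance within 3 SE
  spec <- syntheticAtlasSpec(nCellTypes = 1L, nBatches = 1L, nQueryBatches = 0L,
                             cellsPerBatch = 2000L, nFeatures = 8L,
                             batchEffectScale = 0, typeSeparation = 0,
                             dispersion = 2, fractionUnlabeled = 0, seed = 21L)
  a <- generateSyntheticAtlas(spec)
  m <- rawCells(a$reference)
  n <- nrow(m)
  for (g in seq_len(ncol(m))) {
    mu <- mean(m[, g])
    v <- var(m[, g])
    vTheory <- mu + mu^2 / 2
    seMean <- sqrt(vTheory / n)
    # SE of the sample variance via the fourth central moment
    m4 <- mean((m[, g] - mu)^4)
    seVar <- sqrt((m4 - v^2) / n)
    expect_lt(abs(v - vTheory), 3 * seVar + 3 * seMean * 2 * mu)
  }
})

test_that("held-out types appear only in the query", {
  a <- generateSyntheticAtlas(tinySpec(seed = 8L, heldOutTypes = 2L,
                                       heldOutFraction = 0.2))
  expect_false("type2" %in% a$truth$reference)
  expect_true("type2" %in% a$truth$query)
  expect_error(syntheticAtlasSpec(nCellTypes = 2L, heldOutTypes = 1:2),
               "exhaust")
})
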