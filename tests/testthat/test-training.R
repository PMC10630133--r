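test_that("training is deterministic given seed and config", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 61L, cellsPerBatch = 50L))
  m1 <- buildReference(atlas$reference, tinyConfig(seed = 61L), nEpochs = 12L)
  m2 <- buildReference(atlas$reference, tinyConfig(seed = 61L), nEpochs = 12L)
  r1 <- trainingReport(m1); r2 <- trainingReport(m2)
  expect_identical(r1[, setdiff(names(r1), "seconds")],
                   r2[, setdiff(names(r2), "seconds")])
  expect_identical(m1@params, m2@params)
  expect_identical(getLatent(atlas$reference, m1),
                   getLatent(atlas$reference, m2))
})

test_that("the phase switches once at the pretrain fraction", {
  run <- tinyRun()
  rep <- trainingReport(run$model)
  expect_identical(unique(rep$phase), c("pretrain", "finetune"))
  expect_equal(sum(rep$phase == "pretrain"), ceiling(0.9 * nrow(rep)))
  expect_true(all(diff(rep$klWeight) >= 0))
  expect_true(all(rep$prototype[rep$phase == "pretrain"] == 0))
  expect_true(all(rep$prototype[rep$phase == "finetune"] > 0))
})

test_that("zero prototype weight reproduces plain CVAE training", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 62L, cellsPerBatch = 40L))
  ds <- atlas$reference
  plain <- ExpressionDataset(rawCells(ds),
                             covariates = list(sample = covariateValues(ds, "sample")),
                             cellIds = colnames(ds), featureIds = rownames(ds))
  cfg <- tinyConfig(seed = 62L, prototypeLossWeight = 0)
  mA <- buildReference(ds, cfg, nEpochs = 10L)
  mB <- buildReference(plain, cfg, nEpochs = 10L)
  ra <- trainingReport(mA); rb <- trainingReport(mB)
  expect_equal(ra$recon, rb$recon, tolerance = 1e-12)
  expect_equal(ra$kl, rb$kl, tolerance = 1e-12)
})

test_that("fine-tuning tightens cells around their prototypes", {
  run <- tinyRun()
  rep <- trainingReport(run$model)
  ft <- rep$prototype[rep$phase == "finetune"]
  expect_lt(ft[length(ft)], ft[1])
})

test_that("all-unlabeled reference with prototype weight falls back with a warning", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 63L, cellsPerBatch = 30L,
                                           fractionUnlabeled = 1))
  expect_warning(
    m <- buildReference(atlas$reference, tinyConfig(seed = 63L), nEpochs = 6L),
    "without the prototype loss")
  expect_true(all(trainingReport(m)$prototype == 0))
})

test_that("query mapping freezes the network and the reference embeddings", {
  run <- tinyRun()
  model <- run$model
  qmodel <- run$qmodel
  embNames <- paste0("emb.", covariateKeys(model))
  for (nm in setdiff(names(model@params), embNames))
    expect_identical(qmodel@params[[nm]], model@params[[nm]])
  refLev <- conditionLevels(model, "sample")
  expect_identical(embeddingMatrix(qmodel, "sample")[refLev, ],
                   embeddingMatrix(model, "sample")[refLev, ])
  expect_gt(nrow(embeddingMatrix(qmodel, "sample")), length(refLev))

  # reference-cell latents are bitwise unchanged
  expect_identical(getLatent(run$atlas$reference, qmodel),
                   getLatent(run$atlas$reference, model))
})

test_that("a fully unlabeled query trains without a prototype term", {
  run <- tinyRun()
  rep <- trainingReport(run$qmodel)
  expect_true(all(rep$prototype == 0))
  # and stores query unlabeled cluster prototypes for exploration
  ps <- cellPrototypes(run$qmodel, "cell_type")
  expect_identical(ps@provenance, "query")
  expect_gt(nrow(unlabeledPrototypes(ps)), 0L)
  # labeled prototypes carried over from the reference
  expect_identical(labeledPrototypes(ps),
                   labeledPrototypes(cellPrototypes(run$model, "cell_type")))
})

test_that("mapping rejects mismatched features or covariates", {
  run <- tinyRun()
  q <- run$atlas$query
  expect_error(mapQuery(run$model, q[1:10, ]), "feature set")
  q2 <- ExpressionDataset(rawCells(q),
                          covariates = list(donor = covariateValues(q, "sample")),
                          cellIds = colnames(q), featureIds = rownames(q))
  expect_error(mapQuery(run$model, q2), "covariates")
})

test_that("a labeled query extends the reference with new-label prototypes", {
  run <- tinyRun()
  q <- run$atlas$query
  lab <- run$atlas$truth$query
  lab[lab == "type3"] <- "novelType"
  SummarizedExperiment::colData(q)$cell_type <- lab
  qm <- mapQuery(run$model, q, nEpochs = 12L)
  ps <- cellPrototypes(qm, "cell_type")
  refPs <- cellPrototypes(run$model, "cell_type")
  expect_true("novelType" %in% rownames(labeledPrototypes(ps)))
  # reference prototypes are kept frozen
  keep <- rownames(labeledPrototypes(refPs))
  expect_identical(labeledPrototypes(ps)[keep, ], labeledPrototypes(refPs)[keep, ])
  expect_true(any(trainingReport(qm)$prototype > 0))
})

test_that("latent means expose the expected shape and idempotence", {
  run <- tinyRun()
  z <- getLatent(run$atlas$query, run$qmodel)
  expect_equal(dim(z), c(ncol(run$atlas$query), modelConfig(run$qmodel)$latentDim))
  expect_identical(z, getLatent(run$atlas$query, run$qmodel))
})

test_that("query embeddings are trained while everything else stays frozen", {
  run <- tinyRun()
  emb <- embeddingMatrix(run$qmodel, "sample")
  qLev <- setdiff(rownames(emb), conditionLevels(run$model, "sample"))
  expect_gt(length(qLev), 0L)
  expect_true(all(is.finite(emb[qLev, ])))
  # training must improve the query reconstruction at some point
  rep <- trainingReport(run$qmodel)
  expect_lt(min(rep$recon), rep$recon[1])
})

test_that("integration mixes batches better than raw log1p-PCA space", {
  run <- tinyRun()
  z <- rbind(getLatent(run$atlas$reference, run$qmodel),
             getLatent(run$atlas$query, run$qmodel))
  batch <- c(covariateValues(run$atlas$reference, "sample"),
             covariateValues(run$atlas$query, "sample"))
  raw <- prcomp(log1p(rbind(rawCells(run$atlas$reference),
                            rawCells(run$atlas$query))), rank. = 10)$x
  expect_gt(batchMixingKnn(z, batch), batchMixingKnn(raw, batch))
})
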