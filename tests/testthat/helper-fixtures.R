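# Shared fixtures. Trained models are memoized per session so several test
# files can reuse the same (deterministic) training runs.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Small atlas for fast unit tests.
tinySpec <- function(seed = 1L, ...) {
  args <- list(nCellTypes = 3L, nBatches = 3L, nQueryBatches = 1L,
               cellsPerBatch = 90L, nFeatures = 60L, typeSeparation = 1.2,
               batchEffectScale = 0.2, fractionUnlabeled = 0.15, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(syntheticAtlasSpec, args)
}

tinyConfig <- function(seed = 1L, ...) {
  args <- list(embeddingDim = 3L, latentDim = 6L, klAnnealEpochs = 10L,
               batchSize = 128L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(protoModelConfig, args)
}

# One trained tiny reference + mapped query, reused across test files.
tinyRun <- function() memo("tinyRun", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 5L))
  model <- buildReference(atlas$reference, tinyConfig(seed = 5L), nEpochs = 40L)
  qmodel <- mapQuery(model, atlas$query, nEpochs = 30L)
  list(atlas = atlas, model = model, qmodel = qmodel)
})

# Full-scale atlas run at the default study conditions (5 types, 4 reference
# + 2 query batches, ~4,000 cells, 200 features), per seed.
atlasRun <- function(seed, heldOut = integer(0)) {
  memo(sprintf("atlasRun_%d_%s", seed, paste(heldOut, collapse = "_")), {
    atlas <- generateSyntheticAtlas(
      syntheticAtlasSpec(heldOutTypes = heldOut, seed = seed))
    model <- buildReference(atlas$reference, protoModelConfig(seed = seed),
                            nEpochs = 100L)
    qmodel <- mapQuery(model, atlas$query, nEpochs = 100L)
    list(atlas = atlas, model = model, qmodel = qmodel)
  })
}

rawCells <- function(ds) t(as.matrix(SummarizedExperiment::assay(ds, "counts")))

# Independent brute-force Minkowski distance used as oracle in several files.
bruteMinkowski <- function(a, b, ord) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])^ord
  s^(1 / ord)
}
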