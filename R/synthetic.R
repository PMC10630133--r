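#' Specification for a synthetic multi-batch atlas
#'
#' Defines the generative conditions for synthetic count data emulating a
#' multi-batch single-cell atlas: a shared baseline log-mean per feature,
#' additive per-type log-space signatures, additive per-batch log-space
#' technical shifts (optionally organized into cohorts sharing a shift
#' direction), and negative-binomial sampling noise. Batches are partitioned
#' into reference and query; held-out cell types occur only in query
#' batches, mimicking novel populations.
#'
#' @param nCellTypes,nBatches,cellsPerBatch,nFeatures Atlas dimensions.
#' @param nQueryBatches How many of the `nBatches` batches form the query.
#' @param batchEffectScale Standard deviation (log space) of the per-batch
#'   technical shift added to every feature.
#' @param typeSeparation Standard deviation (log space) of per-type feature
#'   signatures; larger values separate cell types more strongly.
#' @param dispersion Negative-binomial inverse-dispersion (size); variance
#'   is `mu + mu^2 / dispersion`.
#' @param fractionUnlabeled Fraction of reference cells whose annotation is
#'   replaced by the unlabeled sentinel.
#' @param heldOutTypes Integer indices (1-based) of cell types absent from
#'   the reference and present only in the query.
#' @param heldOutFraction Expected fraction of query cells drawn from
#'   held-out types. Novel populations entering a mapped query are
#'   typically rare relative to the shared types; the default keeps them
#'   below the tenth of cells that a 90% uncertainty quantile can flag.
#' @param nCohorts When `> 1`, batch shifts are drawn around one of
#'   `nCohorts` shared shift directions (assigned round-robin across
#'   batches), emulating cohort-level technical structure.
#' @param seed Integer seed; the generator is a pure function of this spec.
#' @return A validated spec (list with class `"SyntheticAtlasSpec"`).
#' @seealso [generateSyntheticAtlas()]
#' @export
syntheticAtlasSpec <- function(nCellTypes = 5L, nBatches = 6L,
                               nQueryBatches = 2L, cellsPerBatch = 660L,
                               nFeatures = 200L, batchEffectScale = 0.2,
                               typeSeparation = 1.0, dispersion = 2.0,
                               fractionUnlabeled = 0.1,
                               heldOutTypes = integer(0),
                               heldOutFraction = 0.08, nCohorts = 1L,
                               seed = 1L) {
  spec <- list(nCellTypes = as.integer(nCellTypes),
               nBatches = as.integer(nBatches),
               nQueryBatches = as.integer(nQueryBatches),
               cellsPerBatch = as.integer(cellsPerBatch),
               nFeatures = as.integer(nFeatures),
               batchEffectScale = batchEffectScale,
               typeSeparation = typeSeparation,
               dispersion = dispersion,
               fractionUnlabeled = fractionUnlabeled,
               heldOutTypes = as.integer(heldOutTypes),
               heldOutFraction = heldOutFraction,
               nCohorts = as.integer(nCohorts),
               seed = as.integer(seed))
  counts <- c("nCellTypes", "nBatches", "cellsPerBatch", "nFeatures")
  for (f in counts)
    if (spec[[f]] < 1L) .stopf("%s must be >= 1", f)
  if (spec$nQueryBatches < 0L || spec$nQueryBatches >= spec$nBatches)
    .stopf("nQueryBatches must be in [0, nBatches)")
  if (spec$batchEffectScale < 0 || spec$typeSeparation < 0)
    .stopf("batchEffectScale and typeSeparation must be non-negative")
  if (spec$dispersion <= 0) .stopf("dispersion must be positive")
  if (spec$fractionUnlabeled < 0 || spec$fractionUnlabeled > 1)
    .stopf("fractionUnlabeled must be in [0, 1]")
  if (spec$heldOutFraction < 0 || spec$heldOutFraction > 1)
    .stopf("heldOutFraction must be in [0, 1]")
  if (length(spec$heldOutTypes)) {
    if (any(spec$heldOutTypes < 1L | spec$heldOutTypes > spec$nCellTypes))
      .stopf("heldOutTypes must be indices in 1..nCellTypes")
    if (length(unique(spec$heldOutTypes)) >= spec$nCellTypes)
      .stopf("held-out types would exhaust all query types")
  }
  class(spec) <- "SyntheticAtlasSpec"
  spec
}

#' Generate a synthetic multi-batch atlas
#'
#' Draws counts `x_cg ~ NB(mu = exp(base_g + type_tg + shift_bg), size =
#' dispersion)` where `base_g ~ N(log 3, 0.7)` is the shared feature
#' baseline, `type_tg ~ N(0, typeSeparation^2)` the cell-type signature and
#' `shift_bg` the per-batch technical shift (`N(0, batchEffectScale^2)`, or
#' cohort-direction plus noise when `nCohorts > 1`). Cell types are drawn
#' uniformly per batch; held-out types are excluded from reference batches.
#' Output is bitwise reproducible from `spec$seed`.
#'
#' @param spec A [syntheticAtlasSpec()].
#' @return A list with elements `reference` and `query` (both
#'   [ExpressionDataset-class] with covariate `"sample"`, extra colData
#'   column `"cohort"`, and annotation `"cell_type"`; query annotations are
#'   entirely unlabeled) and `truth` (list of per-cell true type labels for
#'   both splits).
#' @examples
#' atlas <- generateSyntheticAtlas(syntheticAtlasSpec(
#'   nBatches = 3, nQueryBatches = 1, cellsPerBatch = 50, nFeatures = 40))
#' table(covariateValues(atlas$reference, "sample"))
#' @export
generateSyntheticAtlas <- function(spec) {
  stopifnot(inherits(spec, "SyntheticAtlasSpec"))
  .withSeed(spec$seed, {
    G <- spec$nFeatures
    Tn <- spec$nCellTypes
    B <- spec$nBatches
    base <- stats::rnorm(G, log(3), 0.7)
    typeEff <- matrix(stats::rnorm(Tn * G, 0, spec$typeSeparation), Tn, G)
    cohortOf <- ((seq_len(B) - 1L) %% spec$nCohorts) + 1L
    if (spec$nCohorts > 1L) {
      # batches of a cohort share one shift direction; per-batch magnitude
      # jitter keeps individual batches distinguishable
      dirs <- matrix(stats::rnorm(spec$nCohorts * G), spec$nCohorts, G)
      dirs <- dirs / sqrt(rowMeans(dirs^2))     # unit per-feature RMS
      mag <- stats::runif(B, 0.7, 1.3)
      shift <- (spec$batchEffectScale * mag) * dirs[cohortOf, , drop = FALSE]
    } else {
      shift <- matrix(stats::rnorm(B * G, 0, spec$batchEffectScale), B, G)
    }
    refBatches <- seq_len(B - spec$nQueryBatches)
    refTypes <- setdiff(seq_len(Tn), spec$heldOutTypes)
    n <- B * spec$cellsPerBatch
    batch <- rep(seq_len(B), each = spec$cellsPerBatch)
    type <- integer(n)
    held <- spec$heldOutTypes
    draw <- function(pool, m) pool[sample.int(length(pool), m, replace = TRUE)]
    for (b in seq_len(B)) {
      i <- which(batch == b)
      if (b %in% refBatches || !length(held)) {
        type[i] <- draw(refTypes, length(i))
      } else {
        novel <- stats::runif(length(i)) < spec$heldOutFraction
        type[i[!novel]] <- draw(refTypes, sum(!novel))
        type[i[novel]] <- draw(held, sum(novel))
      }
    }
    logmu <- matrix(base, n, G, byrow = TRUE) +
      typeEff[type, , drop = FALSE] + shift[batch, , drop = FALSE]
    counts <- matrix(stats::rnbinom(n * G, mu = exp(logmu),
                                    size = spec$dispersion), n, G)
    batchNames <- sprintf("batch%02d", batch)
    typeNames <- sprintf("type%d", type)
    cohortNames <- sprintf("cohort%d", cohortOf[batch])
    cellIds <- sprintf("cell%05d", seq_len(n))
    featureIds <- sprintf("gene%04d", seq_len(G))
    isRef <- batch %in% refBatches
    labels <- typeNames
    refIdx <- which(isRef)
    nHide <- round(spec$fractionUnlabeled * length(refIdx))
    if (nHide > 0L)
      labels[sample(refIdx, nHide)] <- .UNLABELED
    mkds <- function(idx, lab) {
      ds <- ExpressionDataset(
        Matrix::Matrix(counts[idx, , drop = FALSE], sparse = TRUE),
        covariates = list(sample = batchNames[idx]),
        annotations = list(cell_type = lab),
        cellIds = cellIds[idx], featureIds = featureIds)
      colData(ds)$cohort <- cohortNames[idx]
      metadata(ds)$batchCohort <- stats::setNames(
        sprintf("cohort%d", cohortOf), sprintf("batch%02d", seq_len(B)))
      ds
    }
    list(reference = mkds(refIdx, labels[refIdx]),
         query = if (any(!isRef))
           mkds(which(!isRef), rep(.UNLABELED, sum(!isRef))),
         truth = list(reference = typeNames[refIdx],
                      query = typeNames[!isRef]))
  })
}
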