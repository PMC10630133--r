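#' @include utils.R AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData colData<- rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Container for multi-batch single-cell count data
#'
#' `ExpressionDataset` extends
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment] with
#' bookkeeping for the two kinds of per-cell metadata the integration model
#' consumes: *condition covariates* (categorical batch descriptors such as
#' sample or study, always fully observed) and *annotations* (cell-type
#' labels, possibly partial, with missing entries marked by a sentinel
#' token). The `"counts"` assay holds raw non-negative integer counts with
#' features as rows and cells as columns, as is conventional for
#' Bioconductor containers; user-facing constructors and readers accept
#' cells-by-features input and transpose.
#'
#' @slot covariateKeys Character vector naming the colData columns holding
#'   condition covariates, in declaration order (the order in which their
#'   embeddings are concatenated to the model input).
#' @slot annotationKeys Character vector naming the colData columns holding
#'   cell annotations, in declaration order (coarse to fine).
#' @slot unlabeledToken Single string; the sentinel marking unannotated
#'   cells.
#'
#' @seealso [ExpressionDataset()] for the constructor,
#'   [readExpressionDataset()] for file input.
#' @export
setClass("ExpressionDataset",
  contains = "SingleCellExperiment",
  slots = c(
    covariateKeys = "character",
    annotationKeys = "character",
    unlabeledToken = "character"
  )
)

setValidity("ExpressionDataset", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "an assay named 'counts' is required")
  else {
    bad <- .checkCounts(assay(object, "counts"))
    if (!is.null(bad)) msgs <- c(msgs, bad)
  }
  if (length(object@unlabeledToken) != 1L || is.na(object@unlabeledToken))
    msgs <- c(msgs, "unlabeledToken must be a single string")
  cd <- colData(object)
  for (key in object@covariateKeys) {
    if (!key %in% colnames(cd)) {
      msgs <- c(msgs, sprintf("covariate '%s' not found in colData", key))
      next
    }
    v <- cd[[key]]
    if (anyNA(v)) msgs <- c(msgs, sprintf("covariate '%s' contains NA", key))
    if (length(unique(v)) < 1L)
      msgs <- c(msgs, sprintf("covariate '%s' must have at least one level", key))
  }
  for (key in object@annotationKeys) {
    if (!key %in% colnames(cd))
      msgs <- c(msgs, sprintf("annotation '%s' not found in colData", key))
    else if (anyNA(cd[[key]]))
      msgs <- c(msgs, sprintf("annotation '%s' contains NA; use the unlabeled token instead", key))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param counts Cells-by-features matrix of raw non-negative integer counts
#'   (base or sparse `Matrix`); it is stored transposed, features-by-cells.
#' @param covariates Named list or data.frame of per-cell categorical
#'   vectors (length = number of cells), in declaration order.
#' @param annotations Named list or data.frame of per-cell label vectors;
#'   entries equal to `unlabeled` mark unannotated cells.
#' @param cellIds,featureIds Optional identifier vectors; defaults are taken
#'   from `dimnames(counts)` or generated.
#' @param unlabeled Sentinel string for missing annotations.
#'
#' @return A validated [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rpois(12, 3), nrow = 3)
#' ds <- ExpressionDataset(m, covariates = list(sample = c("a", "a", "b")))
#' librarySize(ds)
#' @export
ExpressionDataset <- function(counts, covariates = list(), annotations = list(),
                              cellIds = NULL, featureIds = NULL,
                              unlabeled = .UNLABELED) {
  if (is.null(cellIds)) {
    cellIds <- rownames(counts)
    if (is.null(cellIds)) cellIds <- sprintf("cell%04d", seq_len(nrow(counts)))
  }
  if (is.null(featureIds)) {
    featureIds <- colnames(counts)
    if (is.null(featureIds)) featureIds <- sprintf("feature%04d", seq_len(ncol(counts)))
  }
  covariates <- as.list(covariates)
  annotations <- as.list(annotations)
  for (nm in names(covariates)) covariates[[nm]] <- as.character(covariates[[nm]])
  for (nm in names(annotations)) annotations[[nm]] <- as.character(annotations[[nm]])
  lens <- vapply(c(covariates, annotations), length, integer(1L))
  if (any(lens != nrow(counts)))
    .stopf("every covariate/annotation vector must have length %d (cells)", nrow(counts))
  cd <- DataFrame(c(covariates, annotations), row.names = cellIds)
  if (!ncol(cd)) cd <- DataFrame(row.names = cellIds)
  m <- Matrix::t(counts)
  dimnames(m) <- list(featureIds, cellIds)
  sce <- SingleCellExperiment(assays = list(counts = m), colData = cd)
  new("ExpressionDataset", sce,
      covariateKeys = names(covariates) %||% character(),
      annotationKeys = names(annotations) %||% character(),
      unlabeledToken = unlabeled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname scProto-accessors
#' @export
setMethod("covariateKeys", "ExpressionDataset", function(x) x@covariateKeys)

#' @rdname scProto-accessors
#' @export
setMethod("annotationKeys", "ExpressionDataset", function(x) x@annotationKeys)

#' @rdname scProto-accessors
#' @export
setMethod("unlabeledToken", "ExpressionDataset", function(x) x@unlabeledToken)

#' @rdname scProto-accessors
#' @export
setMethod("librarySize", "ExpressionDataset", function(x)
  Matrix::colSums(assay(x, "counts")))

#' @rdname scProto-accessors
#' @param key Covariate or annotation name.
#' @export
setMethod("covariateValues", "ExpressionDataset", function(x, key) {
  if (!key %in% x@covariateKeys)
    .stopf("unknown covariate '%s' (have: %s)", key,
           paste(x@covariateKeys, collapse = ", "))
  as.character(colData(x)[[key]])
})

#' @rdname scProto-accessors
#' @export
setMethod("annotationValues", "ExpressionDataset", function(x, key) {
  if (!key %in% x@annotationKeys)
    .stopf("unknown annotation '%s' (have: %s)", key,
           paste(x@annotationKeys, collapse = ", "))
  as.character(colData(x)[[key]])
})

setMethod("show", "ExpressionDataset", function(object) {
  callNextMethod()
  cat("covariates(", length(object@covariateKeys), "): ",
      paste(object@covariateKeys, collapse = " "), "\n", sep = "")
  cat("annotations(", length(object@annotationKeys), "): ",
      paste(object@annotationKeys, collapse = " "), "\n", sep = "")
  cat("unlabeled token: '", object@unlabeledToken, "'\n", sep = "")
})

#' Latent-space prototypes for one annotation level
#'
#' A `PrototypeSet` stores the per-label mean latent vectors ("prototypes")
#' of cells sharing a cell-type label at one annotation level, together with
#' prototypes of Louvain clusters of unlabeled cells. Labeled prototypes
#' drive the supervised pull-in loss and nearest-prototype label transfer;
#' unlabeled prototypes are reference points for downstream exploration only
#' and never enter the loss.
#'
#' @slot level Annotation level name.
#' @slot labeled Numeric matrix, labels x latent dimensions.
#' @slot unlabeled Numeric matrix, cluster ids x latent dimensions.
#' @slot provenance `"reference"` or `"query"`.
#' @export
setClass("PrototypeSet",
  slots = c(level = "character", labeled = "matrix",
            unlabeled = "matrix", provenance = "character"))

setValidity("PrototypeSet", function(object) {
  msgs <- character()
  if (nrow(object@labeled) && nrow(object@unlabeled) &&
      ncol(object@labeled) != ncol(object@unlabeled))
    msgs <- c(msgs, "labeled and unlabeled prototypes must share the latent dimension")
  if (length(intersect(rownames(object@labeled), rownames(object@unlabeled))))
    msgs <- c(msgs, "labeled and unlabeled key spaces must be disjoint")
  if (!object@provenance %in% c("reference", "query"))
    msgs <- c(msgs, "provenance must be 'reference' or 'query'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PrototypeSet
#'
#' @param level Annotation level name.
#' @param labeled,unlabeled Matrices with one prototype per row (rownames =
#'   labels / cluster ids); either may be empty.
#' @param provenance `"reference"` or `"query"`.
#' @return A [PrototypeSet-class].
#' @export
PrototypeSet <- function(level, labeled = NULL, unlabeled = NULL,
                         provenance = "reference") {
  D <- if (!is.null(labeled)) ncol(labeled) else if (!is.null(unlabeled)) ncol(unlabeled) else 0L
  if (is.null(labeled)) labeled <- matrix(0, 0L, D)
  if (is.null(unlabeled)) unlabeled <- matrix(0, 0L, D)
  new("PrototypeSet", level = level, labeled = labeled,
      unlabeled = unlabeled, provenance = provenance)
}

#' @rdname scProto-accessors
#' @export
setMethod("prototypeLevel", "PrototypeSet", function(x) x@level)

#' @rdname scProto-accessors
#' @export
setMethod("labeledPrototypes", "PrototypeSet", function(x) x@labeled)

#' @rdname scProto-accessors
#' @export
setMethod("unlabeledPrototypes", "PrototypeSet", function(x) x@unlabeled)

#' @rdname scProto-accessors
#' @export
setMethod("latentDim", "PrototypeSet", function(x)
  if (nrow(x@labeled)) ncol(x@labeled) else ncol(x@unlabeled))

setMethod("show", "PrototypeSet", function(object) {
  cat("PrototypeSet (level '", object@level, "', ", object@provenance, ")\n",
      sep = "")
  cat("  labeled:   ", nrow(object@labeled), " prototypes in ",
      ncol(object@labeled), " dims\n", sep = "")
  cat("  unlabeled: ", nrow(object@unlabeled), " cluster prototypes\n", sep = "")
})

#' Trained conditional-VAE model state
#'
#' A `ProtoModel` bundles everything needed to reproduce a forward pass and
#' to continue training: encoder/decoder weights, the per-covariate
#' condition-embedding tables, stored prototypes, the configuration, the
#' freeze mask used during query mapping, and the per-epoch training report.
#'
#' @slot config Model configuration list (see [protoModelConfig()]).
#' @slot params Named list of parameter matrices; condition-embedding tables
#'   are entries named `emb.<covariate>` with one row per condition level.
#' @slot covariateKeys Covariate names in declaration (concatenation) order.
#' @slot annotationKeys Annotation level names seen during training.
#' @slot featureIds Feature identifiers the model was trained on.
#' @slot frozenParams Names of parameter matrices excluded from updates.
#' @slot frozenConditions Per covariate, the condition names whose embedding
#'   rows are frozen (the reference conditions, after query mapping).
#' @slot prototypes Named list of [PrototypeSet-class] objects, one per
#'   annotation level.
#' @slot report data.frame with one row per training epoch.
#' @slot version Serialization format version string.
#' @export
setClass("ProtoModel",
  slots = c(config = "list", params = "list", covariateKeys = "character",
            annotationKeys = "character", featureIds = "character",
            frozenParams = "character", frozenConditions = "list",
            prototypes = "list", report = "data.frame", version = "character"))

setValidity("ProtoModel", function(object) {
  msgs <- character()
  for (key in object@covariateKeys) {
    nm <- paste0("emb.", key)
    if (!nm %in% names(object@params))
      msgs <- c(msgs, sprintf("missing embedding table '%s'", nm))
    else if (is.null(rownames(object@params[[nm]])))
      msgs <- c(msgs, sprintf("embedding table '%s' must have condition rownames", nm))
    else if (anyDuplicated(rownames(object@params[[nm]])))
      msgs <- c(msgs, sprintf("duplicate condition names in '%s'", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname scProto-accessors
#' @export
setMethod("covariateKeys", "ProtoModel", function(x) x@covariateKeys)

#' @rdname scProto-accessors
#' @export
setMethod("annotationKeys", "ProtoModel", function(x) x@annotationKeys)

#' @rdname scProto-accessors
#' @param covariate Covariate name.
#' @export
setMethod("embeddingMatrix", "ProtoModel", function(x, covariate) {
  nm <- paste0("emb.", covariate)
  if (!nm %in% names(x@params))
    .stopf("unknown covariate '%s' (have: %s)", covariate,
           paste(x@covariateKeys, collapse = ", "))
  x@params[[nm]]
})

#' @rdname scProto-accessors
#' @export
setMethod("conditionLevels", "ProtoModel", function(x, covariate)
  rownames(embeddingMatrix(x, covariate)))

#' @rdname scProto-accessors
#' @export
setMethod("modelConfig", "ProtoModel", function(x) x@config)

#' @rdname scProto-accessors
#' @export
setMethod("trainingReport", "ProtoModel", function(x) x@report)

#' @rdname scProto-accessors
#' @param level Annotation level name.
#' @export
setMethod("cellPrototypes", "ProtoModel", function(x, level) {
  if (missing(level)) return(x@prototypes)
  if (!level %in% names(x@prototypes))
    .stopf("no prototypes stored for level '%s'", level)
  x@prototypes[[level]]
})

#' @rdname scProto-accessors
#' @export
setMethod("latentDim", "ProtoModel", function(x) x@config$latentDim)

setMethod("show", "ProtoModel", function(object) {
  cfg <- object@config
  cat("ProtoModel (", cfg$likelihood, " likelihood)\n", sep = "")
  cat("  features: ", length(object@featureIds),
      "  latent dim: ", cfg$latentDim, "\n", sep = "")
  for (key in object@covariateKeys) {
    emb <- embeddingMatrix(object, key)
    frozen <- length(object@frozenConditions[[key]] %||% character())
    cat("  covariate '", key, "': ", nrow(emb), " conditions x E=", ncol(emb),
        if (frozen) sprintf(" (%d frozen)", frozen), "\n", sep = "")
  }
  for (lv in names(object@prototypes)) {
    ps <- object@prototypes[[lv]]
    cat("  prototypes '", lv, "': ", nrow(ps@labeled), " labeled, ",
        nrow(ps@unlabeled), " unlabeled\n", sep = "")
  }
  if (nrow(object@report))
    cat("  trained for ", nrow(object@report), " epochs (",
        sum(object@report$phase == "pretrain"), " pretrain)\n", sep = "")
})
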