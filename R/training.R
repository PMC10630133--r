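# Reference building and frozen-weight query mapping.

# Dataset -> training arrays, using an explicit embedding vocabulary.
.trainData <- function(ds, covKeys, annKeys, embTables) {
  X <- t(.denseMatrix(assay(ds, "counts")))
  condIdx <- list()
  for (key in covKeys) {
    vals <- covariateValues(ds, key)
    idx <- match(vals, rownames(embTables[[key]]))
    if (anyNA(idx))
      .stopf("covariate '%s' contains condition(s) unknown to the model: %s",
             key, paste(unique(vals[is.na(idx)]), collapse = ", "))
    condIdx[[key]] <- idx
  }
  labels <- stats::setNames(lapply(annKeys, function(k) annotationValues(ds, k)),
                            annKeys)
  list(X = X, Xlog = log1p(X), lib = pmax(rowSums(X), 1),
       condIdx = condIdx, labels = labels)
}

# One optimization phase over `epochs` epochs. `protoFun(params)` returns
# the per-level prototype matrices to use for the epoch (NULL during
# pretraining). Returns updated params/opt state and report rows.
.trainPhase <- function(params, cfg, data, epochs, globalEpoch, phase, eta,
                        protoFun, frozenParams, frozenEmbRows, optState) {
  n <- nrow(data$X)
  D <- cfg$latentDim
  rows <- vector("list", epochs)
  for (e in seq_len(epochs)) {
    t0 <- proc.time()[["elapsed"]]
    globalEpoch <- globalEpoch + 1L
    klw <- if (cfg$klAnnealEpochs > 0L) min(1, globalEpoch / cfg$klAnnealEpochs) else 1
    protos <- if (is.null(protoFun)) NULL else protoFun(params)
    perm <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    acc <- c(recon = 0, kl = 0, proto = 0)
    for (s in starts) {
      idx <- perm[s:min(s + cfg$batchSize - 1L, n)]
      nb <- length(idx)
      eps <- matrix(stats::rnorm(nb * D), nb, D)
      lg <- .lossGrads(params, cfg,
                       data$X[idx, , drop = FALSE],
                       data$Xlog[idx, , drop = FALSE],
                       data$lib[idx],
                       lapply(data$condIdx, `[`, idx),
                       eps, klw,
                       protos = protos,
                       labels = lapply(data$labels, `[`, idx),
                       eta = eta)
      if (!is.finite(lg$total))
        .stopf("non-finite loss at epoch %d (phase %s); training diverged",
               globalEpoch, phase)
      st <- .adamStep(params, lg$grads, optState, cfg$learningRate,
                      frozenParams, frozenEmbRows)
      params <- st$params
      optState <- st$state
      acc <- acc + nb * c(lg$recon, lg$kl, lg$proto)
    }
    acc <- acc / n
    rows[[e]] <- data.frame(epoch = globalEpoch, phase = phase,
                            recon = acc[["recon"]], kl = acc[["kl"]],
                            prototype = acc[["proto"]], klWeight = klw,
                            seconds = proc.time()[["elapsed"]] - t0)
  }
  list(params = params, optState = optState,
       report = do.call(rbind, rows), globalEpoch = globalEpoch)
}

# Inference-mode latent means for full training data.
.latentMeans <- function(params, cfg, data) {
  .forwardPass(params, cfg, data$Xlog, data$condIdx, data$lib)$mu
}

# Per-level labeled prototype matrices from latent means.
.labeledProtoMatrices <- function(Mu, labels, unlabeled) {
  out <- list()
  for (lv in names(labels)) {
    lab <- labels[[lv]]
    keep <- lab != unlabeled
    if (!any(keep)) next
    m <- rowsum(Mu[keep, , drop = FALSE], group = lab[keep])
    m <- m / as.vector(table(lab[keep])[rownames(m)])
    out[[lv]] <- m[order(rownames(m)), , drop = FALSE]
  }
  out
}

# Mean latent per fixed cluster assignment (ids from .louvainClusters).
.clusterProtoMatrix <- function(Mu, assign) {
  m <- rowsum(Mu, group = assign)
  m <- m / as.vector(table(assign)[rownames(m)])
  rownames(m) <- paste0("cluster", rownames(m))
  m[order(rownames(m)), , drop = FALSE]
}

#' Build an integrated reference model
#'
#' Two-stage training on the reference dataset. Stage one (pretraining)
#' optimizes the variational objective alone, with the KL weight annealed
#' linearly over the first `klAnnealEpochs` epochs; condition embeddings are
#' trained jointly with the network by backpropagation. Stage two
#' (fine-tuning, the last `1 - pretrainFraction` of epochs) initializes
#' cell-type prototypes as per-label latent means — recomputed at the start
#' of every fine-tuning epoch and held fixed within it — and adds the
#' prototype pull-in loss with weight `prototypeLossWeight`. Cells unlabeled
#' at a level are Louvain-clustered once at the start of fine-tuning; their
#' cluster prototypes are stored with the model but never enter the loss.
#'
#' @param ds Reference [ExpressionDataset-class]; needs at least one
#'   covariate, and labeled cells unless `prototypeLossWeight = 0`.
#' @param config A [protoModelConfig()].
#' @param nEpochs Total epochs (pretrain + fine-tune).
#' @return A trained [ProtoModel-class]; `trainingReport(model)` holds the
#'   per-epoch loss components.
#' @seealso [mapQuery()], [getLatent()]
#' @export
buildReference <- function(ds, config = protoModelConfig(), nEpochs = 100L) {
  if (!length(covariateKeys(ds)))
    .stopf("the reference dataset must declare at least one condition covariate")
  cfg <- unclass(config)
  cfg$covariateKeys <- covariateKeys(ds)
  cfg$annotationKeys <- annotationKeys(ds)
  cfg$unlabeled <- unlabeledToken(ds)
  covLevels <- stats::setNames(
    lapply(cfg$covariateKeys, function(k) sort(unique(covariateValues(ds, k)))),
    cfg$covariateKeys)
  .withSeed(cfg$seed, {
    params <- .initParams(cfg, nrow(ds), covLevels)
    embTables <- stats::setNames(
      lapply(cfg$covariateKeys, function(k) params[[paste0("emb.", k)]]),
      cfg$covariateKeys)
    data <- .trainData(ds, cfg$covariateKeys, cfg$annotationKeys, embTables)
    nPre <- ceiling(cfg$pretrainFraction * nEpochs)
    nFt <- nEpochs - nPre
    optState <- .adamInit(params)

    ph1 <- .trainPhase(params, cfg, data, nPre, 0L, "pretrain", 0,
                       NULL, character(), list(), optState)
    params <- ph1$params
    report <- ph1$report

    eta <- cfg$prototypeLossWeight
    anyLabeled <- any(vapply(data$labels, function(l) any(l != cfg$unlabeled),
                             logical(1L)))
    if (eta > 0 && length(data$labels) && !anyLabeled) {
      .warnf("no labeled cells at any annotation level; fine-tuning without the prototype loss")
      eta <- 0
    }
    if (!length(data$labels)) eta <- 0

    unlabAssign <- list()
    if (nFt > 0L && length(data$labels)) {
      Mu <- .latentMeans(params, cfg, data)
      for (lv in names(data$labels)) {
        u <- which(data$labels[[lv]] == cfg$unlabeled)
        if (length(u) > 1L)
          unlabAssign[[lv]] <- list(cells = u,
                                    cl = .louvainClusters(Mu[u, , drop = FALSE]))
      }
    }
    if (nFt > 0L) {
      protoFun <- if (eta > 0)
        function(p) .labeledProtoMatrices(.latentMeans(p, cfg, data),
                                          data$labels, cfg$unlabeled)
      else NULL
      ph2 <- .trainPhase(params, cfg, data, nFt, ph1$globalEpoch, "finetune",
                         eta, protoFun, character(), list(), ph1$optState)
      params <- ph2$params
      report <- rbind(report, ph2$report)
    }

    protoSets <- list()
    if (length(data$labels)) {
      Mu <- .latentMeans(params, cfg, data)
      for (lv in names(data$labels)) {
        lab <- .labeledProtoMatrices(Mu, data$labels[lv], cfg$unlabeled)[[lv]]
        unl <- if (!is.null(unlabAssign[[lv]]))
          .clusterProtoMatrix(Mu[unlabAssign[[lv]]$cells, , drop = FALSE],
                              unlabAssign[[lv]]$cl)
        else NULL
        protoSets[[lv]] <- PrototypeSet(lv, labeled = lab, unlabeled = unl,
                                        provenance = "reference")
      }
    }
    rownames(report) <- NULL
    new("ProtoModel", config = cfg, params = params,
        covariateKeys = cfg$covariateKeys, annotationKeys = cfg$annotationKeys,
        featureIds = rownames(ds), frozenParams = character(),
        frozenConditions = stats::setNames(
          vector("list", length(cfg$covariateKeys)), cfg$covariateKeys),
        prototypes = protoSets, report = report, version = "1")
  })
}

#' Map a query dataset onto a trained reference
#'
#' Freezes every network weight and every reference condition-embedding row,
#' appends freshly initialized embedding rows for the query's conditions,
#' and trains only those rows on the query data (same two-stage schedule;
#' the KL weight stays at its final annealed value). If the query carries
#' labeled cells, fine-tuning applies the prototype loss using the frozen
#' reference prototypes for labels the reference knows and new prototypes
#' (recomputed per epoch from query cells) for novel labels, extending the
#' reference without retraining it. Unlabeled query cells are clustered and
#' stored as query unlabeled prototypes. A fully unlabeled query reduces the
#' objective to the plain variational loss.
#'
#' @param model A reference [ProtoModel-class] (left untouched).
#' @param query Query [ExpressionDataset-class] with the same features and
#'   covariate structure as the reference.
#' @param nEpochs Total epochs for query training.
#' @param seed Seed for embedding initialization, shuffling and sampling;
#'   defaults to the model seed plus one.
#' @return A new [ProtoModel-class] containing the extended embedding
#'   tables, merged prototypes, and the query training report.
#' @export
mapQuery <- function(model, query, nEpochs = 100L, seed = NULL) {
  cfg <- model@config
  if (!identical(rownames(query), model@featureIds)) {
    miss <- setdiff(model@featureIds, rownames(query))
    .stopf("query feature set does not match the reference%s",
           if (length(miss)) paste0("; missing features: ",
             paste(utils::head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) ", ..." else "") else "")
  }
  if (!identical(covariateKeys(query), model@covariateKeys))
    .stopf("query must declare the same condition covariates as the reference (%s)",
           paste(model@covariateKeys, collapse = ", "))
  if (is.null(seed)) seed <- cfg$seed + 1L
  .withSeed(seed, {
    params <- model@params
    frozenEmbRows <- list()
    for (key in model@covariateKeys) {
      nm <- paste0("emb.", key)
      refLev <- rownames(params[[nm]])
      qLev <- sort(unique(covariateValues(query, key)))
      newLev <- setdiff(qLev, refLev)
      E <- ncol(params[[nm]])
      if (length(newLev)) {
        add <- matrix(stats::rnorm(length(newLev) * E, 0, 1 / sqrt(E)),
                      length(newLev), E, dimnames = list(newLev, NULL))
        params[[nm]] <- rbind(params[[nm]], add)
      }
      frozenEmbRows[[key]] <- seq_along(refLev)
    }
    embTables <- stats::setNames(
      lapply(model@covariateKeys, function(k) params[[paste0("emb.", k)]]),
      model@covariateKeys)
    annKeys <- intersect(cfg$annotationKeys, annotationKeys(query))
    data <- .trainData(query, model@covariateKeys, annKeys, embTables)
    frozenParams <- setdiff(names(params), paste0("emb.", model@covariateKeys))
    nPre <- ceiling(cfg$pretrainFraction * nEpochs)
    nFt <- nEpochs - nPre
    qcfg <- cfg
    qcfg$klAnnealEpochs <- 0L          # keep the mature KL weight of 1
    optState <- .adamInit(params)
    ph1 <- .trainPhase(params, qcfg, data, nPre, 0L, "pretrain", 0,
                       NULL, frozenParams, frozenEmbRows, optState)
    params <- ph1$params
    report <- ph1$report

    eta <- cfg$prototypeLossWeight
    refProtos <- lapply(model@prototypes, labeledPrototypes)
    anyLabeled <- any(vapply(data$labels, function(l) any(l != cfg$unlabeled),
                             logical(1L)))
    if (!length(data$labels) || !anyLabeled) eta <- 0

    unlabAssign <- list()
    if (nFt > 0L && length(data$labels)) {
      Mu <- .latentMeans(params, qcfg, data)
      for (lv in names(data$labels)) {
        u <- which(data$labels[[lv]] == cfg$unlabeled)
        if (length(u) > 1L)
          unlabAssign[[lv]] <- list(cells = u,
                                    cl = .louvainClusters(Mu[u, , drop = FALSE]))
      }
    }
    if (nFt > 0L) {
      protoFun <- if (eta > 0) {
        function(p) {
          Mu <- .latentMeans(p, qcfg, data)
          fresh <- .labeledProtoMatrices(Mu, data$labels, cfg$unlabeled)
          out <- list()
          for (lv in names(fresh)) {
            ref <- refProtos[[lv]]
            newLab <- setdiff(rownames(fresh[[lv]]), rownames(ref))
            out[[lv]] <- rbind(ref, fresh[[lv]][newLab, , drop = FALSE])
          }
          out
        }
      } else NULL
      ph2 <- .trainPhase(params, qcfg, data, nFt, ph1$globalEpoch, "finetune",
                         eta, protoFun, frozenParams, frozenEmbRows,
                         ph1$optState)
      params <- ph2$params
      report <- rbind(report, ph2$report)
    }

    protoSets <- model@prototypes
    if (length(data$labels)) {
      Mu <- .latentMeans(params, qcfg, data)
      for (lv in names(data$labels)) {
        refLab <- refProtos[[lv]]
        fresh <- .labeledProtoMatrices(Mu, data$labels[lv], cfg$unlabeled)[[lv]]
        newLab <- if (!is.null(fresh))
          fresh[setdiff(rownames(fresh), rownames(refLab)), , drop = FALSE]
        else NULL
        lab <- rbind(refLab, newLab)
        unl <- if (!is.null(unlabAssign[[lv]]))
          .clusterProtoMatrix(Mu[unlabAssign[[lv]]$cells, , drop = FALSE],
                              unlabAssign[[lv]]$cl)
        else NULL
        protoSets[[lv]] <- PrototypeSet(
          lv, labeled = if (!is.null(lab)) lab[order(rownames(lab)), , drop = FALSE],
          unlabeled = unl, provenance = "query")
      }
    }
    rownames(report) <- NULL
    frozenConditions <- stats::setNames(
      lapply(model@covariateKeys, function(k)
        rownames(model@params[[paste0("emb.", k)]])),
      model@covariateKeys)
    new("ProtoModel", config = cfg, params = params,
        covariateKeys = model@covariateKeys,
        annotationKeys = union(cfg$annotationKeys, annKeys),
        featureIds = model@featureIds,
        frozenParams = frozenParams, frozenConditions = frozenConditions,
        prototypes = protoSets, report = report, version = "1")
  })
}

#' Per-cell latent representation
#'
#' Convenience wrapper around [encodeCells()] returning the latent
#' coordinates used by all downstream analyses. `"mean"` mode (the
#' variational mean, deterministic) is what prototypes, label transfer and
#' integration metrics operate on.
#'
#' @param ds An [ExpressionDataset-class].
#' @param model A [ProtoModel-class].
#' @param mode `"mean"` or `"sample"`.
#' @return Cells-by-latent-dimensions matrix.
#' @export
getLatent <- function(ds, model, mode = c("mean", "sample")) {
  mode <- match.arg(mode)
  enc <- encodeCells(ds, model, mode)
  if (mode == "mean") enc$mean else enc$z
}
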