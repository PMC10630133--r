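#' Model configuration
#'
#' Collects the tunable hyperparameters of the conditional VAE. Defaults
#' follow common practice for count-data VAEs at atlas scale: Adam with
#' learning rate 0.001, a 0.9 pretrain/fine-tune epoch split, hidden width
#' set to the square root of the feature count, and a negative-binomial
#' likelihood (use `"poisson"` for scATAC-seq fragment counts).
#'
#' @param embeddingDim Condition-embedding dimension E (recycled across
#'   covariates when several are modeled).
#' @param latentDim Latent dimension D.
#' @param encoderDepth,decoderDepth Number of hidden layers.
#' @param hiddenWidth Hidden layer width, or `"auto"` for `round(sqrt(G))`.
#' @param likelihood `"nb"` (negative binomial) or `"poisson"`.
#' @param prototypeLossWeight Weight eta of the prototype pull-in loss
#'   during fine-tuning.
#' @param minkowskiP Order of the Minkowski distance (2 = Euclidean).
#' @param klAnnealEpochs Epochs over which the KL weight ramps linearly from
#'   0 to 1.
#' @param learningRate Adam learning rate.
#' @param pretrainFraction Fraction of total epochs spent in the
#'   unsupervised pretraining phase.
#' @param batchSize Minibatch size.
#' @param norm Hidden-layer normalization: `"layer"` or `"none"`.
#' @param seed Integer seed governing initialization, shuffling, sampling
#'   and clustering.
#' @return A config list (class `"ProtoModelConfig"`).
#' @export
protoModelConfig <- function(embeddingDim = 5L, latentDim = 10L,
                             encoderDepth = 1L, decoderDepth = 1L,
                             hiddenWidth = "auto",
                             likelihood = c("nb", "poisson"),
                             prototypeLossWeight = 1, minkowskiP = 2,
                             klAnnealEpochs = 20L, learningRate = 1e-3,
                             pretrainFraction = 0.9, batchSize = 256L,
                             norm = c("layer", "none"), seed = 1L) {
  likelihood <- match.arg(likelihood)
  norm <- match.arg(norm)
  stopifnot(embeddingDim >= 1, latentDim >= 1, encoderDepth >= 1,
            decoderDepth >= 1, prototypeLossWeight >= 0, minkowskiP > 0,
            learningRate > 0, pretrainFraction >= 0, pretrainFraction <= 1,
            batchSize >= 1)
  cfg <- list(embeddingDim = as.integer(embeddingDim),
              latentDim = as.integer(latentDim),
              encoderDepth = as.integer(encoderDepth),
              decoderDepth = as.integer(decoderDepth),
              hiddenWidth = hiddenWidth, likelihood = likelihood,
              prototypeLossWeight = prototypeLossWeight,
              minkowskiP = minkowskiP,
              klAnnealEpochs = as.integer(klAnnealEpochs),
              learningRate = learningRate,
              pretrainFraction = pretrainFraction,
              batchSize = as.integer(batchSize), norm = norm,
              seed = as.integer(seed))
  class(cfg) <- "ProtoModelConfig"
  cfg
}

# Integer condition indices into the embedding tables for every covariate;
# errors identify the covariate with the unknown condition.
.condIndex <- function(model, ds) {
  out <- list()
  for (key in model@covariateKeys) {
    vals <- covariateValues(ds, key)
    lev <- rownames(model@params[[paste0("emb.", key)]])
    idx <- match(vals, lev)
    if (anyNA(idx))
      .stopf("covariate '%s' contains condition(s) unknown to the model: %s",
             key, paste(unique(vals[is.na(idx)]), collapse = ", "))
    out[[key]] <- idx
  }
  out
}

# Model inputs from a dataset: raw counts (cells x features), the log1p
# encoder transform, library sizes and condition indices.
.modelInputs <- function(model, ds) {
  if (!identical(rownames(ds), model@featureIds))
    .stopf("feature set mismatch: dataset features do not match the %d model features%s",
           length(model@featureIds),
           { miss <- setdiff(model@featureIds, rownames(ds));
             if (length(miss)) paste0(" (missing: ",
               paste(utils::head(miss, 5L), collapse = ", "),
               if (length(miss) > 5L) ", ..." else "", ")") else "" })
  X <- t(.denseMatrix(assay(ds, "counts")))
  list(X = X, Xlog = log1p(X), lib = pmax(rowSums(X), 1),
       condIdx = .condIndex(model, ds))
}

#' Encode cells into the latent space
#'
#' Applies the input transform (log1p of counts), concatenates the condition
#' embedding of each covariate in declaration order, and runs the encoder.
#' In `"mean"` mode the returned sample `z` equals the variational mean and
#' the call is fully deterministic; `"sample"` mode draws one
#' reparameterized sample per cell.
#'
#' @param ds An [ExpressionDataset-class] with the model's feature set and
#'   covariates.
#' @param model A trained [ProtoModel-class].
#' @param mode `"mean"` or `"sample"`.
#' @return List with matrices `mean`, `logvar` and `z` (cells x latent
#'   dimensions).
#' @export
encodeCells <- function(ds, model, mode = c("mean", "sample")) {
  mode <- match.arg(mode)
  inp <- .modelInputs(model, ds)
  eps <- if (mode == "sample")
    matrix(stats::rnorm(ncol(ds) * model@config$latentDim),
           ncol(ds), model@config$latentDim)
  else NULL
  fw <- .forwardPass(model@params, model@config, inp$Xlog, inp$condIdx,
                     inp$lib, eps)
  rn <- colnames(ds)
  out <- list(mean = fw$mu, logvar = fw$lv, z = fw$z)
  for (nm in names(out)) rownames(out[[nm]]) <- rn
  out
}

#' Decode latent vectors into likelihood parameters
#'
#' Concatenates each latent vector with its condition embeddings and runs
#' the decoder. The decoder output is a per-cell simplex over features
#' (softmax) scaled by the library size, so negative-binomial means sum to
#' the library size per cell; the per-feature inverse-dispersion is a free
#' model parameter.
#'
#' @param z Cells-by-latent-dimensions matrix.
#' @param conditions Named list (one entry per model covariate, declaration
#'   order) of per-cell condition names.
#' @param librarySize Per-cell total counts used to scale the mean.
#' @param model A [ProtoModel-class].
#' @return For `"nb"`: list with `mean` (cells x features) and `size`
#'   (per-feature inverse-dispersion); for `"poisson"`: list with `rate`.
#' @export
decodeCells <- function(z, conditions, librarySize, model) {
  cfg <- model@config
  z <- as.matrix(z)
  if (ncol(z) != cfg$latentDim)
    .stopf("z must have %d columns (latent dim)", cfg$latentDim)
  condIdx <- list()
  for (key in model@covariateKeys) {
    vals <- as.character(conditions[[key]])
    if (is.null(conditions[[key]]))
      .stopf("conditions must include covariate '%s'", key)
    lev <- rownames(model@params[[paste0("emb.", key)]])
    idx <- match(vals, lev)
    if (anyNA(idx))
      .stopf("covariate '%s' contains condition(s) unknown to the model: %s",
             key, paste(unique(vals[is.na(idx)]), collapse = ", "))
    condIdx[[key]] <- idx
  }
  S <- .embBlock(model@params, model@covariateKeys, condIdx)
  Zin <- cbind(z, S)
  dec <- .mlpForward(model@params, "dec", cfg$decoderDepth, cfg$norm, Zin)
  O <- sweep(dec$H %*% model@params$Wout, 2L, model@params$cout, "+")
  P <- .rowSoftmax(O)
  rate <- P * librarySize
  colnames(rate) <- model@featureIds
  if (cfg$likelihood == "nb")
    list(mean = rate, size = stats::setNames(exp(model@params$ltheta),
                                             model@featureIds))
  else list(rate = rate)
}

#' Evaluate the variational objective on a dataset
#'
#' Deterministic evaluation (latent means, no sampling) of the loss:
#' mean reconstruction negative log-likelihood plus `klWeight` times the
#' mean KL divergence to the standard-normal prior.
#'
#' @param ds An [ExpressionDataset-class].
#' @param model A [ProtoModel-class].
#' @param klWeight KL weight in `[0, 1]`.
#' @return List with `total`, `recon` and `kl`.
#' @export
cvaeLoss <- function(ds, model, klWeight = 1) {
  inp <- .modelInputs(model, ds)
  fw <- .forwardPass(model@params, model@config, inp$Xlog, inp$condIdx, inp$lib)
  recon <- if (model@config$likelihood == "nb")
    mean(nbNegLogLikelihood(inp$X, fw$rate, fw$theta))
  else mean(poissonNegLogLikelihood(inp$X, fw$rate))
  kl <- mean(gaussianKL(fw$mu, fw$lv))
  total <- recon + klWeight * kl
  if (!is.finite(total))
    .stopf("non-finite loss (recon = %g, kl = %g); training diverged", recon, kl)
  list(total = total, recon = recon, kl = kl)
}

#' Count trainable parameters: condition embeddings vs one-hot encoding
#'
#' Counts the parameters that differ between the two ways of conditioning a
#' CVAE on N conditions, ignoring bias terms: with learnable embeddings of
#' dimension E the model owns the `E x N` embedding table plus input layers
#' `(G + E) x H_enc` and `(D + E) x H_dec`; with one-hot indicators the
#' input layers are `(G + N) x H_enc` and `(D + N) x H_dec`. The embedding
#' model is smaller exactly when `E < N * H / (N + H)` with
#' `H = H_enc + H_dec`.
#'
#' @param config A [protoModelConfig()].
#' @param nFeatures Input feature count G.
#' @param nConditions Number of conditions N.
#' @param mode `"embedding"` or `"onehot"`.
#' @return Parameter count (numeric).
#' @seealso [fewerParamsThanOneHot()]
#' @export
countTrainableParameters <- function(config, nFeatures, nConditions,
                                     mode = c("embedding", "onehot")) {
  mode <- match.arg(mode)
  H <- .hiddenWidth(config, nFeatures)
  E <- config$embeddingDim
  D <- config$latentDim
  if (mode == "embedding")
    E * nConditions + (nFeatures + E) * H + (D + E) * H
  else
    (nFeatures + nConditions) * H + (D + nConditions) * H
}

#' @rdname countTrainableParameters
#' @export
fewerParamsThanOneHot <- function(config, nFeatures, nConditions) {
  countTrainableParameters(config, nFeatures, nConditions, "embedding") <
    countTrainableParameters(config, nFeatures, nConditions, "onehot")
}

#' Save or load a trained model
#'
#' The full model state (parameters, configuration, condition vocabularies,
#' freeze masks, prototypes, training report) is serialized to a single
#' version-stamped archive; loading reproduces an identical forward pass.
#'
#' @param model A [ProtoModel-class].
#' @param path File path.
#' @return `loadProtoModel` returns the [ProtoModel-class];
#'   `saveProtoModel` invisibly returns `path`.
#' @export
saveProtoModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveProtoModel
#' @export
loadProtoModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "ProtoModel")) .stopf("'%s' does not hold a ProtoModel", path)
  model
}
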