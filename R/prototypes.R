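#' Minkowski distance
#'
#' `(sum |z - p|^order)^(1/order)`: Euclidean at order 2, Manhattan at
#' order 1.
#'
#' @param z,p Numeric vectors of equal length.
#' @param order Positive real order.
#' @return Non-negative scalar.
#' @examples
#' minkowskiDistance(c(0, 0), c(3, 4), 2)  # 5
#' minkowskiDistance(c(0, 0), c(3, 4), 1)  # 7
#' @export
minkowskiDistance <- function(z, p, order = 2) {
  if (length(z) != length(p))
    .stopf("z and p must have equal length (%d vs %d)", length(z), length(p))
  if (order <= 0) .stopf("order must be positive")
  sum(abs(z - p)^order)^(1 / order)
}

# All pairwise Minkowski distances between rows of Z and rows of P.
.minkowskiCross <- function(Z, P, order) {
  out <- matrix(0, nrow(Z), nrow(P), dimnames = list(rownames(Z), rownames(P)))
  for (j in seq_len(nrow(P)))
    out[, j] <- rowSums(abs(Z - rep(P[j, ], each = nrow(Z)))^order)^(1 / order)
  out
}

#' Compute labeled prototypes
#'
#' The prototype of a cell type is the arithmetic mean of the latent means
#' of all cells carrying that label; unlabeled cells are excluded. Labels
#' present in the vector but carried by no cell simply produce no prototype.
#'
#' @param latents Cells-by-dimensions matrix of latent means.
#' @param annotations Per-cell labels; entries equal to `unlabeled` are
#'   skipped.
#' @param level Annotation level name recorded in the result.
#' @param unlabeled Sentinel marking unannotated cells.
#' @param provenance `"reference"` or `"query"`.
#' @return A [PrototypeSet-class] with one labeled prototype per observed
#'   label.
#' @export
computeLabeledPrototypes <- function(latents, annotations, level = "cell_type",
                                     unlabeled = .UNLABELED,
                                     provenance = "reference") {
  latents <- as.matrix(latents)
  if (length(annotations) != nrow(latents))
    .stopf("annotations must have one entry per latent row")
  keep <- annotations != unlabeled
  if (!any(keep)) .stopf("no labeled cells at level '%s'", level)
  m <- rowsum(latents[keep, , drop = FALSE], group = annotations[keep])
  m <- m / as.vector(table(annotations[keep])[rownames(m)])
  PrototypeSet(level, labeled = m[order(rownames(m)), , drop = FALSE],
               provenance = provenance)
}

#' Compute unlabeled prototypes by clustering
#'
#' Unlabeled cells are clustered with the Louvain algorithm on a k-nearest-
#' neighbour graph of their latent means (Euclidean, `k = 15` by default);
#' each cluster's prototype is its mean latent vector. The default
#' resolution (0.3) favours coarse, well-separated populations: on an
#' unweighted kNN graph of a few hundred cells, standard-modularity
#' resolution splits even tight isolated groups. These prototypes are
#' reference points for downstream exploration and are never used in the
#' prototype loss.
#'
#' @param latents Latent means of the *unlabeled* cells only. An empty
#'   matrix yields an empty (not an error) prototype set.
#' @param resolution Louvain resolution parameter.
#' @param k Neighbours in the kNN graph.
#' @param level Annotation level name.
#' @param provenance `"reference"` or `"query"`.
#' @return A [PrototypeSet-class] with cluster prototypes named
#'   `"cluster<j>"`.
#' @export
computeUnlabeledPrototypes <- function(latents, resolution = 0.3, k = 15L,
                                       level = "cell_type",
                                       provenance = "reference") {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (n == 0L) return(PrototypeSet(level, provenance = provenance))
  cl <- .louvainClusters(latents, resolution, k)
  m <- rowsum(latents, group = cl)
  m <- m / as.vector(table(cl)[rownames(m)])
  rownames(m) <- paste0("cluster", rownames(m))
  PrototypeSet(level, unlabeled = m[order(rownames(m)), , drop = FALSE],
               provenance = provenance)
}

# Louvain community ids on a symmetrized kNN graph of the rows of X.
.louvainClusters <- function(X, resolution = 0.3, k = 15L) {
  n <- nrow(X)
  if (n == 1L) return(1L)
  k <- min(k, n - 1L)
  nn <- .knnIndices(X, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- .withSeed(0L,
    igraph::cluster_louvain(g, resolution = resolution))
  igraph::membership(comm)
}

#' Prototype pull-in loss
#'
#' Mean over cells of the summed Minkowski distances between each labeled
#' cell's latent mean and the prototype of its label, accumulated over all
#' annotation levels; unlabeled cells (and unlabeled prototypes) contribute
#' nothing. The normalizer is the number of cells in the batch.
#'
#' @param latents Cells-by-dimensions matrix.
#' @param annotations Named list (one entry per annotation level) of
#'   per-cell label vectors; a single vector is treated as one level.
#' @param prototypeSets Named list of [PrototypeSet-class] objects matching
#'   the annotation levels.
#' @param order Minkowski order.
#' @param unlabeled Sentinel for unannotated cells.
#' @return Non-negative scalar.
#' @export
prototypeLoss <- function(latents, annotations, prototypeSets, order = 2,
                          unlabeled = .UNLABELED) {
  latents <- as.matrix(latents)
  if (!is.list(annotations)) annotations <- list(cell_type = annotations)
  if (is(prototypeSets, "PrototypeSet"))
    prototypeSets <- stats::setNames(list(prototypeSets), names(annotations)[1L])
  protos <- lapply(prototypeSets, labeledPrototypes)
  pl <- .protoLossGrad(latents, annotations, protos, order, unlabeled)
  pl$loss
}
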