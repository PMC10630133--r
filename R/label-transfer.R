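#' Nearest-prototype classification with distance uncertainty
#'
#' Assigns each cell the label of the closest labeled prototype (Minkowski
#' distance in latent space) and reports that minimum distance as the
#' cell's uncertainty. Ties are broken towards the lexicographically
#' smallest label so results are platform-independent. Unlabeled prototypes
#' are ignored.
#'
#' @param latents Cells-by-dimensions matrix of latent means (see
#'   [getLatent()]).
#' @param prototypes A [PrototypeSet-class] (its labeled prototypes are
#'   used) or a labels-by-dimensions matrix.
#' @param order Minkowski order.
#' @return A [S4Vectors::DataFrame] with columns `predictedLabel`,
#'   `uncertainty`, `scaledUncertainty` (min-max over the scored
#'   population) and `unknown` (all `FALSE`; see [flagUnknown()]).
#' @seealso [flagUnknown()], [thresholdSweep()]
#' @export
classifyCells <- function(latents, prototypes, order = 2) {
  latents <- as.matrix(latents)
  P <- if (is(prototypes, "PrototypeSet")) labeledPrototypes(prototypes)
       else as.matrix(prototypes)
  if (!nrow(P)) .stopf("no labeled prototypes to classify against")
  P <- P[order(rownames(P)), , drop = FALSE]
  Dm <- .minkowskiCross(latents, P, order)
  pick <- apply(Dm, 1L, which.min)        # first minimum = smallest label
  u <- Dm[cbind(seq_len(nrow(Dm)), pick)]
  DataFrame(predictedLabel = rownames(P)[pick],
            uncertainty = u,
            scaledUncertainty = scaleUncertainty(u),
            unknown = rep(FALSE, length(u)),
            row.names = rownames(latents))
}

#' Scale uncertainties to the unit interval
#'
#' Monotone min-max rescaling over the scored population; rank order is
#' preserved. A degenerate (constant) vector maps to all zeros.
#'
#' @param u Non-negative per-cell uncertainties.
#' @return Values in `[0, 1]`.
#' @export
scaleUncertainty <- function(u) {
  if (any(u < 0)) .stopf("uncertainties must be non-negative")
  r <- max(u) - min(u)
  if (r == 0) return(rep(0, length(u)))
  (u - min(u)) / r
}

#' Flag unknown cells by an uncertainty quantile
#'
#' Marks cells whose uncertainty exceeds the `q`-quantile of the classified
#' population (linear-interpolation sample quantile) as unknown — cells too
#' far from every reference prototype to trust their transferred label. The
#' default `q = 0.9` flags roughly the most uncertain tenth.
#'
#' @param result Output of [classifyCells()].
#' @param q Quantile in `[0, 1]`; `q = 1` flags nothing, `q = 0` flags
#'   every cell.
#' @return `result` with the `unknown` column set.
#' @export
flagUnknown <- function(result, q = 0.9) {
  if (!nrow(result)) .stopf("empty classification result")
  if (q <= 0) {
    result$unknown <- rep(TRUE, nrow(result))
    return(result)
  }
  thr <- stats::quantile(result$uncertainty, q, names = FALSE, type = 7)
  result$unknown <- result$uncertainty > thr
  result
}

#' Accuracy of label transfer across unknown-detection thresholds
#'
#' For each quantile in `grid`, re-flags unknown cells and counts a
#' prediction as true when a truly novel cell (truth label absent from the
#' prototypes) is flagged unknown, or a known cell is not flagged and its
#' predicted label matches the truth.
#'
#' @param result Output of [classifyCells()].
#' @param truth Per-cell true labels (may contain labels the prototypes do
#'   not cover).
#' @param grid Quantiles to sweep.
#' @param knownLabels Labels the reference can predict; defaults to the
#'   predicted labels' universe in `result`.
#' @return data.frame with columns `q` and `accuracy`.
#' @export
thresholdSweep <- function(result, truth,
                           grid = seq(0, 1, by = 0.1),
                           knownLabels = NULL) {
  if (length(truth) != nrow(result))
    .stopf("truth must have one label per classified cell")
  if (is.null(knownLabels)) knownLabels <- unique(result$predictedLabel)
  novel <- !truth %in% knownLabels
  acc <- vapply(grid, function(q) {
    r <- flagUnknown(result, q)
    mean(ifelse(novel, r$unknown, !r$unknown & r$predictedLabel == truth))
  }, numeric(1L))
  data.frame(q = grid, accuracy = acc)
}

#' Write a label-transfer result as TSV
#'
#' @param result Output of [classifyCells()] / [flagUnknown()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeTransferResult <- function(result, path) {
  tab <- data.frame(cell_id = rownames(result) %||% seq_len(nrow(result)),
                    predicted_label = result$predictedLabel,
                    uncertainty = result$uncertainty,
                    scaled_uncertainty = result$scaledUncertainty,
                    unknown_flag = result$unknown)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export or import prototypes as a delimited table
#'
#' Prototype coordinates suffice for label transfer; exchanging this small
#' table lets labels be transferred without ever sharing the reference
#' dataset itself.
#'
#' @param x A [PrototypeSet-class] (export) or file path (import).
#' @param path Output file for export.
#' @return `writePrototypes` invisibly returns `path`; `readPrototypes`
#'   returns a [PrototypeSet-class].
#' @export
writePrototypes <- function(x, path) {
  stopifnot(is(x, "PrototypeSet"))
  mk <- function(m, flag) if (nrow(m))
    data.frame(level = x@level, label = rownames(m), labeled = flag,
               provenance = x@provenance, unname(as.data.frame(m)))
  tab <- rbind(mk(x@labeled, TRUE), mk(x@unlabeled, FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePrototypes
#' @export
readPrototypes <- function(x) {
  tab <- utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE)
  coords <- as.matrix(tab[, -(1:4), drop = FALSE])
  rownames(coords) <- tab$label
  colnames(coords) <- NULL
  PrototypeSet(tab$level[1L],
               labeled = coords[tab$labeled, , drop = FALSE],
               unlabeled = coords[!tab$labeled, , drop = FALSE],
               provenance = tab$provenance[1L])
}
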