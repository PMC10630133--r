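# Internal helpers shared across modules.

# Default sentinel marking a cell without an annotation at some level.
.UNLABELED <- "unlabeled"

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dense numeric matrix from any Matrix/base input.
.denseMatrix <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# Check a (possibly sparse) matrix holds non-negative integral values.
# Returns NULL when valid, otherwise a message naming offending entries.
.checkCounts <- function(m) {
  v <- if (is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(v)) {
    bad <- which(v < 0 | abs(v - round(v)) > 1e-8 | !is.finite(v))
    if (length(bad)) {
      return(sprintf("counts must be non-negative integers; %d offending entr%s (first value: %g)",
                     length(bad), if (length(bad) == 1L) "y" else "ies", v[bad[1L]]))
    }
  }
  NULL
}

# Indices of the k nearest Euclidean neighbours (self excluded) for each row
# of X. Ties broken by row index for determinism. O(n^2); intended for the
# desk-scale problems the package targets.
.knnIndices <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k >= n) .stopf("k (%d) must be smaller than the number of points (%d)", k, n)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  diag(D2) <- Inf
  t(apply(D2, 1L, function(d) order(d, method = "radix")[seq_len(k)]))
}

# Row-wise softmax with the usual max-shift for stability.
.rowSoftmax <- function(O) {
  O <- O - apply(O, 1L, max)
  E <- exp(O)
  E / rowSums(E)
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
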