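ns <- asNamespace("scProto")

test_that("count likelihoods match independent density routines", {
  set.seed(101)
  for (i in 1:50) {
    x <- rpois(1, 10)
    mu <- runif(1, 0.05, 20)
    size <- runif(1, 0.2, 10)
    expect_equal(nbNegLogLikelihood(x, mu, size),
                 -dnbinom(x, mu = mu, size = size, log = TRUE),
                 tolerance = 1e-6)
    lam <- runif(1, 0.01, 20)
    expect_equal(poissonNegLogLikelihood(x, lam),
                 -dpois(x, lam, log = TRUE), tolerance = 1e-8)
  }
  # matrix form sums over features per cell
  X <- matrix(rpois(12, 5), 3, 4)
  Mu <- matrix(runif(12, 0.5, 8), 3, 4)
  sz <- runif(4, 0.5, 5)
  manual <- sapply(1:3, function(i)
    -sum(dnbinom(X[i, ], mu = Mu[i, ], size = sz, log = TRUE)))
  expect_equal(nbNegLogLikelihood(X, Mu, sz), manual, tolerance = 1e-8)
})

test_that("NB tends to Poisson as inverse-dispersion grows", {
  x <- c(0, 1, 3, 7, 12)
  mu <- c(0.5, 1, 2.5, 6, 15)
  expect_lt(abs(nbNegLogLikelihood(x, mu, 1e6) - poissonNegLogLikelihood(x, mu)),
            1e-3)
})

test_that("likelihood edge cases behave", {
  expect_equal(poissonNegLogLikelihood(1, 1), 1)
  expect_equal(poissonNegLogLikelihood(0, 0), 0)
  expect_lt(nbNegLogLikelihood(0, 1e-12, 2), 1e-10)
  expect_error(nbNegLogLikelihood(1, -1, 2), "positive")
  expect_error(nbNegLogLikelihood(1, 1, 0), "positive")
  expect_error(poissonNegLogLikelihood(-1, 1), "non-negative")
})

test_that("Gaussian KL matches its closed form and is non-negative", {
  expect_equal(gaussianKL(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  expect_equal(gaussianKL(matrix(1), matrix(0)), 0.5)
  set.seed(7)
  Mu <- matrix(rnorm(1000 * 2), 1000)
  Lv <- matrix(rnorm(1000 * 2, 0, 0.5), 1000)
  kl <- gaussianKL(Mu, Lv)
  expect_true(all(kl >= 0))
  manual <- 0.5 * rowSums(Mu^2 + exp(Lv) - 1 - Lv)
  expect_equal(kl, manual)
})

test_that("encoding is deterministic, permutation-equivariant, shape-correct", {
  run <- tinyRun()
  ds <- run$atlas$reference[, 1:40]
  e1 <- encodeCells(ds, run$model, "mean")
  e2 <- encodeCells(ds, run$model, "mean")
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$z, e1$mean)
  expect_equal(dim(e1$mean), c(40L, modelConfig(run$model)$latentDim))

  perm <- sample(40)
  e3 <- encodeCells(ds[, perm], run$model, "mean")
  expect_equal(unname(e3$mean), unname(e1$mean[perm, ]))

  bad <- ds
  SummarizedExperiment::colData(bad)$sample <- rep("nonesuch", ncol(bad))
  expect_error(encodeCells(bad, run$model), "sample")
})

test_that("training-mode z varies around a fixed mean", {
  run <- tinyRun()
  ds <- run$atlas$reference[, 1:10]
  s1 <- encodeCells(ds, run$model, "sample")
  s2 <- encodeCells(ds, run$model, "sample")
  expect_identical(s1$mean, s2$mean)
  expect_false(identical(s1$z, s2$z))
})

test_that("decoder output is a library-scaled simplex", {
  run <- tinyRun()
  ds <- run$atlas$reference[, 1:25]
  z <- getLatent(ds, run$model)
  lib <- librarySize(ds)
  dec <- decodeCells(z, list(sample = covariateValues(ds, "sample")), lib,
                     run$model)
  expect_equal(unname(rowSums(dec$mean)), unname(lib), tolerance = 1e-9)
  expect_true(all(dec$mean >= 0))
  expect_true(all(dec$size > 0))
  # identical (z, condition) rows decode identically
  z2 <- rbind(z[1, ], z[1, ])
  d2 <- decodeCells(z2, list(sample = rep(covariateValues(ds, "sample")[1], 2)),
                    c(100, 100), run$model)
  expect_identical(d2$mean[1, ], d2$mean[2, ])
})

test_that("poisson-likelihood model trains and emits non-negative rates", {
  atlas <- generateSyntheticAtlas(tinySpec(seed = 31L, cellsPerBatch = 40L))
  cfg <- tinyConfig(seed = 31L, likelihood = "poisson")
  m <- buildReference(atlas$reference, cfg, nEpochs = 10L)
  ds <- atlas$reference[, 1:10]
  dec <- decodeCells(getLatent(ds, m), list(sample = covariateValues(ds, "sample")),
                     librarySize(ds), m)
  expect_true(all(dec$rate >= 0))
  expect_true(all(is.finite(trainingReport(m)$recon)))
})

test_that("cvaeLoss decomposes into its components", {
  run <- tinyRun()
  ds <- run$atlas$reference[, 1:50]
  l0 <- cvaeLoss(ds, run$model, klWeight = 0)
  l1 <- cvaeLoss(ds, run$model, klWeight = 0.37)
  expect_equal(l0$total, l0$recon)
  expect_equal(l1$total, l1$recon + 0.37 * l1$kl)
  expect_equal(l0$recon, l1$recon)
})

test_that("analytic gradients match finite differences", {
  set.seed(55)
  n <- 6L; G <- 8L; D <- 3L
  cfg <- unclass(protoModelConfig(embeddingDim = 2L, latentDim = D,
                                  hiddenWidth = 5L, seed = 1L))
  cfg$covariateKeys <- "sample"
  cfg$unlabeled <- "unlabeled"
  params <- ns$.initParams(cfg, G, list(sample = c("a", "b")))
  X <- matrix(rpois(n * G, 4), n, G)
  lib <- pmax(rowSums(X), 1)
  condIdx <- list(sample = sample(1:2, n, TRUE))
  eps <- matrix(rnorm(n * D), n, D)
  protos <- list(ct = matrix(rnorm(2 * D), 2, D,
                             dimnames = list(c("T1", "T2"), NULL)))
  labels <- list(ct = sample(c("T1", "T2", "unlabeled"), n, TRUE))
  lossOf <- function(p) ns$.lossGrads(p, cfg, X, log1p(X), lib, condIdx, eps,
                                      0.6, protos, labels, eta = 0.5)$total
  lg <- ns$.lossGrads(params, cfg, X, log1p(X), lib, condIdx, eps, 0.6,
                      protos, labels, eta = 0.5)
  h <- 1e-5
  for (nm in names(lg$grads)) {
    g <- lg$grads[[nm]]
    for (i in sample(length(g), min(3L, length(g)))) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - h
      num <- (lossOf(p2) - lossOf(p3)) / (2 * h)
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("a gradient step at a small learning rate decreases the loss", {
  set.seed(77)
  n <- 64L; G <- 12L; D <- 4L
  cfg <- unclass(protoModelConfig(embeddingDim = 2L, latentDim = D,
                                  hiddenWidth = 6L))
  cfg$covariateKeys <- "sample"
  cfg$unlabeled <- "unlabeled"
  params <- ns$.initParams(cfg, G, list(sample = c("a", "b")))
  X <- matrix(rpois(n * G, 6), n, G)
  condIdx <- list(sample = rep(1:2, each = 32L))
  eps <- matrix(0, n, D)    # deterministic comparison at the latent mean
  lossOf <- function(p) ns$.lossGrads(p, cfg, X, log1p(X), pmax(rowSums(X), 1),
                                      condIdx, eps, 1)$total
  lg <- ns$.lossGrads(params, cfg, X, log1p(X), pmax(rowSums(X), 1),
                      condIdx, eps, 1)
  p2 <- params
  for (nm in names(lg$grads)) p2[[nm]] <- p2[[nm]] - 1e-3 * lg$grads[[nm]]
  expect_lt(lossOf(p2), lossOf(params))
})

test_that("identity embedding table reproduces a one-hot CVAE input bitwise", {
  set.seed(13)
  n <- 9L; G <- 7L; N <- 4L
  cfg <- unclass(protoModelConfig(embeddingDim = N, latentDim = 3L,
                                  hiddenWidth = 5L))
  cfg$covariateKeys <- "sample"
  cfg$unlabeled <- "unlabeled"
  levels <- paste0("s", 1:N)
  params <- ns$.initParams(cfg, G, list(sample = levels))
  params$emb.sample <- diag(N)
  rownames(params$emb.sample) <- levels
  idx <- sample(N, n, TRUE)
  Xlog <- matrix(runif(n * G), n, G)
  S <- ns$.embBlock(params, "sample", list(sample = idx))
  onehot <- diag(N)[idx, ]
  expect_identical(unname(S), onehot)
  # and the full encoder pass equals a manual pass on the one-hot input
  fw <- ns$.forwardPass(params, cfg, Xlog, list(sample = idx),
                        rep(100, n))
  manual <- ns$.mlpForward(params, "enc", cfg$encoderDepth, cfg$norm,
                           cbind(Xlog, onehot))
  muManual <- sweep(manual$H %*% params$Wmu, 2L, params$bmu, "+")
  expect_identical(unname(fw$mu), unname(muManual))
})

test_that("parameter counting reproduces the embedding-vs-one-hot crossover", {
  # direct-counting oracle over a grid, both sides of the threshold
  for (G in c(50L, 200L)) for (N in c(5L, 40L, 120L)) for (D in c(8L, 16L)) {
    H <- 12L
    thr <- N * (2 * H) / (N + 2 * H)
    for (E in unique(pmax(1L, c(floor(thr), ceiling(thr) + 1L)))) {
      cfg <- protoModelConfig(embeddingDim = E, latentDim = D, hiddenWidth = H)
      emb <- E * N + (G + E) * H + (D + E) * H           # counted directly
      oh <- (G + N) * H + (D + N) * H
      expect_equal(countTrainableParameters(cfg, G, N, "embedding"), emb,
                   ignore_attr = TRUE)
      expect_equal(countTrainableParameters(cfg, G, N, "onehot"), oh,
                   ignore_attr = TRUE)
      expect_identical(fewerParamsThanOneHot(cfg, G, N), E < thr)
    }
  }
  # printed example: G=100, D=10, H_enc=H_dec=10, N=50 -> threshold 1000/70
  c14 <- protoModelConfig(embeddingDim = 14, latentDim = 10, hiddenWidth = 10)
  c15 <- protoModelConfig(embeddingDim = 15, latentDim = 10, hiddenWidth = 10)
  expect_true(fewerParamsThanOneHot(c14, 100, 50))
  expect_false(fewerParamsThanOneHot(c15, 100, 50))
  # single condition: embeddings are never fewer (E >= 1 = N)
  for (E in c(1L, 3L, 10L))
    expect_false(fewerParamsThanOneHot(
      protoModelConfig(embeddingDim = E, hiddenWidth = 20), 100, 1))
})

test_that("serialization round-trips to an identical forward pass", {
  run <- tinyRun()
  path <- file.path(tempdir(), "model.rds")
  saveProtoModel(run$model, path)
  back <- loadProtoModel(path)
  ds <- run$atlas$reference[, 1:20]
  expect_identical(getLatent(ds, back), getLatent(ds, run$model))
  expect_identical(back@params, run$model@params)
})
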