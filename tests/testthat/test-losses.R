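test_that("content-consistency loss follows its closed form", {
  # identical content vectors -> 0
  F <- matrix(rep(c(1, 2, 3), each = 7), 7, 3)
  expect_equal(contentConsistencyLoss(featureSet(F, La = 0L)), 0)
  # two-modality variant: c1 = 0, c2 = 2 -> mean 1, loss (1 + 1)/(2*1) = 1
  expect_equal(contentConsistencyLoss(matrix(c(0, 2), 2, 1), La = 0L), 1)
  # quadratic homogeneity
  fs <- randomFeatureSet(D = 5L, La = 2L, seed = 11)
  L1 <- contentConsistencyLoss(fs)
  for (t in c(0.5, 2, 3)) {
    scaled <- featureSet(features(fs) * t, La = 2L)
    expect_equal(contentConsistencyLoss(scaled), t^2 * L1)
  }
  # empty content part warns and returns 0
  expect_warning(v <- contentConsistencyLoss(fs, La = 5L), "undefined")
  expect_equal(v, 0)
})

test_that("appearance-separation loss is the mean squared pairwise cosine", {
  # identical nonzero appearance vectors -> 1
  A <- matrix(rep(c(1, 2), each = 7), 7, 2)
  expect_equal(appearanceSeparationLoss(featureSet(A, La = 2L)), 1)
  # seven pairwise orthogonal vectors -> 0
  expect_equal(appearanceSeparationLoss(featureSet(diag(7), La = 7L)), 0)
  # a1 = (1,0), a2 = (1,1), rest zero: only pair (1,2) contributes 1/2
  A2 <- matrix(0, 7, 2)
  A2[1, ] <- c(1, 0); A2[2, ] <- c(1, 1)
  expect_equal(appearanceSeparationLoss(featureSet(A2, La = 2L)),
               (1 / 2) / 21)
  expect_warning(v <- appearanceSeparationLoss(featureSet(A2, La = 0L)),
                 "undefined")
  expect_equal(v, 0)
  # bounded in [0, 1]
  for (i in 1:10) {
    fs <- randomFeatureSet(D = 4L, La = 3L, seed = 100 + i)
    L <- appearanceSeparationLoss(fs)
    expect_gte(L, 0); expect_lte(L, 1)
  }
})

test_that("total loss composes cross-entropy with the weighted terms", {
  zero <- lossWeights(0, 0, 0)
  expect_equal(totalLoss(c(0.5, 0.5), NULL, "MCN", NULL, zero), log(2))
  expect_equal(totalLoss(c(0.25, 0.75), NULL, "MCN", NULL, zero),
               -log(0.75))
  # every added term is nonnegative: L >= CE(main, label)
  set.seed(12)
  for (i in 1:10) {
    fs <- randomFeatureSet(D = 4L, La = 2L, seed = 200 + i)
    sec <- matrix(runif(7), 7, 1)
    sec <- cbind(1 - sec, sec)
    main <- runif(1)
    main <- c(1 - main, main)
    L <- totalLoss(main, sec, "SCN", fs, lossWeights(0.7, 0.3, 0.2))
    expect_gte(L, crossEntropy(main, "SCN") - 1e-12)
    expect_true(is.finite(L))
  }
  # clamping keeps the loss finite at degenerate probabilities
  expect_true(is.finite(crossEntropy(c(1, 0), "MCN")))
  expect_error(crossEntropy(c(0.5, 0.5), "bad"), "label")
})

test_that("hand-derived network gradients match finite differences", {
  # end-to-end gradient of the full DIS training loss (main CE + auxiliary
  # CE + content and appearance constraints) against central differences
  set.seed(13)
  p <- makePack(function(m) matrix(runif(6400, -1, 1), 80, 80), label = "MCN")
  model <- fusionModel("DIS", D = 4L, La = 2L, hidden = 3L, seed = 14L)
  lw <- lossWeights(0.5, 0.3, 0.2)
  an <- cystfuse:::.sliceGrad(model, p, lw)

  numGrad <- function(path, idx, eps = 1e-5) {
    peek <- function(sgn) {
      m2 <- model
      w <- m2@weights
      w[[path[[1]]]][[path[[2]]]][[path[[3]]]][[path[[4]]]][idx] <-
        w[[path[[1]]]][[path[[2]]]][[path[[3]]]][[path[[4]]]][idx] + sgn * eps
      m2@weights <- w
      cystfuse:::.sliceGrad(m2, p, lw, computeGrads = FALSE)$loss
    }
    (peek(1) - peek(-1)) / (2 * eps)
  }
  checks <- list(
    list(path = list("backbones", 3L, 1L, "W"), idx = 5L),
    list(path = list("backbones", 3L, 1L, "b"), idx = 2L),
    list(path = list("backbones", 6L, 4L, "W"), idx = 17L),
    list(path = list("backbones", 1L, 4L, "b"), idx = 3L))
  for (ck in checks) {
    analytic <- an$grads[[ck$path[[1]]]][[ck$path[[2]]]][[ck$path[[3]]]][[
      ck$path[[4]]]][ck$idx]
    numeric <- numGrad(ck$path, ck$idx)
    expect_equal(analytic, numeric, tolerance = 1e-4)
  }

  # head weights (different nesting depth)
  numGradHead <- function(part, field, idx, eps = 1e-5) {
    peek <- function(sgn) {
      m2 <- model
      if (part == "mainHead") {
        m2@weights$mainHead[[field]][idx] <-
          m2@weights$mainHead[[field]][idx] + sgn * eps
      } else {
        m2@weights$secHeads[[5L]][[field]][idx] <-
          m2@weights$secHeads[[5L]][[field]][idx] + sgn * eps
      }
      cystfuse:::.sliceGrad(m2, p, lw, computeGrads = FALSE)$loss
    }
    (peek(1) - peek(-1)) / (2 * eps)
  }
  expect_equal(an$grads$mainHead$W1[4L], numGradHead("mainHead", "W1", 4L),
               tolerance = 1e-4)
  expect_equal(an$grads$mainHead$b2[1L], numGradHead("mainHead", "b2", 1L),
               tolerance = 1e-4)
  expect_equal(an$grads$secHeads[[5L]]$W2[2L],
               numGradHead("secHeads", "W2", 2L), tolerance = 1e-4)
})

test_that("gradients are exact for the other fusion routings", {
  set.seed(15)
  p <- makePack(function(m) matrix(runif(6400, -1, 1), 80, 80), label = "SCN")
  lw <- lossWeights(0.4, 0, 0)
  for (method in c("SUM", "MAX", "CAT", "IMG-F")) {
    model <- fusionModel(method, D = 3L, hidden = 3L, seed = 16L)
    an <- cystfuse:::.sliceGrad(model, p, lw)
    eps <- 1e-5
    peek <- function(sgn) {
      m2 <- model
      m2@weights$backbones[[1L]][[1L]]$W[7L] <-
        m2@weights$backbones[[1L]][[1L]]$W[7L] + sgn * eps
      cystfuse:::.sliceGrad(m2, p, lw, computeGrads = FALSE)$loss
    }
    expect_equal(an$grads$backbones[[1L]][[1L]]$W[7L],
                 (peek(1) - peek(-1)) / (2 * eps), tolerance = 1e-4,
                 info = method)
  }
})
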