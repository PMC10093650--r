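test_that("an ELM with zeroed hidden layer predicts the target mean", {
  x <- seq(0, 1, length.out = 9)
  y <- x^2 + 1
  m <- elmFit(x, y, hidden = 4, weights = matrix(0, 1, 4), biases = rep(0, 4))
  # H is constant 0.5 everywhere, so the least-squares fit is the mean
  expect_equal(predict(m, x), rep(mean(y), 9), tolerance = 1e-10)
  expect_equal(predict(m, c(-5, 42)), rep(mean(y), 2), tolerance = 1e-10)
})

test_that("ELM interpolates when hidden nodes outnumber distinct samples", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  y <- sin(3 * x)
  m <- elmFit(x, y, hidden = 12, seed = 4)
  expect_lt(rmse(evaluateFit(y, predict(m, x))), 1e-6)
})

test_that("ELM output weights equal an independent least-squares solve", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    L <- sample(2:15, 1)
    x <- runif(n)
    y <- runif(n)
    m <- elmFit(x, y, hidden = L, seed = i)
    H <- 1 / (1 + exp(-(outer(x, as.numeric(m@W)) +
                        matrix(m@b, n, L, byrow = TRUE))))
    beta <- as.numeric(MASS::ginv(H, tol = max(dim(H)) *
                                    .Machine$double.eps) %*% y)
    relerr <- sqrt(sum((m@beta - beta)^2)) / max(sqrt(sum(beta^2)), 1e-12)
    expect_lt(relerr, 1e-8)
  }
})

test_that("ELM training error is non-increasing in nested hidden bases", {
  set.seed(6)
  x <- runif(40)
  y <- exp(-2 * x) + rnorm(40, 0, 0.02)
  errs <- vapply(1:20, function(L) {
    m <- elmFit(x, y, hidden = L, seed = 99)
    rmse(evaluateFit(y, predict(m, x)))
  }, numeric(1))
  # non-increasing up to the pseudoinverse truncation noise: nested bases
  # can only add fitting power, but near-collinear sigmoid columns are
  # truncated at the SVD cutoff, which perturbs the solve at ~1e-5 relative
  expect_true(all(diff(errs) <= 1e-3 * head(errs, -1)))
})

test_that("ELM prediction is a pointwise map and demands a fitted model", {
  m <- elmFit(runif(10), runif(10), hidden = 5, seed = 7)
  xnew <- runif(15)
  perm <- sample(15)
  expect_equal(predict(m, xnew)[perm], predict(m, xnew[perm]))
  unfit <- new("ELMModel", W = m@W, b = m@b, beta = numeric(0), hidden = 5L,
               activation = "sigmoid", seed = 7L)
  expect_error(predict(unfit, 0.5), "no fitted output weights")
  expect_error(elmFit(c(1, NA, 3), c(1, 2, 3)), "non-finite")
})

test_that("the LM-trained ANN represents an easy function and is deterministic", {
  set.seed(8)
  x <- seq(0, 1, length.out = 40)
  y <- 2 * x - 0.3
  m <- annFit(x, y, hidden = 3, seed = 1)
  expect_gt(rsquared(evaluateFit(y, predict(m, x))), 0.999)

  m2 <- annFit(x, y, hidden = 3, seed = 1)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@W2, m2@W2)
  expect_identical(m@b1, m2@b1)
  expect_identical(m@b2, m2@b2)
})

test_that("heavy weight decay shrinks the ANN toward its output bias", {
  set.seed(9)
  x <- runif(30)
  y <- sin(6 * x)
  m <- annFit(x, y, hidden = 5, lambda = 1e6, seed = 2)
  w <- c(m@W1, m@b1, m@W2)
  expect_lt(max(abs(w)), 0.05)
  p <- predict(m, seq(0, 1, 0.1))
  expect_lt(diff(range(p)), 0.05)    # essentially constant at the bias
})

test_that("fit metrics match the standard formulas", {
  m <- evaluateFit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(rmse(m), sqrt(1 / 3))
  expect_equal(mae(m), 1 / 3)
  expect_equal(rsquared(m), 0.5)
  expect_equal(m@n, 3L)

  perfect <- evaluateFit(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(rmse(perfect), 0)
  expect_equal(mae(perfect), 0)
  expect_equal(rsquared(perfect), 1)

  expect_warning(z <- evaluateFit(c(1, 1, 1), c(1, 2, 0)), "zero variance")
  expect_true(is.na(rsquared(z)))
  expect_error(evaluateFit(1:3, 1:2), "equal lengths")
})

test_that("metrics satisfy RMSE >= MAE and scale linearly in the residuals", {
  set.seed(10)
  for (i in 1:25) {
    y <- rnorm(30)
    yhat <- y + rnorm(30, 0, runif(1, 0.01, 2))
    m <- evaluateFit(y, yhat)
    expect_gte(rmse(m), mae(m))
    expect_lte(rsquared(m), 1)
    cc <- runif(1, 0.1, 5)
    ms <- evaluateFit(y, y + cc * (yhat - y))
    expect_equal(rmse(ms), cc * rmse(m), tolerance = 1e-12)
    expect_equal(mae(ms), cc * mae(m), tolerance = 1e-12)
  }
})

test_that("the train/predict protocol evaluates both runs and guards input", {
  spec <- tinyScene(r = 30)
  law <- dryingLaw(sigmaMass = 0)
  times <- seq(0, 20, by = 2)
  sq <- renderSequence(spec, law, times, seed = 12)
  run <- buildRun(sq$frames, times, generateWeights(law, times, seed = 13))
  res <- trainPredictProtocol(run, run, model = "elm", seed = 3)
  expect_equal(rmse(res$train), rmse(res$test))
  expect_equal(rsquared(res$train), rsquared(res$test))

  tiny <- run
  tiny@data <- tiny@data[1:3, ]
  expect_error(trainPredictProtocol(tiny, run, model = "elm"),
               "fewer than 4")
})

test_that("ELM and ANN both recover a low-noise synthetic relation", {
  spec <- tinyScene(r = 35, width = 140L, height = 120L)
  law <- dryingLaw(sigmaMass = 0.002)
  times <- seq(0, 30, by = 1)
  pair <- makeExperimentPair(spec, law, times, seed = 21)
  tr <- buildRun(pair$train$frames, times, pair$train$weights)
  te <- buildRun(pair$test$frames, times, pair$test$weights)
  for (kind in c("elm", "ann")) {
    res <- trainPredictProtocol(tr, te, model = kind, seed = 5)
    expect_gt(rsquared(res$test), 0.98)
  }
})

test_that("test RMSE tracks the injected noise floor on synthetic pairs", {
  spec <- tinyScene(r = 35, width = 140L, height = 120L)
  law <- dryingLaw()
  floorMR <- law@sigmaMass / (law@dryMass * law@mc0)
  times <- seq(0, 30, by = 1)
  ratios <- vapply(1:5, function(s) {
    pair <- makeExperimentPair(spec, law, times, seed = s)
    tr <- buildRun(pair$train$frames, times, pair$train$weights)
    te <- buildRun(pair$test$frames, times, pair$test$weights)
    rmse(trainPredictProtocol(tr, te, "elm", seed = s)$test) / floorMR
  }, numeric(1))
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 1.5)
})
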