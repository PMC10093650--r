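.sigmoid <- function(x) 1 / (1 + exp(-x))

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Moore-Penrose pseudoinverse by SVD; singular values below
# max(dim) * eps relative to the largest are treated as zero — the
# conventional pinv cutoff, which keeps enough of the near-collinear
# sigmoid feature directions for interpolation-quality fits
.pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

.asPredictorMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
}

#' Fit an extreme learning machine
#'
#' Draws the input-to-hidden weights and biases from a seeded uniform(-1, 1)
#' distribution (node by node, so the bases for L and L + 1 hidden nodes are
#' nested), maps the predictors through a sigmoid hidden layer, and solves
#' the output weights in closed form as the minimum-norm least-squares
#' solution \code{beta = pinv(H) T}. No iterative training takes place.
#'
#' @param x predictor values: numeric vector or n x d matrix (typically the
#'   area ratio, d = 1).
#' @param y target values (typically the moisture ratio).
#' @param hidden number of hidden nodes L (default 12).
#' @param seed RNG seed for the random hidden layer.
#' @param weights,biases optional fixed hidden weights (d x L) and biases
#'   (length L), overriding the random draw; for diagnostics and testing.
#' @return an \linkS4class{ELMModel}.
#' @examples
#' x <- seq(0, 1, length.out = 20)
#' m <- elmFit(x, exp(-3 * x), hidden = 12, seed = 1)
#' predict(m, 0.5)
#' @export
elmFit <- function(x, y, hidden = 12L, seed = 1L,
                   weights = NULL, biases = NULL) {
  X <- .asPredictorMatrix(x)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("x and y must have matching lengths")
  if (nrow(X) < 2) stop("at least 2 samples are required")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in x or y")
  hidden <- as.integer(hidden)
  if (hidden < 1L) stop("hidden must be >= 1")
  d <- ncol(X)
  if (is.null(weights) != is.null(biases))
    stop("supply both weights and biases or neither")
  if (is.null(weights)) {
    draws <- .withSeed(as.integer(seed),
                       matrix(stats::runif((d + 1L) * hidden, -1, 1),
                              nrow = d + 1L))
    W <- draws[seq_len(d), , drop = FALSE]
    b <- draws[d + 1L, ]
  } else {
    W <- matrix(weights, nrow = d, ncol = hidden)
    b <- rep_len(as.numeric(biases), hidden)
  }
  H <- .sigmoid(sweep(X %*% W, 2, b, "+"))
  beta <- as.numeric(.pinv(H) %*% y)
  new("ELMModel", W = W, b = b, beta = beta, hidden = hidden,
      activation = "sigmoid", seed = as.integer(seed))
}

#' @describeIn elmFit predict moisture ratios for new area-ratio values
#' @param object a fitted \linkS4class{ELMModel}
#' @param newdata predictor values (vector or matrix)
#' @param ... ignored
#' @export
setMethod("predict", "ELMModel", function(object, newdata, ...) {
  if (length(object@beta) == 0) stop("model has no fitted output weights")
  X <- .asPredictorMatrix(newdata)
  if (ncol(X) != nrow(object@W)) stop("newdata has the wrong dimensionality")
  H <- .sigmoid(sweep(X %*% object@W, 2, object@b, "+"))
  as.numeric(H %*% object@beta)
})

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d sigmoid hidden node(s), seed %d\n",
              object@hidden, object@seed))
})

# ---- feedforward ANN trained by Levenberg-Marquardt ----

.annUnpack <- function(theta, d, L) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(d * L)], d, L); i <- i + d * L
  b1 <- theta[i + seq_len(L)]; i <- i + L
  W2 <- theta[i + seq_len(L)]; i <- i + L
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.annForward <- function(X, p) {
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  list(H = H, yhat = as.numeric(H %*% p$W2 + p$b2))
}

# Jacobian of the network output wrt all parameters, one row per sample
.annJacobian <- function(X, p) {
  n <- nrow(X); d <- ncol(X); L <- length(p$b1)
  fw <- .annForward(X, p)
  dH <- 1 - fw$H^2                       # tanh'
  JW1 <- matrix(0, n, d * L)
  for (j in seq_len(L)) {
    g <- p$W2[j] * dH[, j]
    JW1[, (j - 1L) * d + seq_len(d)] <- X * g
  }
  Jb1 <- dH * rep(p$W2, each = n)
  cbind(JW1, Jb1, fw$H, 1)
}

#' Fit a one-hidden-layer feedforward network by Levenberg-Marquardt
#'
#' tanh hidden layer, linear output. The objective is the penalized sum of
#' squares \code{sum(residual^2) + lambda * sum(weights^2)} (weight decay).
#' Each epoch solves the damped normal equations
#' \code{(J'J + lambda I + mu I) step = -(J'r + lambda theta)}; \code{mu}
#' shrinks by 10 after an accepted step and grows by 10 after a rejected
#' one. Training stops at \code{maxEpochs}, at a small penalized-gradient
#' norm, or by early stopping: when the RMSE on a seeded held-out
#' validation split has not improved for \code{patience} epochs, the weights
#' revert to the best validation epoch.
#'
#' @param x predictor values (vector or n x d matrix).
#' @param y target values.
#' @param hidden hidden node count (default 10).
#' @param lambda weight-decay coefficient (default 1e-4).
#' @param maxEpochs epoch cap (default 1000).
#' @param patience early-stopping patience in epochs (default 6).
#' @param valFraction fraction of samples held out for validation
#'   (default 0.2).
#' @param mu0 initial damping (default 1e-3).
#' @param gtol stop when the penalized gradient infinity-norm falls below
#'   this (default 1e-8).
#' @param seed RNG seed for initialization and the validation split.
#' @return an \linkS4class{ANNModel}.
#' @export
annFit <- function(x, y, hidden = 10L, lambda = 1e-4, maxEpochs = 1000L,
                   patience = 6L, valFraction = 0.2, mu0 = 1e-3,
                   gtol = 1e-8, seed = 1L) {
  X <- .asPredictorMatrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n != length(y)) stop("x and y must have matching lengths")
  if (n < 4) stop("at least 4 samples are required for a validation split")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in x or y")
  d <- ncol(X); L <- as.integer(hidden)
  np <- d * L + L + L + 1L

  init <- .withSeed(as.integer(seed), {
    theta0 <- stats::runif(np, -0.7, 0.7)
    nval <- max(1L, round(valFraction * n))
    vidx <- sort(sample.int(n, nval))
    list(theta = theta0, vidx = vidx)
  })
  vidx <- init$vidx
  tidx <- setdiff(seq_len(n), vidx)
  Xt <- X[tidx, , drop = FALSE]; yt <- y[tidx]
  Xv <- X[vidx, , drop = FALSE]; yv <- y[vidx]

  cost <- function(theta) {
    p <- .annUnpack(theta, d, L)
    r <- .annForward(Xt, p)$yhat - yt
    sum(r^2) + lambda * sum(theta^2)
  }
  valRMSE <- function(theta) {
    p <- .annUnpack(theta, d, L)
    sqrt(mean((.annForward(Xv, p)$yhat - yv)^2))
  }

  theta <- init$theta
  mu <- mu0
  cur <- cost(theta)
  best <- list(theta = theta, val = valRMSE(theta), epoch = 0L)
  stall <- 0L
  hist <- vector("list", maxEpochs)
  epoch <- 0L
  while (epoch < maxEpochs) {
    epoch <- epoch + 1L
    p <- .annUnpack(theta, d, L)
    r <- .annForward(Xt, p)$yhat - yt
    J <- .annJacobian(Xt, p)
    g <- 2 * (crossprod(J, r) + lambda * theta)   # penalized gradient
    if (max(abs(g)) < gtol) break
    A0 <- crossprod(J) + diag(lambda, np)
    accepted <- FALSE
    while (!accepted) {
      step <- tryCatch(
        solve(A0 + diag(mu, np), -(crossprod(J, r) + lambda * theta)),
        error = function(e) NULL)
      if (is.null(step)) {
        mu <- mu * 10
        if (mu > 1e12)
          stop("damped Hessian remained singular after mu escalation")
        next
      }
      cand <- theta + as.numeric(step)
      cc <- cost(cand)
      if (is.finite(cc) && cc < cur) {
        theta <- cand; cur <- cc
        mu <- max(mu / 10, 1e-12)
        accepted <- TRUE
      } else {
        mu <- mu * 10
        if (mu > 1e10) break                      # step cannot improve: done
      }
    }
    vr <- valRMSE(theta)
    hist[[epoch]] <- c(epoch = epoch, train_cost = cur, val_rmse = vr)
    if (vr < best$val - 1e-12) {
      best <- list(theta = theta, val = vr, epoch = epoch)
      stall <- 0L
    } else stall <- stall + 1L
    if (stall >= patience) break                  # early stopping
    if (!accepted) break
  }
  theta <- best$theta
  p <- .annUnpack(theta, d, L)
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null,
                                                    logical(1))]))
  new("ANNModel", W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2, hidden = L,
      config = list(lambda = lambda, maxEpochs = as.integer(maxEpochs),
                    patience = as.integer(patience),
                    valFraction = valFraction, mu0 = mu0, gtol = gtol),
      seed = as.integer(seed), history = hist)
}

#' @describeIn annFit predict moisture ratios for new area-ratio values
#' @param object a fitted \linkS4class{ANNModel}
#' @param newdata predictor values (vector or matrix)
#' @param ... ignored
#' @export
setMethod("predict", "ANNModel", function(object, newdata, ...) {
  X <- .asPredictorMatrix(newdata)
  if (ncol(X) != nrow(object@W1)) stop("newdata has the wrong dimensionality")
  .annForward(X, list(W1 = object@W1, b1 = object@b1, W2 = object@W2,
                      b2 = object@b2))$yhat
})

setMethod("show", "ANNModel", function(object) {
  cat(sprintf(
    "ANNModel: %d tanh hidden node(s), LM-trained for %d epoch(s), seed %d\n",
    object@hidden, nrow(object@history), object@seed))
})

#' Evaluate predictions against measurements
#'
#' Computes the three standard regression metrics:
#' RMSE = sqrt(mean((Yhat - Y)^2)), MAE = mean(|Yhat - Y|), and
#' R^2 = 1 - sum((Y - Yhat)^2) / sum((Y - mean(Y))^2).
#'
#' @param y measured values (e.g. moisture ratio).
#' @param yhat predicted values, same length.
#' @return a \linkS4class{FitMetrics}.
#' @examples
#' evaluateFit(c(1, 2, 3), c(1, 2, 4))  # RMSE 0.577, MAE 0.333, R2 0.5
#' @export
evaluateFit <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("y and yhat must have equal lengths")
  keep <- !is.na(y) & !is.na(yhat)
  y <- y[keep]; yhat <- yhat[keep]
  n <- length(y)
  if (n < 2) stop("at least 2 complete pairs are required")
  e <- yhat - y
  ss <- sum((y - mean(y))^2)
  r2 <- if (ss > 0) 1 - sum(e^2) / ss else {
    warning("measured values have zero variance: R^2 is undefined")
    NA_real_
  }
  new("FitMetrics", rmse = sqrt(mean(e^2)), mae = mean(abs(e)), r2 = r2,
      n = n)
}

#' @describeIn rmse RMSE of a FitMetrics
#' @export
setMethod("rmse", "FitMetrics", function(x) x@rmse)
#' @describeIn mae MAE of a FitMetrics
#' @export
setMethod("mae", "FitMetrics", function(x) x@mae)
#' @describeIn rsquared R^2 of a FitMetrics
#' @export
setMethod("rsquared", "FitMetrics", function(x) x@r2)

setMethod("show", "FitMetrics", function(object) {
  cat(sprintf("FitMetrics (n = %d): RMSE %.4g, MAE %.4g, R2 %s\n",
              object@n, object@rmse, object@mae,
              if (is.na(object@r2)) "NA" else sprintf("%.4f", object@r2)))
})

#' @export
setMethod("as.data.frame", "FitMetrics",
          function(x, row.names = NULL, optional = FALSE, ...)
            data.frame(rmse = x@rmse, mae = x@mae, r2 = x@r2, n = x@n))

#' Train on one run, predict a different run
#'
#' The protocol that makes the model claim honest: a shrinkage model is
#' fitted on the complete (AR, MR) pairs of one drying experiment and
#' evaluated both on its own training pairs and on an independent
#' experiment. AR and MR are already on a [0, 1]-like scale, so no further
#' normalization is applied.
#'
#' @param trainRun,testRun \linkS4class{DryingRun} objects.
#' @param model "elm" or "ann".
#' @param hidden hidden node count; defaults to 12 for the ELM and 10 for
#'   the ANN.
#' @param seed RNG seed forwarded to the fitter.
#' @param ... further arguments to \code{\link{elmFit}} or
#'   \code{\link{annFit}}.
#' @return a list with elements \code{model} (the kind), \code{fit} (the
#'   fitted \linkS4class{ShrinkageModel}), \code{train} and \code{test}
#'   (\linkS4class{FitMetrics}), and \code{predictions} (per-run predicted
#'   MR).
#' @export
trainPredictProtocol <- function(trainRun, testRun, model = c("elm", "ann"),
                                 hidden = NULL, seed = 1L, ...) {
  model <- match.arg(model)
  stopifnot(is(trainRun, "DryingRun"), is(testRun, "DryingRun"))
  pairs <- function(run) {
    d <- as.data.frame(run)
    d[!is.na(d$AR) & !is.na(d$MR), c("AR", "MR")]
  }
  tr <- pairs(trainRun); te <- pairs(testRun)
  if (nrow(tr) < 4) stop("fewer than 4 usable (AR, MR) pairs in the training run")
  if (is.null(hidden)) hidden <- if (model == "elm") 12L else 10L
  fit <- if (model == "elm")
    elmFit(tr$AR, tr$MR, hidden = hidden, seed = seed, ...)
  else
    annFit(tr$AR, tr$MR, hidden = hidden, seed = seed, ...)
  ptr <- predict(fit, tr$AR)
  pte <- predict(fit, te$AR)
  list(model = model, fit = fit,
       train = evaluateFit(tr$MR, ptr), test = evaluateFit(te$MR, pte),
       predictions = list(train = ptr, test = pte))
}
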