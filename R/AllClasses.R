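#' @useDynLib dryvision, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' GrayHistogram: gray-level counts of an 8-bit image
#'
#' Holds the counts \code{h(i)} of each gray level \code{i} in 0..255 and the
#' total pixel count \code{n}. This is the sufficient statistic for metric
#' thresholding: the segmentation threshold depends on the image only through
#' its histogram.
#'
#' @slot counts integer vector of length 256; \code{counts[i+1]} is the number
#'   of pixels at gray level \code{i}.
#' @slot n total number of pixels; equals \code{sum(counts)}.
#' @export
setClass("GrayHistogram",
  representation(counts = "integer", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != 256L)
      msg <- c(msg, "counts must have length 256 (gray levels 0..255)")
    if (any(object@counts < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (sum(object@counts) != object@n)
      msg <- c(msg, "sum(counts) must equal n")
    if (is.null(msg)) TRUE else msg
  })

#' ThresholdResult: the gray level selected by metric thresholding
#'
#' The metric threshold is the gray level k minimizing the count-weighted sum
#' of absolute deviations of each class (levels <= k, levels > k) from its
#' class mean. \code{mu1}/\code{mu2} are those class means; \code{cost} is the
#' minimized objective.
#'
#' @slot k integer threshold in 0..254; pixels <= k are background.
#' @slot cost numeric, minimized objective value.
#' @slot mu1 mean gray level of the lower class (levels 0..k).
#' @slot mu2 mean gray level of the upper class (levels k+1..255).
#' @export
setClass("ThresholdResult",
  representation(k = "integer", cost = "numeric", mu1 = "numeric",
                 mu2 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@k < 0L || object@k > 255L)
      msg <- c(msg, "k must lie in 0..255")
    if (!(object@mu1 <= object@k && object@k < object@mu2))
      msg <- c(msg, "class means must satisfy mu1 <= k < mu2")
    if (object@cost < 0) msg <- c(msg, "cost must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' ParticleSet: labeled connected components of a binary mask
#'
#' Particles are maximal 8-connected components of foreground (1) pixels.
#' Labels are assigned in raster-scan order, 1..u, so labeling is
#' deterministic. The per-particle table records pixel counts and bounding
#' boxes (row/column ranges, 1-based).
#'
#' @slot labels integer matrix, same shape as the mask; 0 = background.
#' @slot particles data.frame with columns \code{label}, \code{pixels},
#'   \code{rmin}, \code{rmax}, \code{cmin}, \code{cmax}.
#' @export
setClass("ParticleSet",
  representation(labels = "matrix", particles = "data.frame"),
  validity = function(object) {
    msg <- NULL
    u <- nrow(object@particles)
    if (u > 0 && !identical(object@particles$label, seq_len(u)))
      msg <- c(msg, "labels must be contiguous 1..u")
    if (sum(object@particles$pixels) != sum(object@labels > 0L))
      msg <- c(msg, "particle pixel counts must sum to total foreground")
    if (is.null(msg)) TRUE else msg
  })

#' WeightSeries: sample mass over drying time
#'
#' @slot times sampling times in minutes from drying start, strictly
#'   increasing.
#' @slot masses sample masses in grams.
#' @slot dryMass bone-dry mass in grams (from e.g. 24 h hot-air drying at
#'   105 C). Noisy masses may dip below \code{dryMass} near the end of a run;
#'   they are kept as measured and the moisture bookkeeping clips at zero.
#' @export
setClass("WeightSeries",
  representation(times = "numeric", masses = "numeric", dryMass = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@masses))
      msg <- c(msg, "times and masses must have equal length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@dryMass) != 1 || !is.finite(object@dryMass) ||
        object@dryMass <= 0)
      msg <- c(msg, "dryMass must be a single positive number")
    if (any(!is.finite(object@masses)) || any(object@masses <= 0))
      msg <- c(msg, "masses must be finite and positive")
    if (is.null(msg)) TRUE else msg
  })

#' DryingRun: the aligned per-frame record of one drying experiment
#'
#' One row per acquired frame: time, segmented sample area (pixels), area
#' ratio AR_t = A_t/A_0, aligned mass, dry-basis moisture content
#' MC_t = (m_t - m_d)/m_d, and moisture ratio MR_t = MC_t/MC_0, plus the
#' per-frame segmentation diagnostics (threshold, particle count). Unsegmented
#' frames and unmatched weights are recorded as NA, never as zero.
#'
#' @slot data data.frame with columns \code{time_min}, \code{area_px},
#'   \code{AR}, \code{mass_g}, \code{MC}, \code{MR}, \code{threshold_k},
#'   \code{n_particles}.
#' @slot dryMass dry mass in grams used for the moisture bookkeeping.
#' @export
setClass("DryingRun",
  representation(data = "data.frame", dryMass = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("time_min", "area_px", "AR", "mass_g", "MC", "MR",
              "threshold_k", "n_particles")
    if (!all(need %in% names(object@data)))
      msg <- c(msg, paste("data must contain columns:",
                          paste(need, collapse = ", ")))
    else {
      d <- object@data
      if (nrow(d) > 0) {
        if (is.unsorted(d$time_min, strictly = TRUE))
          msg <- c(msg, "time_min must be strictly increasing")
        if (!is.na(d$AR[1]) && abs(d$AR[1] - 1) > 1e-12)
          msg <- c(msg, "AR at the first frame must equal 1")
        if (!is.na(d$MR[1]) && abs(d$MR[1] - 1) > 1e-12)
          msg <- c(msg, "MR at the first frame must equal 1")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Virtual parent for shrinkage regressors mapping area ratio to moisture
#' ratio.
#' @export
setClass("ShrinkageModel", representation("VIRTUAL"))

#' ELMModel: extreme learning machine regressor
#'
#' Single-hidden-layer feedforward network with randomly drawn, fixed
#' input-to-hidden weights and closed-form output weights: the hidden
#' activations H = sigmoid(X W + b) form a random feature map and
#' \code{beta} is the minimum-norm least-squares solution of H beta = T,
#' computed by SVD pseudoinverse.
#'
#' @slot W input-to-hidden weight matrix (d x L), drawn uniform(-1, 1).
#' @slot b hidden biases (length L), drawn uniform(-1, 1).
#' @slot beta hidden-to-output weights (length L).
#' @slot hidden number of hidden nodes L.
#' @slot activation activation tag; only "sigmoid" is implemented.
#' @slot seed RNG seed used for W and b.
#' @export
setClass("ELMModel", contains = "ShrinkageModel",
  representation(W = "matrix", b = "numeric", beta = "numeric",
                 hidden = "integer", activation = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@hidden < 1L) msg <- c(msg, "hidden must be >= 1")
    if (ncol(object@W) != object@hidden || length(object@b) != object@hidden)
      msg <- c(msg, "W and b must match the hidden node count")
    if (length(object@beta) && length(object@beta) != object@hidden)
      msg <- c(msg, "beta must have one weight per hidden node")
    if (!identical(object@activation, "sigmoid"))
      msg <- c(msg, "only the sigmoid activation is implemented")
    if (is.null(msg)) TRUE else msg
  })

#' ANNModel: one-hidden-layer feedforward network trained by
#' Levenberg-Marquardt
#'
#' tanh hidden layer, linear output, trained by damped Gauss-Newton
#' (Levenberg-Marquardt) on the residuals augmented with a weight-decay
#' penalty, with early stopping on a held-out validation split.
#'
#' @slot W1 input-to-hidden weights (d x L).
#' @slot b1 hidden biases (length L).
#' @slot W2 hidden-to-output weights (length L).
#' @slot b2 output bias.
#' @slot hidden hidden node count L.
#' @slot config training configuration (lambda, maxEpochs, patience, ...).
#' @slot seed RNG seed for initialization and validation split.
#' @slot history per-epoch training/validation RMSE record.
#' @export
setClass("ANNModel", contains = "ShrinkageModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "numeric",
                 b2 = "numeric", hidden = "integer", config = "list",
                 seed = "integer", history = "data.frame"),
  validity = function(object) {
    msg <- NULL
    w <- c(object@W1, object@b1, object@W2, object@b2)
    if (any(!is.finite(w))) msg <- c(msg, "weights must be finite")
    if (ncol(object@W1) != object@hidden ||
        length(object@b1) != object@hidden ||
        length(object@W2) != object@hidden)
      msg <- c(msg, "layer shapes must match the hidden node count")
    if (is.null(msg)) TRUE else msg
  })

#' FitMetrics: regression performance summary
#'
#' RMSE, MAE and the coefficient of determination R^2 between measured and
#' predicted moisture ratios. R^2 is NA when the measured values have zero
#' variance.
#'
#' @slot rmse root mean squared error.
#' @slot mae mean absolute error.
#' @slot r2 coefficient of determination (possibly NA).
#' @slot n number of points evaluated.
#' @export
setClass("FitMetrics",
  representation(rmse = "numeric", mae = "numeric", r2 = "numeric",
                 n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@rmse < 0 || object@mae < 0)
      msg <- c(msg, "rmse and mae must be non-negative")
    if (object@rmse + 1e-12 < object@mae)
      msg <- c(msg, "rmse must be >= mae")
    if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
      msg <- c(msg, "r2 cannot exceed 1")
    if (is.null(msg)) TRUE else msg
  })

#' SceneSpec: geometry and photometry of a synthetic drying scene
#'
#' Describes what the camera sees: bright circular samples on a dark
#' background, plus the nuisance structure the segmentation pipeline must
#' survive (gray-level jitter, dust specks on the background cloth, transient
#' dark bubbles inside the samples).
#'
#' @slot width,height frame size in pixels.
#' @slot centers u x 2 matrix of disk centers (row, col), 1-based.
#' @slot radii initial disk radii r_0 in pixels.
#' @slot fgLevel,fgJitter foreground gray level and Gaussian jitter sd.
#' @slot bgLevel,bgJitter background gray level and Gaussian jitter sd.
#' @slot dustCount number of dust specks per frame.
#' @slot dustSizeRange speck radius range in pixels (small: below any sane
#'   particle filter).
#' @slot bubbleRate expected number of new bubbles per disk per frame
#'   (Poisson).
#' @slot bubbleRadiusRange bubble radius range in pixels.
#' @slot bubbleLifetime bubble persistence in frames.
#' @export
setClass("SceneSpec",
  representation(width = "integer", height = "integer", centers = "matrix",
                 radii = "numeric", fgLevel = "numeric", fgJitter = "numeric",
                 bgLevel = "numeric", bgJitter = "numeric",
                 dustCount = "integer", dustSizeRange = "numeric",
                 bubbleRate = "numeric", bubbleRadiusRange = "numeric",
                 bubbleLifetime = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@centers) != length(object@radii))
      msg <- c(msg, "one radius per disk center required")
    r <- object@radii
    cen <- object@centers
    if (any(cen[, 1] - r < 1 | cen[, 1] + r > object@height |
            cen[, 2] - r < 1 | cen[, 2] + r > object@width))
      msg <- c(msg, "disks must lie fully inside the frame at t = 0")
    if (nrow(cen) > 1) {
      dd <- as.matrix(dist(cen))
      rr <- outer(r, r, "+")
      diag(dd) <- Inf
      if (any(dd <= rr)) msg <- c(msg, "disks must not overlap")
    }
    if (object@fgLevel - object@bgLevel < 80)
      msg <- c(msg, "foreground must exceed background by >= 80 gray levels")
    if (is.null(msg)) TRUE else msg
  })

#' DryingLaw: parametric ground truth for synthetic drying runs
#'
#' Moisture ratio follows a Page-type law MR(t) = exp(-k t^n) (or any
#' user-supplied non-increasing curve with MR(0) = 1), and shrinkage is
#' linked linearly: AR(t) = 1 - c (1 - MR(t)) with c in (0, 1]. Masses are
#' reconstructed as m_t = m_d (1 + MC_0 MR(t)) plus Gaussian noise.
#'
#' @slot k,n Page-law parameters (k in 1/min^n, n dimensionless).
#' @slot mrFun optional MR(t) callable overriding the Page law.
#' @slot shrinkLink linear AR-MR link coefficient c.
#' @slot dryMass dry mass m_d in grams.
#' @slot mc0 initial dry-basis moisture content in g/g.
#' @slot sigmaMass sd of additive mass noise in grams.
#' @slot sigmaArea sd of relative area noise applied as radius jitter.
#' @export
setClass("DryingLaw",
  representation(k = "numeric", n = "numeric", mrFun = "ANY",
                 shrinkLink = "numeric", dryMass = "numeric", mc0 = "numeric",
                 sigmaMass = "numeric", sigmaArea = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@shrinkLink < 0 || object@shrinkLink > 1)
      msg <- c(msg, "shrinkLink must lie in [0, 1] (0 = no shrinkage)")
    if (object@dryMass <= 0) msg <- c(msg, "dryMass must be positive")
    if (object@mc0 <= 0) msg <- c(msg, "mc0 must be positive")
    if (object@sigmaMass < 0 || object@sigmaArea < 0)
      msg <- c(msg, "noise sds must be non-negative")
    if (!is.null(object@mrFun) && !is.function(object@mrFun))
      msg <- c(msg, "mrFun must be NULL or a function of time")
    if (is.null(msg)) TRUE else msg
  })
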