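#' Convert an RGB frame to grayscale by the channel-mean method
#'
#' Each output pixel is the mean of the R, G and B components, rounded half
#' up, so a light sample on a dark background keeps its full contrast. This
#' is the first dimensionality-reduction step of the online pipeline: 24-bit
#' pixels become 8-bit.
#'
#' @param img H x W x 3 numeric array with channel values in 0..255.
#' @return integer H x W matrix with values in 0..255.
#' @examples
#' frame <- array(c(30, 60, 90), dim = c(1, 1, 3))
#' toGrayscale(frame)  # 60
#' @export
toGrayscale <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop("img must be non-empty")
  if (any(img < 0 | img > 255)) stop("channel values must lie in 0..255")
  g <- floor((img[, , 1] + img[, , 2] + img[, , 3]) / 3 + 0.5)
  dim(g) <- dim(img)[1:2]
  storage.mode(g) <- "integer"
  g[g > 255L] <- 255L
  g
}

#' Gray-level histogram of an 8-bit image
#'
#' @param img integer matrix with values in 0..255.
#' @return a \linkS4class{GrayHistogram}.
#' @export
grayHistogram <- function(img) {
  if (!is.matrix(img) || length(img) == 0L) stop("img must be a non-empty matrix")
  if (any(img < 0 | img > 255)) stop("gray values must lie in 0..255")
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  new("GrayHistogram", counts = as.integer(counts), n = length(img))
}

#' Metric threshold selection
#'
#' Chooses the gray level k minimizing
#' \deqn{\sum_{i=0}^{k} h(i) |i - \mu_1| + \sum_{i=k+1}^{255} h(i) |i - \mu_2|,}
#' where \eqn{\mu_1} and \eqn{\mu_2} are the count-weighted mean gray levels
#' of the two classes. Only splits with both classes non-empty are
#' candidates; ties are broken toward the smallest k. The computation is
#' vectorized over k via cumulative sums: for a class with mean \eqn{\mu},
#' the weighted absolute deviation splits at \eqn{\lfloor\mu\rfloor} into two
#' prefix-sum differences.
#'
#' @param x a \linkS4class{GrayHistogram} or an integer gray matrix.
#' @return a \linkS4class{ThresholdResult}.
#' @examples
#' h <- grayHistogram(matrix(c(rep(20L, 10), rep(220L, 10)), 4, 5))
#' metricThreshold(h)  # k = 20, cost = 0
#' @export
metricThreshold <- function(x) {
  if (is.matrix(x)) x <- grayHistogram(x)
  stopifnot(is(x, "GrayHistogram"))
  h <- as.numeric(x@counts)
  lev <- 0:255
  C <- cumsum(h)
  S <- cumsum(lev * h)
  n <- C[256]
  if (n < 1) stop("empty histogram")
  k <- 0:254
  kk <- k + 1L                 # 1-based index of level k
  n1 <- C[kk]
  n2 <- n - n1
  valid <- n1 > 0 & n2 > 0
  if (!any(valid))
    stop(errorCondition(
      "all pixels share one gray level: no two-class split exists",
      class = c("dryvision_degenerate_frame", "error", "condition")))
  mu1 <- S[kk] / n1
  mu2 <- (S[256] - S[kk]) / n2
  # lower class [0, k]: split the |i - mu1| sum at floor(mu1)
  m1 <- pmin(floor(mu1), k) + 1L
  d1 <- (mu1 * C[m1] - S[m1]) + (S[kk] - S[m1]) - mu1 * (C[kk] - C[m1])
  # upper class [k+1, 255]: split at floor(mu2)
  m2 <- pmax(pmin(floor(mu2), 255), k + 1) + 1L
  d2 <- (mu2 * (C[m2] - C[kk]) - (S[m2] - S[kk])) +
    (S[256] - S[m2]) - mu2 * (C[256] - C[m2])
  cost <- d1 + d2
  cost[!valid] <- Inf
  best <- which.min(cost)      # first minimum = smallest k
  new("ThresholdResult", k = k[best], cost = cost[best],
      mu1 = mu1[best], mu2 = mu2[best])
}

#' Binarize a gray image at a threshold
#'
#' Pixels at or below k become background (0); pixels above k become
#' foreground (1).
#'
#' @param img integer gray matrix.
#' @param k threshold gray level in 0..255, or a
#'   \linkS4class{ThresholdResult}.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize <- function(img, k) {
  if (is(k, "ThresholdResult")) k <- k@k
  stopifnot(is.matrix(img), length(k) == 1, k >= 0, k <= 255)
  m <- (img > k) + 0L
  dim(m) <- dim(img)
  m
}

#' Convert a binary mask to a displayable 8-bit image
#'
#' Multiplies each pixel by 255 so the foreground renders white.
#'
#' @param mask integer 0/1 matrix.
#' @return integer matrix with values 0/255.
#' @export
toDisplay <- function(mask) {
  .checkMask(mask)
  mask * 255L
}

.checkMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask == 0L | mask == 1L)) stop("mask must contain only 0 and 1")
  invisible(TRUE)
}

#' Label connected particles in a binary mask
#'
#' A particle is a maximal 8-connected component of foreground pixels.
#' Labels are assigned in raster-scan order (1..u), and per-particle pixel
#' counts and bounding boxes are tabulated.
#'
#' @param mask integer 0/1 matrix.
#' @return a \linkS4class{ParticleSet}.
#' @export
labelParticles <- function(mask) {
  .checkMask(mask)
  m <- mask
  storage.mode(m) <- "integer"
  lab <- .label8(m)
  u <- max(lab)
  if (u == 0L) {
    tab <- data.frame(label = integer(0), pixels = integer(0),
                      rmin = integer(0), rmax = integer(0),
                      cmin = integer(0), cmax = integer(0))
    return(new("ParticleSet", labels = lab, particles = tab))
  }
  fg <- lab > 0L
  lb <- lab[fg]
  idx <- which(fg, arr.ind = TRUE)
  tab <- data.frame(
    label = seq_len(u),
    pixels = tabulate(lb, nbins = u),
    rmin = as.integer(tapply(idx[, 1], lb, min)),
    rmax = as.integer(tapply(idx[, 1], lb, max)),
    cmin = as.integer(tapply(idx[, 2], lb, min)),
    cmax = as.integer(tapply(idx[, 2], lb, max)),
    row.names = NULL)
  new("ParticleSet", labels = lab, particles = tab)
}

#' Fill enclosed holes in particles
#'
#' A hole is a connected region of background pixels completely encircled by
#' foreground — during drying, the dark specular spots of transient air
#' bubbles. Every background component not 4-connected to the image border is
#' set to foreground; border-connected background is untouched and foreground
#' is never removed, so the operation is idempotent and monotone.
#'
#' @param x a \linkS4class{ParticleSet} or an integer 0/1 mask.
#' @return integer 0/1 matrix with holes filled.
#' @export
fillHoles <- function(x) {
  mask <- if (is(x, "ParticleSet")) (x@labels > 0L) + 0L else x
  .checkMask(mask)
  m <- mask
  storage.mode(m) <- "integer"
  reach <- .borderBackground4(m)
  filled <- (m == 1L | !reach) + 0L
  dim(filled) <- dim(mask)
  filled
}

#' Filter particles by pixel count
#'
#' Retains the particles with at least \code{minPixels} pixels — the samples
#' — and drops the tiny specks produced by dust on the background cloth.
#' Survivors are relabeled contiguously, preserving raster order.
#'
#' @param particles a \linkS4class{ParticleSet}.
#' @param minPixels minimum pixel count for a particle to be retained.
#' @return a \linkS4class{ParticleSet} containing only the retained
#'   particles.
#' @export
filterParticles <- function(particles, minPixels = 200) {
  stopifnot(is(particles, "ParticleSet"), minPixels >= 0)
  tab <- particles@particles
  keep <- tab$pixels >= minPixels
  kept <- tab[keep, , drop = FALSE]
  lab <- particles@labels
  newlab <- match(lab, kept$label, nomatch = 0L)
  dim(newlab) <- dim(lab)
  kept$label <- seq_len(nrow(kept))
  row.names(kept) <- NULL
  new("ParticleSet", labels = newlab, particles = kept)
}

#' @describeIn totalArea sum of retained particle pixel counts
#' @export
setMethod("totalArea", "ParticleSet", function(x) sum(x@particles$pixels))

#' @describeIn particleCount number of particles
#' @export
setMethod("particleCount", "ParticleSet", function(x) nrow(x@particles))

#' @describeIn particlePixels per-particle pixel counts
#' @export
setMethod("particlePixels", "ParticleSet", function(x) x@particles$pixels)

#' @describeIn labelMatrix the label matrix
#' @export
setMethod("labelMatrix", "ParticleSet", function(x) x@labels)

setMethod("show", "ParticleSet", function(object) {
  cat("ParticleSet:", particleCount(object), "particle(s),",
      sum(object@particles$pixels), "foreground pixel(s) in a",
      paste(dim(object@labels), collapse = " x "), "mask\n")
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf(
    "Metric threshold k = %d (cost %.2f, class means %.2f / %.2f)\n",
    object@k, object@cost, object@mu1, object@mu2))
})

setMethod("show", "GrayHistogram", function(object) {
  nz <- which(object@counts > 0L) - 1L
  cat("GrayHistogram:", object@n, "pixels over levels",
      min(nz), "..", max(nz), "\n")
})

#' Segment one frame and measure the sample area
#'
#' Runs the full per-frame chain: grayscale conversion, metric threshold,
#' binarization, particle labeling, hole filling, relabeling, dust
#' filtering, and area summation. Each frame is thresholded independently,
#' matching the online acquire-process-record loop.
#'
#' @param img an H x W x 3 RGB array (values 0..255) or an integer gray
#'   matrix.
#' @param minPixels dust filter: minimum particle size in pixels.
#' @return a list with elements \code{area} (pixels), \code{threshold}
#'   (a \linkS4class{ThresholdResult}), \code{nParticles} (retained count),
#'   \code{mask} (final 0/1 matrix) and \code{particles}
#'   (final \linkS4class{ParticleSet}).
#' @export
segmentFrame <- function(img, minPixels = 200) {
  g <- if (is.matrix(img)) img else toGrayscale(img)
  th <- metricThreshold(grayHistogram(g))
  mask <- binarize(g, th)
  ps <- labelParticles(mask)
  filled <- fillHoles(ps)
  kept <- filterParticles(labelParticles(filled), minPixels)
  list(area = totalArea(kept), threshold = th,
       nParticles = particleCount(kept),
       mask = (labelMatrix(kept) > 0L) + 0L, particles = kept)
}
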