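#' Dry-basis moisture content
#'
#' MC = (m_t - m_d) / m_d, in grams of water per gram of dry solids.
#'
#' @param mass sample mass(es) m_t in grams.
#' @param dryMass dry mass m_d in grams.
#' @param clip if TRUE, masses below the dry mass (scale noise near the end
#'   of a run) are clipped to MC = 0 with a warning instead of erroring.
#' @return numeric moisture content(s), g/g dry basis.
#' @examples
#' moistureContent(10.87, 1)  # 9.87
#' @export
moistureContent <- function(mass, dryMass, clip = FALSE) {
  stopifnot(length(dryMass) == 1, is.finite(dryMass), dryMass > 0)
  mc <- (mass - dryMass) / dryMass
  low <- !is.na(mc) & mc < 0
  if (any(low)) {
    if (!clip)
      stop("mass below dry mass: negative moisture content is impossible")
    warning(sum(low), " mass value(s) below the dry mass clipped to MC = 0")
    mc[low] <- 0
  }
  mc
}

#' @describeIn moistureRatio MC_t / MC_0 for numeric moisture contents
#' @param mc0 initial dry-basis moisture content MC_0 (> 0)
#' @export
setMethod("moistureRatio", "numeric", function(x, mc0) {
  stopifnot(length(mc0) == 1)
  if (!is.finite(mc0) || mc0 <= 0)
    stop("mc0 must be a positive number")
  x / mc0
})

#' Convert wet-basis to dry-basis moisture content
#'
#' A wet-basis fraction w (water mass over total mass) corresponds to
#' w / (1 - w) grams of water per gram of dry solids. A common drying
#' endpoint of 15 % wet basis is 0.176 g/g dry basis.
#'
#' @param w wet-basis moisture fraction(s) in [0, 1).
#' @return dry-basis moisture content(s), g/g.
#' @examples
#' wetToDryBasis(0.15)  # 0.1765
#' @export
wetToDryBasis <- function(w) {
  if (any(w < 0 | w >= 1)) stop("wet-basis fraction must lie in [0, 1)")
  w / (1 - w)
}

#' Convert dry-basis to wet-basis moisture content
#'
#' Inverse of \code{\link{wetToDryBasis}}: d / (1 + d).
#' @param d dry-basis moisture content(s), g/g (>= 0).
#' @return wet-basis fraction(s).
#' @export
dryToWetBasis <- function(d) {
  if (any(d < 0)) stop("dry-basis moisture content must be non-negative")
  d / (1 + d)
}

#' Area ratio series
#'
#' AR_t = A_t / A_0, the segmented sample area normalized by the initial
#' area; AR_0 is exactly 1. Missing areas (unsegmentable frames) propagate
#' as missing ratios.
#'
#' @param areas numeric vector of per-frame areas A_t in pixels; the first
#'   element is A_0.
#' @return numeric vector of area ratios, same length.
#' @export
areaRatioSeries <- function(areas) {
  if (length(areas) == 0) stop("no areas supplied")
  a0 <- areas[1]
  if (is.na(a0) || a0 <= 0)
    stop("first frame area A_0 is missing or zero: run cannot be normalized")
  ar <- areas / a0
  ar[1] <- 1
  ar
}

#' Construct a WeightSeries
#'
#' @param times sampling times in minutes, strictly increasing.
#' @param masses sample masses in grams.
#' @param dryMass dry mass in grams.
#' @return a \linkS4class{WeightSeries}.
#' @export
weightSeries <- function(times, masses, dryMass) {
  new("WeightSeries", times = as.numeric(times), masses = as.numeric(masses),
      dryMass = as.numeric(dryMass))
}

#' @describeIn runTimes times of a WeightSeries
#' @export
setMethod("runTimes", "WeightSeries", function(x) x@times)

setMethod("show", "WeightSeries", function(object) {
  cat(sprintf(
    "WeightSeries: %d samples over %.1f..%.1f min, mass %.3f -> %.3f g (dry %.3f g)\n",
    length(object@times), min(object@times), max(object@times),
    object@masses[1], object@masses[length(object@masses)], object@dryMass))
})

#' Build a DryingRun from frames and a weight series
#'
#' Runs the imaging pipeline on every frame, aligns each frame with the
#' nearest weight sample (within half the acquisition interval), and
#' assembles the full per-frame record: area, area ratio, mass, dry-basis
#' moisture content and moisture ratio. Frames on which segmentation fails
#' (degenerate histogram, or no particle surviving the dust filter) are
#' recorded as missing, except the first frame, whose area A_0 anchors the
#' normalization and must be measurable.
#'
#' @param frames a list of frames (H x W x 3 arrays or gray matrices) or a
#'   character vector of PNG paths.
#' @param times frame acquisition times in minutes; defaults to an
#'   \code{interval}-spaced grid from 0.
#' @param weights a \linkS4class{WeightSeries}.
#' @param minPixels dust filter threshold passed to
#'   \code{\link{segmentFrame}}.
#' @param interval acquisition interval in minutes (used for the alignment
#'   tolerance); defaults to the median spacing of \code{times}.
#' @param strict if TRUE, masses below the dry mass abort the run instead of
#'   being clipped to MC = 0.
#' @return a \linkS4class{DryingRun}.
#' @export
buildRun <- function(frames, times = NULL, weights, minPixels = 200,
                     interval = NULL, strict = FALSE) {
  stopifnot(is(weights, "WeightSeries"))
  if (is.character(frames)) frames <- lapply(frames, readFrame)
  nf <- length(frames)
  if (nf == 0) stop("no frames supplied")
  if (is.null(times)) {
    step <- if (is.null(interval)) 0.5 else interval
    times <- seq(0, by = step, length.out = nf)
  }
  stopifnot(length(times) == nf)
  if (is.null(interval))
    interval <- if (nf > 1) stats::median(diff(times)) else 0.5

  area <- rep(NA_real_, nf)
  thk <- rep(NA_integer_, nf)
  npart <- rep(NA_integer_, nf)
  for (i in seq_len(nf)) {
    seg <- tryCatch(segmentFrame(frames[[i]], minPixels = minPixels),
                    dryvision_degenerate_frame = function(e) NULL)
    if (!is.null(seg) && seg$area > 0) {
      area[i] <- seg$area
      thk[i] <- seg$threshold@k
      npart[i] <- seg$nParticles
    }
  }
  if (is.na(area[1]))
    stop("first frame is unsegmentable: cannot establish A_0")
  ar <- areaRatioSeries(area)

  # nearest-neighbor weight alignment within half the acquisition interval
  wt <- runTimes(weights)
  mass <- vapply(times, function(tt) {
    j <- which.min(abs(wt - tt))
    if (abs(wt[j] - tt) <= interval / 2) weights@masses[j] else NA_real_
  }, numeric(1))
  mc <- rep(NA_real_, nf)
  ok <- !is.na(mass)
  mc[ok] <- moistureContent(mass[ok], weights@dryMass, clip = !strict)
  if (is.na(mc[1]) || mc[1] <= 0)
    stop("initial moisture content is missing or zero: cannot normalize MR")
  mr <- moistureRatio(mc, mc0 = mc[1])

  d <- data.frame(time_min = as.numeric(times), area_px = area, AR = ar,
                  mass_g = mass, MC = mc, MR = mr, threshold_k = thk,
                  n_particles = npart)
  new("DryingRun", data = d, dryMass = weights@dryMass)
}

#' @describeIn areaRatio AR series of a run
#' @export
setMethod("areaRatio", "DryingRun", function(x) x@data$AR)

#' @describeIn moistureRatio MR series of a DryingRun
#' @export
setMethod("moistureRatio", "DryingRun", function(x) x@data$MR)

#' @describeIn runTimes times of a DryingRun
#' @export
setMethod("runTimes", "DryingRun", function(x) x@data$time_min)

#' @export
setMethod("as.data.frame", "DryingRun",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

setMethod("show", "DryingRun", function(object) {
  d <- object@data
  cat(sprintf(
    "DryingRun: %d frames over %.1f..%.1f min\n  AR %.3f -> %.3f, MR %.3f -> %.4f (%d incomplete row(s))\n",
    nrow(d), min(d$time_min), max(d$time_min),
    d$AR[1], d$AR[nrow(d)], d$MR[1], d$MR[nrow(d)],
    sum(!stats::complete.cases(d[, c("AR", "MR")]))))
})

#' Average replicate drying runs
#'
#' Replicate experiments on one time grid are averaged pointwise (arithmetic
#' mean per time point, NA-propagating), yielding one consensus run.
#'
#' @param runs a list of \linkS4class{DryingRun} objects sharing an
#'   identical time grid.
#' @return a \linkS4class{DryingRun} of pointwise means.
#' @export
averageRuns <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, is, logical(1), "DryingRun")))
  t0 <- runs[[1]]@data$time_min
  for (r in runs)
    if (!isTRUE(all.equal(r@data$time_min, t0)))
      stop("replicate runs must share an identical time grid")
  cols <- c("area_px", "AR", "mass_g", "MC", "MR")
  d <- runs[[1]]@data
  for (cc in cols)
    d[[cc]] <- rowMeans(do.call(cbind, lapply(runs, function(r) r@data[[cc]])))
  d$threshold_k <- NA_integer_
  d$n_particles <- NA_integer_
  new("DryingRun", data = d,
      dryMass = mean(vapply(runs, function(r) r@dryMass, numeric(1))))
}
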