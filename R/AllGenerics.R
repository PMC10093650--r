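#' Number of particles in a ParticleSet
#' @param x a \linkS4class{ParticleSet}
#' @return integer particle count u
#' @export
setGeneric("particleCount", function(x) standardGeneric("particleCount"))

#' Per-particle pixel counts
#' @param x a \linkS4class{ParticleSet}
#' @return integer vector of pixel counts P_j, one per particle
#' @export
setGeneric("particlePixels", function(x) standardGeneric("particlePixels"))

#' Label matrix of a ParticleSet
#' @param x a \linkS4class{ParticleSet}
#' @return integer matrix; 0 = background, 1..u = particle labels
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' Total segmented sample area in pixels
#'
#' The sum of the pixel counts of the retained particles,
#' A = sum_j P_j. Apply after \code{\link{filterParticles}} so dust does not
#' contribute.
#' @param x a \linkS4class{ParticleSet}
#' @return numeric pixel count
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))

#' Moisture ratio
#'
#' For numeric input, MR_t = MC_t / MC_0 (both dry basis). For a
#' \linkS4class{DryingRun}, the aligned MR series.
#' @param x dry-basis moisture content values, or a DryingRun
#' @param ... \code{mc0} for the numeric method
#' @return numeric moisture ratio(s)
#' @export
setGeneric("moistureRatio", function(x, ...) standardGeneric("moistureRatio"))

#' Area ratio series of a drying run
#' @param x a \linkS4class{DryingRun}
#' @return numeric vector AR_t (NA where a frame was unsegmentable)
#' @export
setGeneric("areaRatio", function(x) standardGeneric("areaRatio"))

#' Acquisition times of a drying run
#' @param x a \linkS4class{DryingRun} or \linkS4class{WeightSeries}
#' @return numeric times in minutes
#' @export
setGeneric("runTimes", function(x) standardGeneric("runTimes"))

#' Root mean squared error of a fit
#' @param x a \linkS4class{FitMetrics}
#' @return numeric RMSE
#' @export
setGeneric("rmse", function(x) standardGeneric("rmse"))

#' Mean absolute error of a fit
#' @param x a \linkS4class{FitMetrics}
#' @return numeric MAE
#' @export
setGeneric("mae", function(x) standardGeneric("mae"))

#' Coefficient of determination of a fit
#' @param x a \linkS4class{FitMetrics}
#' @return numeric R^2 (NA if the reference values had zero variance)
#' @export
setGeneric("rsquared", function(x) standardGeneric("rsquared"))
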