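#' Construct a SceneSpec
#'
#' Defaults emulate the imaging conditions the pipeline targets: three
#' bright cylindrical samples (disks, initial radius 45 px) on a dark
#' cloth in a 240 x 320 frame, high foreground/background contrast, a
#' sprinkling of small bright dust specks, and transient dark bubbles that
#' appear inside the samples while moisture evaporates.
#'
#' @param width,height frame size in pixels.
#' @param centers u x 2 matrix of disk centers (row, col).
#' @param radii initial disk radii in pixels.
#' @param fgLevel,fgJitter foreground gray level and jitter sd.
#' @param bgLevel,bgJitter background gray level and jitter sd.
#' @param dustCount dust specks per frame.
#' @param dustSizeRange dust speck radius range (px).
#' @param bubbleRate expected new bubbles per disk per frame.
#' @param bubbleRadiusRange bubble radius range (px).
#' @param bubbleLifetime bubble persistence (frames).
#' @return a \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(width = 320L, height = 240L,
                      centers = rbind(c(70, 80), c(70, 240), c(170, 160)),
                      radii = c(45, 45, 45),
                      fgLevel = 200, fgJitter = 6,
                      bgLevel = 30, bgJitter = 6,
                      dustCount = 120L, dustSizeRange = c(1, 3),
                      bubbleRate = 0.3, bubbleRadiusRange = c(2, 6),
                      bubbleLifetime = 3L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      centers = as.matrix(centers), radii = as.numeric(radii),
      fgLevel = fgLevel, fgJitter = fgJitter, bgLevel = bgLevel,
      bgJitter = bgJitter, dustCount = as.integer(dustCount),
      dustSizeRange = dustSizeRange, bubbleRate = bubbleRate,
      bubbleRadiusRange = bubbleRadiusRange,
      bubbleLifetime = as.integer(bubbleLifetime))
}

#' Construct a DryingLaw
#'
#' Defaults describe a microwave drying run of fresh fruit cylinders: a
#' Page-law moisture curve reaching MR ~ 0.016 after 30 min (below the
#' usual 15 % wet-basis endpoint of MR ~ 0.018), initial dry-basis moisture
#' 9.87 g/g, dry mass 0.26 g per sample set, mass noise of 0.5 % of the
#' initial mass, and a linear shrinkage link AR = 1 - 0.6 (1 - MR).
#'
#' @param k,n Page-law parameters: MR(t) = exp(-k t^n), t in minutes.
#' @param mrFun optional function(t) overriding the Page law; must be
#'   non-increasing with value 1 at t = 0.
#' @param shrinkLink linear AR-MR link coefficient c in (0, 1].
#' @param dryMass dry mass in grams.
#' @param mc0 initial dry-basis moisture content, g/g.
#' @param sigmaMass additive mass noise sd in grams; the default is 0.5 %
#'   of the initial mass \code{dryMass * (1 + mc0)}.
#' @param sigmaArea relative area noise sd applied as radius jitter
#'   (default 0).
#' @return a \linkS4class{DryingLaw}.
#' @export
dryingLaw <- function(k = 0.025, n = 1.5, mrFun = NULL, shrinkLink = 0.6,
                      dryMass = 0.26, mc0 = 9.87,
                      sigmaMass = 0.005 * dryMass * (1 + mc0),
                      sigmaArea = 0) {
  new("DryingLaw", k = k, n = n, mrFun = mrFun, shrinkLink = shrinkLink,
      dryMass = dryMass, mc0 = mc0, sigmaMass = sigmaMass,
      sigmaArea = sigmaArea)
}

#' Moisture-ratio curve of a drying law
#' @param law a \linkS4class{DryingLaw}.
#' @param times times in minutes.
#' @return MR values in (0, 1], MR(0) = 1.
#' @export
moistureRatioCurve <- function(law, times) {
  stopifnot(is(law, "DryingLaw"))
  if (is.function(law@mrFun)) law@mrFun(times)
  else exp(-law@k * times^law@n)
}

#' Area-ratio curve of a drying law
#'
#' The linear shrinkage link AR(t) = 1 - c (1 - MR(t)).
#' @param law a \linkS4class{DryingLaw}.
#' @param times times in minutes.
#' @return AR values in (0, 1].
#' @export
areaRatioCurve <- function(law, times) {
  1 - law@shrinkLink * (1 - moistureRatioCurve(law, times))
}

# rasterize one disk into logical matrix `into` (modified by reference
# semantics via return); restricted to its bounding box for speed
.paintDisk <- function(into, cy, cx, r) {
  if (r <= 0) return(into)
  nr <- nrow(into); nc <- ncol(into)
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  sub <- outer((rows - cy)^2, (cols - cx)^2, "+") <= r^2
  into[rows, cols] <- into[rows, cols] | sub
  into
}

#' Render a synthetic drying frame sequence
#'
#' For each time point, renders an RGB frame of bright disks at radius
#' r_t = r_0 sqrt(AR_t) on a jittered dark background, with dust specks on
#' the cloth (kept clear of the samples so ground truth stays exact) and
#' dark bubbles strictly interior to the disks (a seeded Poisson birth
#' process with finite lifetime). A ground-truth table records the exact
#' rasterized disk pixel count per frame, both with bubble pixels excluded
#' ("visible") and included ("filled").
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param law a \linkS4class{DryingLaw}.
#' @param times frame times in minutes.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param dir optional directory; when given, frames are written as
#'   \code{frame_0001.png} ... plus \code{groundtruth.csv}.
#' @param bubbles,dust logical switches for the two nuisance processes.
#' @return a list with \code{frames} (list of H x W x 3 integer arrays),
#'   \code{truth} (data.frame: frame, time_min, radius columns, area_filled,
#'   area_visible), \code{times}, \code{files} (paths or NULL) and
#'   \code{seed}.
#' @export
renderSequence <- function(spec, law, times, seed = 1L, dir = NULL,
                           bubbles = TRUE, dust = TRUE) {
  stopifnot(is(spec, "SceneSpec"), is(law, "DryingLaw"))
  validObject(spec)
  nt <- length(times)
  u <- nrow(spec@centers)
  ar <- areaRatioCurve(law, times)
  .withSeed(as.integer(seed), {
    radii <- outer(spec@radii, sqrt(ar))              # u x nt
    if (law@sigmaArea > 0) {
      jit <- matrix(stats::rnorm(u * nt, 0, law@sigmaArea), u, nt)
      jit[, 1] <- 0                                   # AR_0 stays exactly 1
      radii <- radii * sqrt(pmax(1 + jit, 0.25))
    }
    # bubble birth process per disk
    events <- list()
    if (bubbles && spec@bubbleRate > 0) {
      for (dsk in seq_len(u)) {
        nNew <- stats::rpois(nt, spec@bubbleRate)
        for (f in which(nNew > 0)) {
          for (b in seq_len(nNew[f])) {
            fEnd <- min(nt, f + spec@bubbleLifetime - 1L)
            rb <- stats::runif(1, spec@bubbleRadiusRange[1],
                               spec@bubbleRadiusRange[2])
            rmin <- min(radii[dsk, f:fEnd])
            maxd <- rmin - rb - 2                      # strictly interior
            ang <- stats::runif(1, 0, 2 * pi)
            dd <- sqrt(stats::runif(1)) * max(maxd, 0)
            if (maxd > 0)
              events[[length(events) + 1L]] <-
                c(disk = dsk, from = f, to = fEnd, rb = rb,
                  dy = dd * sin(ang), dx = dd * cos(ang))
          }
        }
      }
    }
    H <- spec@height; W <- spec@width
    frames <- vector("list", nt)
    areaFilled <- areaVisible <- numeric(nt)
    for (f in seq_len(nt)) {
      diskMask <- matrix(FALSE, H, W)
      for (dsk in seq_len(u))
        diskMask <- .paintDisk(diskMask, spec@centers[dsk, 1],
                               spec@centers[dsk, 2], radii[dsk, f])
      bubMask <- matrix(FALSE, H, W)
      for (ev in events)
        if (ev["from"] <= f && f <= ev["to"]) {
          dsk <- ev["disk"]
          bubMask <- .paintDisk(bubMask,
                                spec@centers[dsk, 1] + ev["dy"],
                                spec@centers[dsk, 2] + ev["dx"], ev["rb"])
        }
      bubMask <- bubMask & diskMask
      areaFilled[f] <- sum(diskMask)
      areaVisible[f] <- sum(diskMask & !bubMask)

      g <- matrix(stats::rnorm(H * W, spec@bgLevel, spec@bgJitter), H, W)
      if (dust && spec@dustCount > 0) {
        placed <- 0L
        guard <- 0L
        clearance <- radii[, f] + max(spec@dustSizeRange) + 3
        while (placed < spec@dustCount && guard < 50L * spec@dustCount) {
          guard <- guard + 1L
          py <- stats::runif(1, 1, H); px <- stats::runif(1, 1, W)
          if (all((py - spec@centers[, 1])^2 + (px - spec@centers[, 2])^2 >
                  clearance^2)) {
            rd <- stats::runif(1, spec@dustSizeRange[1], spec@dustSizeRange[2])
            rows <- max(1L, floor(py - rd)):min(H, ceiling(py + rd))
            cols <- max(1L, floor(px - rd)):min(W, ceiling(px + rd))
            sub <- outer((rows - py)^2, (cols - px)^2, "+") <= rd^2
            blk <- g[rows, cols]
            blk[sub] <- spec@fgLevel - 30 +
              stats::rnorm(sum(sub), 0, spec@fgJitter)
            g[rows, cols] <- blk
            placed <- placed + 1L
          }
        }
      }
      fgpx <- diskMask & !bubMask
      g[fgpx] <- spec@fgLevel + stats::rnorm(sum(fgpx), 0, spec@fgJitter)
      g[bubMask] <- spec@bgLevel + stats::rnorm(sum(bubMask), 0, spec@bgJitter)
      g <- round(pmin(pmax(g, 0), 255))
      frame <- array(0L, dim = c(H, W, 3))
      frame[, , 1] <- frame[, , 2] <- frame[, , 3] <- as.integer(g)
      frames[[f]] <- frame
    }
    truth <- data.frame(frame = seq_len(nt), time_min = as.numeric(times),
                        area_filled = areaFilled, area_visible = areaVisible)
    for (dsk in seq_len(u)) truth[[paste0("radius_", dsk)]] <- radii[dsk, ]
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- file.path(dir, sprintf("frame_%04d.png", seq_len(nt)))
      for (f in seq_len(nt)) png::writePNG(frames[[f]] / 255, files[f])
      utils::write.csv(truth, file.path(dir, "groundtruth.csv"),
                       row.names = FALSE)
    }
    list(frames = frames, truth = truth, times = as.numeric(times),
         files = files, seed = as.integer(seed))
  })
}

#' Generate a weight series consistent with a drying law
#'
#' Inverts the moisture bookkeeping: m_t = m_d (1 + MC_0 MR(t)) plus
#' N(0, sigmaMass^2) noise, so a noiseless series round-trips through
#' moisture content and moisture ratio back to the law exactly.
#'
#' @param law a \linkS4class{DryingLaw}.
#' @param times sampling times in minutes.
#' @param seed RNG seed for the mass noise.
#' @return a \linkS4class{WeightSeries}.
#' @export
generateWeights <- function(law, times, seed = 1L) {
  stopifnot(is(law, "DryingLaw"))
  mr <- moistureRatioCurve(law, times)
  backbone <- law@dryMass * (1 + law@mc0 * mr)
  m <- .withSeed(as.integer(seed),
                 backbone + stats::rnorm(length(times), 0, law@sigmaMass))
  m <- pmax(m, law@dryMass * 0.5)      # scales cannot report near-zero mass
  weightSeries(times, m, law@dryMass)
}

#' Generate a matched train/test pair of synthetic drying experiments
#'
#' Two full runs (frames + weights + ground truth) from the same scene and
#' law but independent noise draws, mirroring the protocol of fitting on
#' one experiment and predicting a separate one. Sub-seeds for the four
#' noise sources are derived from \code{seed}, so the pair is reproducible.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param law a \linkS4class{DryingLaw}.
#' @param times frame/weighing times in minutes (default 0..30 by 0.5, the
#'   usual half-minute acquisition interval).
#' @param seed master RNG seed.
#' @param dir optional directory; when given, \code{train/} and
#'   \code{test/} subdirectories of frames are written.
#' @return a list with elements \code{train} and \code{test}, each a list
#'   of \code{frames}, \code{times}, \code{weights}
#'   (\linkS4class{WeightSeries}) and \code{truth}.
#' @export
makeExperimentPair <- function(spec = sceneSpec(), law = dryingLaw(),
                               times = seq(0, 30, by = 0.5), seed = 1L,
                               dir = NULL) {
  sub <- .withSeed(as.integer(seed), sample.int(.Machine$integer.max - 1L, 4))
  one <- function(sFrames, sMass, subdir) {
    seqn <- renderSequence(spec, law, times, seed = sFrames,
                           dir = if (is.null(dir)) NULL
                                 else file.path(dir, subdir))
    list(frames = seqn$frames, times = seqn$times,
         weights = generateWeights(law, times, seed = sMass),
         truth = seqn$truth, files = seqn$files)
  }
  list(train = one(sub[1], sub[2], "train"),
       test = one(sub[3], sub[4], "test"),
       seed = as.integer(seed))
}
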