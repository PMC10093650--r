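test_that("grayscale conversion averages channels with round-half-up", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(toGrayscale(px(0, 0, 0))[1, 1], 0L)
  expect_equal(toGrayscale(px(255, 255, 255))[1, 1], 255L)
  expect_equal(toGrayscale(px(30, 60, 90))[1, 1], 60L)
  expect_equal(toGrayscale(px(1, 0, 0))[1, 1], 0L)    # 1/3 rounds down
  expect_equal(toGrayscale(px(1, 1, 0))[1, 1], 1L)    # 2/3 rounds up
  expect_equal(toGrayscale(px(0, 1, 3))[1, 1], 1L)    # 4/3 -> 1 (half-up at .33)
  expect_equal(toGrayscale(px(1, 2, 0))[1, 1], 1L)    # exactly 1
  expect_equal(toGrayscale(px(2, 2, 5))[1, 1], 3L)    # 3.0 exactly
  expect_equal(toGrayscale(px(2, 2, 3))[1, 1], 2L)
  expect_equal(toGrayscale(px(1, 1, 1 + 3 * 0.5))[1, 1], 2L)  # half rounds up
  expect_error(toGrayscale(matrix(0, 2, 2)), "H x W x 3")
  expect_error(toGrayscale(array(300, dim = c(1, 1, 3))), "0\\.\\.255")
})

test_that("gray histogram counts every level and sums to the pixel count", {
  h <- grayHistogram(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  expect_equal(h@counts[1], 2L)
  expect_equal(h@counts[256], 2L)
  expect_equal(sum(h@counts), 4L)
  h2 <- grayHistogram(matrix(7L, 3, 3))
  expect_equal(h2@counts[8], 9L)

  set.seed(11)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  h3 <- grayHistogram(img)
  tally <- vapply(0:255, function(v) sum(img == v), integer(1))
  expect_equal(h3@counts, tally)
  expect_equal(h3@n, 64L)
})

test_that("metric threshold matches exhaustive minimization and honors ties", {
  img <- matrix(c(rep(20L, 10), rep(220L, 10)), 4, 5)
  th <- metricThreshold(grayHistogram(img))
  expect_s4_class(th, "ThresholdResult")
  expect_equal(th@k, 20L)     # smallest k of the zero-cost plateau
  expect_equal(th@cost, 0)
  expect_equal(th@mu1, 20)
  expect_equal(th@mu2, 220)

  expect_error(metricThreshold(grayHistogram(matrix(100L, 3, 3))),
               class = "dryvision_degenerate_frame")

  set.seed(21)
  for (i in 1:50) {
    h <- randomHistogram(500)
    got <- metricThreshold(h)
    want <- oracleThreshold(as.numeric(h@counts))
    expect_equal(got@k, want$k)
    expect_equal(got@cost, want$cost, tolerance = 1e-10)
  }
})

test_that("binarization splits at the threshold and partitions the image", {
  expect_equal(binarize(matrix(c(10L, 200L), 1), 20), matrix(c(0L, 1L), 1))
  expect_true(all(binarize(matrix(sample(0:255, 30), 5), 255) == 0L))

  set.seed(31)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  h <- grayHistogram(img)
  for (k in c(0, 7, 128, 254)) {
    m <- binarize(img, k)
    expect_equal(sum(m == 0L), sum(h@counts[seq_len(k + 1)]))
    expect_equal(sum(m == 0L) + sum(m == 1L), 400L)
  }
})

test_that("display conversion scales to 0/255 and inverts through binarize", {
  expect_equal(toDisplay(matrix(c(0L, 1L), 1)), matrix(c(0L, 255L), 1))
  expect_true(all(toDisplay(matrix(0L, 3, 3)) == 0L))
  set.seed(41)
  m <- randomMask(12, 9)
  expect_equal(binarize(toDisplay(m), 128), m)
})

test_that("particle labeling finds 8-connected components with counts and boxes", {
  m <- matrix(0L, 8, 8)
  m[1:2, 1:2] <- 1L        # 4 pixels
  m[5:7, 5:7] <- 1L        # 9 pixels
  ps <- labelParticles(m)
  expect_equal(particleCount(ps), 2L)
  expect_setequal(particlePixels(ps), c(4L, 9L))
  expect_equal(particleCount(labelParticles(matrix(0L, 4, 4))), 0L)

  # diagonal touching pixels are one particle under 8-connectivity
  d <- matrix(0L, 3, 3); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(particleCount(labelParticles(d)), 1L)

  set.seed(51)
  for (i in 1:20) {
    mk <- randomMask(15, 17, p = runif(1, 0.2, 0.6))
    got <- labelMatrix(labelParticles(mk))
    want <- oracleLabel(mk, conn = 8)
    expect_true(sameLabeling(got, want))
  }

  box <- labelParticles(m)@particles
  big <- box[box$pixels == 9L, ]
  expect_equal(c(big$rmin, big$rmax, big$cmin, big$cmax), c(5L, 7L, 5L, 7L))
})

test_that("hole filling closes enclosed background only, idempotently", {
  ring <- matrix(0L, 5, 5)
  ring[2:4, 2:4] <- 1L; ring[3, 3] <- 0L
  filled <- fillHoles(labelParticles(ring))
  expect_equal(filled[3, 3], 1L)
  expect_equal(sum(filled), 9L)

  stripe <- matrix(1L, 5, 5); stripe[, 3] <- 0L   # background reaches border
  expect_equal(fillHoles(stripe), stripe)

  set.seed(61)
  for (i in 1:30) {
    mk <- randomMask(14, 14, p = runif(1, 0.3, 0.7))
    got <- fillHoles(mk)
    expect_equal(got, oracleFillHoles(mk))
    expect_equal(fillHoles(got), got)            # idempotent
    expect_true(sum(got) >= sum(mk))             # monotone
  }
})

test_that("particle filtering keeps large particles and relabels contiguously", {
  m <- matrix(0L, 30, 110)
  m[2:26, 2:26] <- 1L                            # 625 px
  m[2, 30] <- 1L                                 # 1 px speck
  m[10:12, 40:42] <- 1L                          # 9 px speck
  m[2:26, 60:84] <- 1L                           # 625 px
  ps <- labelParticles(m)
  kept <- filterParticles(ps, 100)
  expect_equal(particleCount(kept), 2L)
  expect_equal(particlePixels(kept), c(625L, 625L))
  expect_equal(sort(unique(as.vector(labelMatrix(kept)))), c(0L, 1L, 2L))
  expect_equal(particlePixels(filterParticles(ps, 0)), particlePixels(ps))

  set.seed(71)
  for (i in 1:10) {
    mk <- randomMask(20, 20, 0.45)
    ps <- labelParticles(mk)
    thr <- sample(0:6, 1)
    kept <- filterParticles(ps, thr)
    expect_equal(particlePixels(kept),
                 particlePixels(ps)[particlePixels(ps) >= thr])
    # area after filtering equals foreground count of the final mask
    expect_equal(totalArea(kept), sum(labelMatrix(kept) > 0L))
  }
})

test_that("total area sums retained particle pixels", {
  m <- matrix(0L, 40, 80)
  m[3:32, 3:32] <- 1L     # 900
  m[21:40, 51:65] <- 1L   # 300
  ps <- labelParticles(m)
  expect_equal(totalArea(ps), 1200)
  expect_equal(totalArea(labelParticles(matrix(0L, 5, 5))), 0)
})

test_that("the full pipeline recovers disk area within rasterization tolerance", {
  set.seed(81)
  for (r in c(20, 35, 60)) {
    spec <- tinyScene(r = r, width = as.integer(4 * r), height = as.integer(4 * r))
    sq <- renderSequence(spec, dryingLaw(), times = 0, seed = r)
    seg <- segmentFrame(sq$frames[[1]])
    expect_lt(abs(seg$area - pi * r^2) / (pi * r^2), 0.03)
  }
})
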