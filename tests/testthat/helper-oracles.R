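# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each operation so they share no code path
# with the implementation they check.

# exhaustive metric-threshold minimization: direct double loop over k and
# gray levels
oracleThreshold <- function(counts) {
  lev <- 0:255
  best <- NULL
  for (k in 0:254) {
    lo <- lev <= k
    n1 <- sum(counts[lo]); n2 <- sum(counts[!lo])
    if (n1 == 0 || n2 == 0) next
    mu1 <- sum(counts[lo] * lev[lo]) / n1
    mu2 <- sum(counts[!lo] * lev[!lo]) / n2
    cost <- sum(counts[lo] * abs(lev[lo] - mu1)) +
      sum(counts[!lo] * abs(lev[!lo] - mu2))
    if (is.null(best) || cost < best$cost) best <- list(k = k, cost = cost)
  }
  best
}

# queue-based flood fill labeling from each unvisited foreground pixel
oracleLabel <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (conn == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        yi <- p[1] + nb[q, 1]; xj <- p[2] + nb[q, 2]
        if (yi >= 1 && yi <= nr && xj >= 1 && xj <= nc &&
            mask[yi, xj] != 0 && lab[yi, xj] == 0) {
          lab[yi, xj] <- cur
          queue[[length(queue) + 1]] <- c(yi, xj)
        }
      }
    }
  }
  lab
}

# hole filling as the complement of a 4-connected background flood fill
# seeded from every border pixel, realized by propagation to a fixed point
oracleFillHoles <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- mask == 0L
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- TRUE; reach[nr, ] <- TRUE
  reach[, 1] <- TRUE; reach[, nc] <- TRUE
  reach <- reach & bg
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  matrix(as.integer(mask == 1L | !reach), nr, nc)
}

# same-partition check: two labelings agree up to label renaming
sameLabeling <- function(a, b) {
  if (max(a) != max(b)) return(FALSE)
  all(tapply(b[a > 0], a[a > 0], function(v) length(unique(v)) == 1)) &&
    all((a > 0) == (b > 0))
}

randomMask <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

randomHistogram <- function(n = 500) {
  # random sparse support so skewed and near-degenerate shapes occur
  support <- sample(0:255, sample(2:40, 1))
  draws <- sample(support, n, replace = TRUE)
  counts <- tabulate(draws + 1L, nbins = 256)
  new("GrayHistogram", counts = as.integer(counts), n = as.integer(n))
}

# small rendered scene helpers used across test files
tinyScene <- function(r = 30, width = 120L, height = 100L, dustCount = 20L,
                      ...) {
  sceneSpec(width = width, height = height,
            centers = rbind(c(height / 2, width / 2)), radii = r,
            dustCount = dustCount, ...)
}
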