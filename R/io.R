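#' Read an image frame from a PNG file
#'
#' Returns an H x W x 3 integer array with channel values 0..255. Grayscale
#' PNGs are expanded to three equal channels; an alpha channel, if present,
#' is dropped.
#'
#' @param path path to an 8-bit PNG file.
#' @return H x W x 3 integer array.
#' @export
readFrame <- function(path) {
  if (!file.exists(path)) stop("frame not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  out <- array(as.integer(round(img * 255)), dim = dim(img))
  out
}

#' Write a DryingRun to CSV
#'
#' One row per frame with the columns time_min, area_px, AR, mass_g, MC,
#' MR, threshold_k, n_particles. The dry mass is carried in a
#' \code{# dry_mass_g:} comment header so the file round-trips.
#'
#' @param run a \linkS4class{DryingRun}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRunCSV <- function(run, path) {
  stopifnot(is(run, "DryingRun"))
  con <- file(path, open = "wb")            # binary: fixed newlines, so
  on.exit(close(con))                       # reruns are byte-identical
  writeLines(sprintf("# dry_mass_g: %.17g", run@dryMass), con, sep = "\n")
  d <- as.data.frame(run)
  out <- d
  for (nm in names(out))                    # %.17g round-trips doubles exactly
    out[[nm]] <- if (is.double(d[[nm]])) sprintf("%.17g", d[[nm]])
                 else as.character(d[[nm]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DryingRun from CSV
#'
#' @param path a CSV written by \code{\link{writeRunCSV}}.
#' @return a \linkS4class{DryingRun}.
#' @export
readRunCSV <- function(path) {
  first <- readLines(path, n = 1)
  dryMass <- NA_real_
  if (startsWith(first, "# dry_mass_g:"))
    dryMass <- as.numeric(sub("# dry_mass_g:", "", first))
  d <- utils::read.csv(path, comment.char = "#")
  for (nm in c("time_min", "area_px", "AR", "mass_g", "MC", "MR"))
    if (!is.null(d[[nm]])) d[[nm]] <- as.double(d[[nm]])
  for (nm in c("threshold_k", "n_particles"))
    if (!is.null(d[[nm]])) d[[nm]] <- as.integer(d[[nm]])
  new("DryingRun", data = d, dryMass = dryMass)
}
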