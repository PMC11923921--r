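# Aggregate morphometry: Otsu segmentation, maximum Feret diameter from the
# convex hull of object boundary pixels, and size statistics with the
# necrosis-risk (300 um) and undersampling (< 200 objects) quality flags.

#' Segment cell aggregates in a grayscale image
#'
#' Global Otsu threshold, hole filling and connected-component labelling,
#' followed by removal of objects whose equivalent-circle diameter falls
#' below `min_diameter_um`.  Touching aggregates are counted as one object
#' (no watershed splitting).
#'
#' @param image Numeric matrix, grayscale; foreground brighter than
#'   background.
#' @param pixel_size_um Pixel pitch, um/pixel.
#' @param min_diameter_um Minimum equivalent diameter retained (default 40).
#' @param threshold Optional manual threshold overriding Otsu.
#' @return Integer label matrix (0 = background); zero labels for a blank
#'   image.
#' @export
segment_aggregates <- function(image, pixel_size_um, min_diameter_um = 40,
                               threshold = NULL) {
  if (!is.matrix(image)) stop("image must be a numeric matrix")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  rng <- range(image)
  if (diff(rng) == 0) {
    if (rng[1] > 0) warning("saturated (constant) image; nothing to segment")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  scaled <- (image - rng[1]) / diff(rng)
  if (is.null(threshold)) threshold <- EBImage::otsu(scaled)
  bin <- EBImage::fillHull(scaled > threshold)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    eq_diam_um <- 2 * sqrt(areas / pi) * pixel_size_um
    drop <- which(eq_diam_um < min_diameter_um)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- EBImage::bwlabel(lab > 0)       # relabel consecutively
  }
  matrix(as.integer(lab), nrow(image), ncol(image))
}

# Convex hull of one labelled object's pixel centers.
.object_hull <- function(lab, id) {
  px <- which(lab == id, arr.ind = TRUE)
  px[grDevices::chull(px), , drop = FALSE]
}

#' Maximum Feret diameter of labelled objects
#'
#' Maximum pairwise distance between convex-hull vertices of each object's
#' pixel centers, plus one pixel width to account for the pixel extent (a
#' disc of radius r px then measures close to 2r px), scaled to micrometres.
#'
#' @param lab Integer label matrix from [segment_aggregates()].
#' @param pixel_size_um Pixel pitch, um/pixel.
#' @return Numeric vector of Feret diameters, um, one per label; objects
#'   with fewer than 3 boundary pixels are dropped with a message.
#' @export
feret_diameter <- function(lab, pixel_size_um) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  out <- numeric(0)
  for (id in ids) {
    if (sum(lab == id) < 3) {
      message("object ", id, " is degenerate (< 3 pixels); excluded")
      next
    }
    h <- .object_hull(lab, id)
    dmax <- max(stats::dist(h)) + 1
    out <- c(out, dmax * pixel_size_um)
  }
  out
}

#' Aggregate-size statistics with quality flags
#'
#' Mean and SD of the Feret diameters, a size-risk flag when the mean or any
#' single aggregate exceeds the necrosis threshold (aggregates beyond about
#' 300 um develop hypoxic, necrotic cores), and an undersampling flag when
#' fewer than `min_n` aggregates were measured.
#'
#' @param ferets_um Feret diameters, um (possibly empty).
#' @param threshold_um Necrosis-risk size threshold, um (default 300).
#' @param min_n Minimum number of aggregates for a reliable estimate
#'   (default 200).
#' @return An object of class `aggregate_stats`: `feret_um`, `count`,
#'   `mean_um`, `sd_um`, `size_risk`, `undersampled`.
#' @export
aggregate_stats <- function(ferets_um, threshold_um = 300, min_n = 200) {
  count <- length(ferets_um)
  structure(list(feret_um = ferets_um, count = count,
                 mean_um = if (count) mean(ferets_um) else NA_real_,
                 sd_um = if (count > 1) stats::sd(ferets_um) else NA_real_,
                 size_risk = count > 0 &&
                   (mean(ferets_um) > threshold_um ||
                    any(ferets_um > threshold_um)),
                 undersampled = count < min_n,
                 threshold_um = threshold_um, min_n = min_n),
            class = "aggregate_stats")
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat(sprintf("aggregate_stats: n = %d, Feret %.1f +/- %.1f um\n",
              x$count, x$mean_um, x$sd_um))
  if (isTRUE(x$size_risk))
    cat(sprintf("  size-risk flag: aggregates exceed %g um\n", x$threshold_um))
  if (isTRUE(x$undersampled))
    cat(sprintf("  undersampled flag: fewer than %d aggregates\n", x$min_n))
  invisible(x)
}
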