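# Synthetic brightfield-like images of cell aggregates: bright shapes of
# known maximum Feret diameter (disc: diameter; square of side s: s*sqrt(2);
# ellipse: major axis) on a dark background, for validating segmentation and
# morphometry.

#' Specify shapes for a synthetic aggregate image
#'
#' @param kind `"disc"`, `"square"` or `"ellipse"` per shape.
#' @param cx,cy Centers, pixels (x = column, y = row).
#' @param size Disc diameter, square side, or ellipse major-axis length, px.
#' @param size2 Ellipse minor-axis length, px (ignored otherwise).
#' @param angle_deg Rotation of squares/ellipses, degrees (default 0).
#' @return A data frame of class `aggregate_shapes`.
#' @export
aggregate_shapes <- function(kind, cx, cy, size, size2 = NA, angle_deg = 0) {
  df <- data.frame(kind = kind, cx = cx, cy = cy, size = size,
                   size2 = size2, angle_deg = angle_deg,
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% c("disc", "square", "ellipse")))
    stop("kind must be disc, square or ellipse")
  if (any(df$size <= 0)) stop("shape sizes must be positive")
  if (any(df$kind == "ellipse" & (is.na(df$size2) | df$size2 <= 0)))
    stop("ellipses need a positive minor axis (size2)")
  class(df) <- c("aggregate_shapes", "data.frame")
  df
}

# True maximum Feret diameter of one shape row, px.
.true_feret <- function(row) {
  switch(row$kind,
         disc = row$size,
         square = row$size * sqrt(2),
         ellipse = max(row$size, row$size2))
}

# Enclosing-circle radius, used for the overlap warning.
.enclosing_radius <- function(row) .true_feret(row) / 2

#' Generate a synthetic aggregate image with known Feret diameters
#'
#' Renders the shapes as bright foreground (intensity 1) on dark background
#' (intensity 0), adds optional Gaussian noise, and returns the true maximum
#' Feret diameter of each shape.  Overlapping shapes trigger a warning since
#' connected-component analysis then merges them.
#'
#' @param shapes An [aggregate_shapes()] table.
#' @param height_px,width_px Image dimensions, pixels.
#' @param noise_sd Gaussian noise SD (intensity units; foreground is 1).
#' @param seed Seed for the noise.
#' @return A list with `image` (numeric matrix) and `feret_true_px`
#'   (one value per shape, in the order given).
#' @export
generate_aggregate_image <- function(shapes, height_px, width_px,
                                     noise_sd = 0, seed = 1L) {
  stopifnot(inherits(shapes, "aggregate_shapes"))
  n <- nrow(shapes)
  for (i in seq_len(n)) {
    r <- .enclosing_radius(shapes[i, ])
    if (shapes$cx[i] - r < 1 || shapes$cx[i] + r > width_px ||
        shapes$cy[i] - r < 1 || shapes$cy[i] + r > height_px)
      stop(sprintf("shape %d extends beyond the image bounds", i))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dd <- sqrt((shapes$cx[i] - shapes$cx[j])^2 +
                 (shapes$cy[i] - shapes$cy[j])^2)
      if (dd < .enclosing_radius(shapes[i, ]) + .enclosing_radius(shapes[j, ]))
        warning(sprintf(paste0("shapes %d and %d may overlap; per-shape ",
                               "ground truth is then unreliable"), i, j))
    }
  }
  xx <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  yy <- matrix(seq_len(height_px), height_px, width_px)
  img <- matrix(0, height_px, width_px)
  for (i in seq_len(n)) {
    s <- shapes[i, ]
    th <- s$angle_deg * pi / 180
    u <- (xx - s$cx) * cos(th) + (yy - s$cy) * sin(th)
    v <- -(xx - s$cx) * sin(th) + (yy - s$cy) * cos(th)
    inside <- switch(s$kind,
      disc = u^2 + v^2 <= (s$size / 2)^2,
      square = abs(u) <= s$size / 2 & abs(v) <= s$size / 2,
      ellipse = (u / (s$size / 2))^2 + (v / (s$size2 / 2))^2 <= 1)
    img[inside] <- 1
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed,
      matrix(stats::rnorm(length(img), sd = noise_sd), height_px, width_px))
  feret <- vapply(seq_len(n), function(i) .true_feret(shapes[i, ]), 0)
  list(image = img, feret_true_px = feret)
}
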