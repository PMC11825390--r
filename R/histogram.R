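# Fixed-grid color histograms.
#
# The color space is divided into bins_per_channel equal intervals per
# channel (default 2, hence 8 boxes). Channel ranges are fixed by the
# space — CIELAB: L in [0,100], a and b in [-100,100]; RGB: each channel in
# [0,1] — so bin centers are the same for every image (with two bins per
# channel: L in {25,75}, a,b in {-50,50}; RGB channels in {0.25,0.75}).
# Bins are half-open [lo, hi) with the final bin closed on top, so a value
# exactly on an interior boundary belongs to the upper bin. Conversion
# output slightly outside the nominal a/b range is kept in the edge bins.
#
# Bin index is 1 + i1 + n*i2 + n^2*i3 over the 0-based per-channel indices
# (first channel varies fastest), matching the row order in which results
# are reported.

.space_ranges <- function(space) {
  switch(space,
    lab = list(lo = c(0, -100, -100), hi = c(100, 100, 100)),
    rgb = list(lo = c(0, 0, 0), hi = c(1, 1, 1)),
    stop(sprintf("unknown color space '%s' (use 'lab' or 'rgb')", space),
         call. = FALSE)
  )
}

.match_space <- function(space) {
  space <- tolower(space)
  if (space %in% c("cielab", "lab")) return("lab")
  if (space %in% c("rgb", "srgb")) return("rgb")
  stop(sprintf("unknown color space '%s' (use 'lab' or 'rgb')", space),
       call. = FALSE)
}

#' Bin foreground pixels into a normalized color histogram
#'
#' Converts foreground pixels to the chosen space (CIELAB via
#' [rgb_to_lab()]; RGB used as-is) and tallies them on a fixed grid of
#' `bins_per_channel^3` boxes. Every box is reported, occupied or not:
#' a non-empty bin's representative color is the per-channel mean of its
#' member pixels, while an empty bin reports its geometric center with
#' proportion 0. Proportions are counts over the total foreground pixel
#' count and sum to 1.
#'
#' @param fg `n x 3` matrix of foreground sRGB pixels (from
#'   [mask_background()]).
#' @param space `"lab"` (CIELAB, the default) or `"rgb"`.
#' @param bins_per_channel number of intervals per channel (default 2).
#' @return an object of class `color_histogram`: a data frame with one row
#'   per bin (`bin`, the three coordinate columns, `center.1..3`, `count`,
#'   `Pct`) and attributes `space`, `bins_per_channel`, `total_pixels`.
#'   Coordinate columns are `L,a,b` or `r,g,b` and hold the representative
#'   color.
#' @examples
#' fg <- matrix(rep(c(0.9, 0.8, 0.3), 5), ncol = 3, byrow = TRUE)
#' build_histogram(fg, space = "lab")
#' @export
build_histogram <- function(fg, space = c("lab", "rgb"),
                            bins_per_channel = 2L) {
  space <- .match_space(if (missing(space)) "lab" else space[1])
  if (!is.matrix(fg)) fg <- .as_color_matrix(fg, c("r", "g", "b"))
  if (nrow(fg) == 0L) {
    stop("build_histogram(): no foreground pixels", call. = FALSE)
  }
  nb <- as.integer(bins_per_channel)
  if (is.na(nb) || nb < 1L) {
    stop("bins_per_channel must be a positive integer", call. = FALSE)
  }
  coords <- if (space == "lab") rgb_to_lab(fg) else fg
  rng <- .space_ranges(space)
  width <- (rng$hi - rng$lo) / nb

  # 0-based per-channel interval index, clamped so that values on or past
  # the outer edges stay in the edge bins (final bin closed on top)
  idx <- sapply(1:3, function(k) {
    i <- floor((coords[, k] - rng$lo[k]) / width[k])
    pmin(pmax(i, 0), nb - 1L)
  })
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  bin <- 1L + idx[, 1] + nb * idx[, 2] + nb^2 * idx[, 3]

  n_bins <- nb^3
  counts <- tabulate(bin, nbins = n_bins)
  total <- nrow(coords)

  # geometric centers in the same index order (first channel fastest)
  ctr_1d <- lapply(1:3, function(k) {
    rng$lo[k] + (seq_len(nb) - 0.5) * width[k]
  })
  grid <- expand.grid(i1 = ctr_1d[[1]], i2 = ctr_1d[[2]], i3 = ctr_1d[[3]])
  centers <- as.matrix(grid)

  rep_coords <- centers
  occ <- which(counts > 0L)
  for (b in occ) {
    rep_coords[b, ] <- colMeans(coords[bin == b, , drop = FALSE])
  }

  cn <- if (space == "lab") c("L", "a", "b") else c("r", "g", "b")
  out <- data.frame(bin = seq_len(n_bins), rep_coords[, 1], rep_coords[, 2],
                    rep_coords[, 3], centers[, 1], centers[, 2],
                    centers[, 3], count = counts, Pct = counts / total)
  names(out)[2:7] <- c(cn, paste0("center.", cn))
  attr(out, "space") <- space
  attr(out, "bins_per_channel") <- nb
  attr(out, "total_pixels") <- total
  class(out) <- c("color_histogram", "data.frame")
  out
}

#' @export
print.color_histogram <- function(x, digits = 5, ...) {
  cat(sprintf("Color histogram (%s space, %d bins, %d pixels)\n",
              toupper(attr(x, "space")), nrow(x), attr(x, "total_pixels")))
  df <- as.data.frame(x)[, c(1:4, 8:9)]
  df$Pct <- sprintf("%.3f", df$Pct)
  print(format(df, digits = digits), row.names = FALSE, ...)
  invisible(x)
}
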