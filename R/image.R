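# Image loading and chroma-key background removal.
#
# Photographs come in with the background either already transparent (alpha
# channel) or filled with a bright-green key color; masking drops those
# pixels before any color statistics are computed.

#' Load a photograph as a pixel array
#'
#' Reads a PNG or JPEG image into an `height x width x 3` array of sRGB
#' intensities in \[0, 1\]. Grayscale images are promoted to three channels;
#' an alpha channel, when present, is preserved in the attribute `alpha`
#' (an `height x width` matrix of opacities in \[0, 1\]).
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return numeric array `c(height, width, 3)` with optional attribute
#'   `alpha`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop(sprintf(
                     "cannot read '%s': corrupted or not a valid PNG (%s)",
                     path, conditionMessage(e)), call. = FALSE)),
    jpg = ,
    jpeg = tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop(sprintf(
                      "cannot read '%s': corrupted or not a valid JPEG (%s)",
                      path, conditionMessage(e)), call. = FALSE)),
    stop(sprintf("unsupported image format '.%s' (use PNG or JPEG)", ext),
         call. = FALSE)
  )
  alpha <- NULL
  if (length(dim(img)) == 2L) {
    # grayscale: promote to 3 identical channels
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] == 2L) {
    # gray + alpha
    alpha <- img[, , 2L]
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  } else if (dim(img)[3] == 4L) {
    alpha <- img[, , 4L]
    img <- img[, , 1:3, drop = FALSE]
  }
  out <- img[, , 1:3, drop = FALSE]
  attr(out, "alpha") <- alpha
  attr(out, "path") <- path
  out
}

#' Default chroma-key bounds for a bright-green background
#'
#' The background of a fungal photograph is keyed on bright green: a pixel
#' whose channels all fall inside `[lower, upper]` (inclusive) is treated as
#' background. The default interval is centered on pure green `(0, 1, 0)`
#' and wide enough to absorb compression artifacts around the key color.
#'
#' @param lower,upper numeric RGB triples in \[0, 1\] with
#'   `lower <= upper` channel-wise.
#' @return a list with elements `lower` and `upper`.
#' @export
background_bounds <- function(lower = c(0, 0.55, 0),
                              upper = c(0.24, 1, 0.24)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L) {
    stop("background bounds must be RGB triples", call. = FALSE)
  }
  if (any(lower < 0 | upper > 1 | lower > upper)) {
    stop("background bounds must satisfy 0 <= lower <= upper <= 1 per channel",
         call. = FALSE)
  }
  list(lower = lower, upper = upper)
}

#' Remove background pixels from an image
#'
#' Flattens an image to its non-background pixels. A pixel is background iff
#' its alpha (when the image has one) falls below `alpha_cutoff`, or all
#' three channels lie inside the chroma-key interval `bounds` (inclusive).
#'
#' @param img array from [load_image()] (or any `h x w x 3` array in
#'   \[0, 1\], optionally with an `alpha` attribute).
#' @param bounds chroma-key interval from [background_bounds()].
#' @param alpha_cutoff opacity below which a pixel counts as background.
#' @return an `n x 3` matrix of foreground sRGB pixels (columns `r,g,b`).
#' @examples
#' img <- array(c(0, 0.8, 1, 0.2, 0, 0.2), dim = c(1, 2, 3))
#' nrow(mask_background(img))   # the pure-green pixel is dropped
#' @export
mask_background <- function(img, bounds = background_bounds(),
                            alpha_cutoff = 0.5) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) {
    stop("img must be an h x w x 3 array", call. = FALSE)
  }
  px <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
              as.vector(img[, , 3L]))
  bg <- px[, 1] >= bounds$lower[1] & px[, 1] <= bounds$upper[1] &
        px[, 2] >= bounds$lower[2] & px[, 2] <= bounds$upper[2] &
        px[, 3] >= bounds$lower[3] & px[, 3] <= bounds$upper[3]
  alpha <- attr(img, "alpha")
  if (!is.null(alpha)) bg <- bg | as.vector(alpha) < alpha_cutoff
  fg <- px[!bg, , drop = FALSE]
  if (nrow(fg) == 0L) {
    stop(paste("no foreground pixels remain after masking;",
               "adjust the background bounds or alpha cutoff"),
         call. = FALSE)
  }
  colnames(fg) <- c("r", "g", "b")
  fg
}
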