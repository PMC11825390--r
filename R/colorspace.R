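# sRGB <-> CIELAB conversion, D65 illuminant, 2 degree observer.
#
# All conversions are exact double-precision implementations of the CIE
# pipeline: sRGB decompanding -> linear RGB -> XYZ (sRGB primaries) ->
# CIELAB against the D65 white point. No lookup tables, no clamping of
# L*/a*/b* to nominal display ranges.

# sRGB (D65) RGB -> XYZ matrix and its inverse; white point XYZ for D65/2deg.
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.D65_WHITE <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)
# Row-normalize so that RGB (1,1,1) maps exactly onto the D65 white point;
# the published 7-digit constants are off by ~1e-7, which would leave
# neutral grays with tiny nonzero a*/b*.
.SRGB_TO_XYZ <- .SRGB_TO_XYZ * (.D65_WHITE / rowSums(.SRGB_TO_XYZ))
.XYZ_TO_SRGB <- solve(.SRGB_TO_XYZ)
.CIE_DELTA <- 6 / 29

#' Convert sRGB colors to CIELAB
#'
#' Applies the standard CIE pipeline under the D65 illuminant (2 degree
#' observer): inverse sRGB companding, linear RGB to XYZ through the sRGB
#' primaries, then XYZ to CIELAB with the piecewise cube-root function.
#' L* lies in \[0, 100\]; a* and b* are nominally in \[-100, 100\] but are
#' never clamped, since saturated colors near the gamut edge can exceed the
#' nominal range and clamping would distort color distances.
#'
#' @param rgb numeric vector of length 3, or an n x 3 matrix, of sRGB
#'   channel intensities in \[0, 1\].
#' @return a numeric matrix with columns `L`, `a`, `b` (one row per input
#'   color); a single input vector still yields a 1 x 3 matrix.
#' @examples
#' rgb_to_lab(c(1, 1, 1))      # white: L = 100, a = b = 0
#' rgb_to_lab(c(0.5, 0.5, 0.5))
#' @seealso [lab_to_rgb()] for the inverse.
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- .as_color_matrix(rgb, c("r", "g", "b"))
  if (anyNA(rgb) || any(rgb < 0 | rgb > 1)) {
    stop("rgb_to_lab(): all sRGB channels must be finite and in [0, 1]",
         call. = FALSE)
  }
  lin <- .srgb_decompand(rgb)
  xyz <- lin %*% t(.SRGB_TO_XYZ)
  t3 <- sweep(xyz, 2, .D65_WHITE, "/")
  f <- .cie_f(t3)
  out <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  out
}

#' Convert CIELAB colors to sRGB
#'
#' Exact inverse of [rgb_to_lab()] for in-gamut colors. Colors that fall
#' outside the sRGB gamut are clipped channel-wise to \[0, 1\]; the returned
#' matrix then carries the attribute `clipped`, a logical vector marking the
#' rows that required clipping. Clipping is a flagged post-condition, not an
#' error, so that reference-chart swatches can always be rendered.
#'
#' @param lab numeric vector of length 3, or an n x 3 matrix, of
#'   CIELAB coordinates (`L`, `a`, `b`).
#' @return numeric matrix with columns `r`, `g`, `b` in \[0, 1\] and a
#'   logical attribute `clipped` of length n.
#' @examples
#' lab_to_rgb(c(100, 0, 0))          # white
#' out <- lab_to_rgb(c(50, 120, -120))
#' attr(out, "clipped")              # TRUE: outside the sRGB gamut
#' @export
lab_to_rgb <- function(lab) {
  lab <- .as_color_matrix(lab, c("L", "a", "b"))
  if (anyNA(lab) || any(!is.finite(lab))) {
    stop("lab_to_rgb(): CIELAB coordinates must be finite", call. = FALSE)
  }
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.cie_f_inv(fx), .cie_f_inv(fy), .cie_f_inv(fz))
  xyz <- sweep(xyz, 2, .D65_WHITE, "*")
  lin <- xyz %*% t(.XYZ_TO_SRGB)
  rgb <- .srgb_compand(lin)
  clipped <- apply(rgb < 0 | rgb > 1, 1, any)
  rgb <- pmin(pmax(rgb, 0), 1)
  colnames(rgb) <- c("r", "g", "b")
  attr(rgb, "clipped") <- unname(clipped)
  rgb
}

# Coerce a length-3 vector or n x 3 matrix/data.frame to an unnamed matrix.
.as_color_matrix <- function(x, cols) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L) {
      stop("expected a 3-channel color or an n x 3 matrix", call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) {
    stop("expected a 3-channel color or an n x 3 matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, cols)
  x
}

.srgb_decompand <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

# Companding of linear RGB; negative linear values (out of gamut) fall in the
# linear branch and end up negative, to be clipped by the caller.
.srgb_compand <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * pmax(u, 0)^(1 / 2.4) - 0.055)
}

.cie_f <- function(t3) {
  ifelse(t3 > .CIE_DELTA^3, t3^(1 / 3), t3 / (3 * .CIE_DELTA^2) + 4 / 29)
}

.cie_f_inv <- function(f) {
  ifelse(f > .CIE_DELTA, f^3, 3 * .CIE_DELTA^2 * (f - 4 / 29))
}
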