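# Methods for "color_match" objects.

#' @export
print.color_match <- function(x, ...) {
  cat(sprintf("Color match (%s space, %s distance, %d foreground pixels)\n",
              toupper(x$space), x$metric, x$total_pixels))
  df <- .label_view(x, "ColorName")
  df$Pct <- sprintf("%.3f", df$Pct)
  for (k in 1:3) df[[k]] <- sprintf("%.5f", df[[k]])
  print(df, ...)
  invisible(x)
}

#' Summarize a color match
#'
#' Reports the dominant bin (highest pixel proportion, earliest bin on
#' ties), its matched color name, hue group and pigment classes, and the
#' share of foreground pixels it holds.
#'
#' @param object a `color_match` from [match_colors()].
#' @param ... unused.
#' @return `object`, invisibly; prints the summary.
#' @export
summary.color_match <- function(object, ...) {
  m <- object$matches
  i <- which.max(m$Pct)
  cat(sprintf("Image: %s\n", if (is.null(object$image)) "<array>"
              else object$image))
  cat(sprintf("Space: %s   Metric: %s   Foreground pixels: %d\n",
              toupper(object$space), object$metric, object$total_pixels))
  cat(sprintf("Dominant color: %s (bin %d, %.1f%% of pixels)\n",
              m$ColorName[i], m$bin[i], 100 * m$Pct[i]))
  cat(sprintf("Hue group: %s\n", m$HueGroup[i]))
  pig <- m$Pigments[[i]]
  cat(sprintf("Associated pigments: %s\n",
              if (length(pig)) paste(pig, collapse = "; ") else "(none known)"))
  occupied <- m[m$Pct > 0, c("bin", "ColorName", "HueGroup", "Pct")]
  occupied$Pct <- sprintf("%.3f", occupied$Pct)
  cat("\nOccupied bins:\n")
  print(occupied, row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.color_match <- function(x, ...) {
  out <- x$matches
  out$Pigments <- vapply(out$Pigments, paste, character(1), collapse = "; ")
  rownames(out) <- NULL
  out
}

#' Plot a color match
#'
#' Draws the per-bin pixel proportions as a bar chart, each bar filled with
#' the sRGB swatch of the matched reference color and labelled by bin
#' index. This is the histogram panel of the standard result display.
#'
#' @param x a `color_match`.
#' @param main plot title.
#' @param ... further arguments to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot.color_match <- function(x, main = NULL, ...) {
  m <- x$matches
  if (is.null(main)) {
    main <- sprintf("Pixel proportions by bin (%s, %s)",
                    toupper(x$space), x$metric)
  }
  mids <- graphics::barplot(m$Pct, names.arg = m$bin, col = m$Swatch,
                            border = "grey30", xlab = "Bin",
                            ylab = "Proportion of pixels", main = main, ...)
  invisible(mids)
}

#' Export foreground pixel coordinates for scatter plotting
#'
#' Returns the non-background pixels of an image in the chosen space (the
#' data behind the usual 3D pixel-cloud panel), optionally writing them to
#' delimited text.
#'
#' @inheritParams match_colors
#' @param out optional path; when given, the coordinates are written as CSV.
#' @return a data frame of pixel coordinates (`L,a,b` or `r,g,b`),
#'   invisibly when `out` is given.
#' @export
pixel_coordinates <- function(image, space = c("lab", "rgb"),
                              bounds = background_bounds(),
                              alpha_cutoff = 0.5, out = NULL) {
  space <- .match_space(if (missing(space)) "lab" else space[1])
  img <- if (is.character(image)) load_image(image) else image
  fg <- mask_background(img, bounds = bounds, alpha_cutoff = alpha_cutoff)
  coords <- if (space == "lab") rgb_to_lab(fg) else fg
  df <- as.data.frame(coords)
  if (!is.null(out)) {
    utils::write.csv(df, out, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Write a result table to delimited text
#'
#' Serializes the 8-row result of [rayner_color()], [hue_groups()] or
#' [fungal_pigments()] (or a full `color_match`) with display rounding:
#' coordinates to 5 decimals, `Pct` to 3 decimals. Proportions are kept at
#' full precision inside the objects; rounding happens only here.
#'
#' @param result a data frame from one of the result entry points, or a
#'   `color_match`.
#' @param path output file path.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, sep = ",") {
  if (inherits(result, "color_match")) result <- as.data.frame(result)
  out <- result
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- if (nm == "Pct") sprintf("%.3f", out[[nm]])
                   else sprintf("%.5f", out[[nm]])
    }
  }
  if ("bin" %in% names(result)) out$bin <- result$bin
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
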