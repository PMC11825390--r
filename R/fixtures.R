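# Synthetic fixtures: swatch images with a chroma-key background, a
# miniature reference chart, and labelled datasets with known ground truth.
# Everything is deterministic given a seed, so the full pipeline can be
# exercised end-to-end with no external data.

#' Specification of a synthetic swatch image
#'
#' Describes a flat-color test image: the left `ceiling(fg_fraction * width)`
#' columns hold the foreground color (plus optional i.i.d. Gaussian noise
#' per channel, clipped to \[0, 1\]) and the rest the background color
#' (pure chroma-key green by default).
#'
#' @param fg_color foreground sRGB triple in \[0, 1\].
#' @param bg_color background sRGB triple (default pure green `(0, 1, 0)`).
#' @param fg_fraction fraction of columns occupied by foreground, in (0, 1].
#' @param width,height image size in pixels.
#' @param noise_sd per-channel Gaussian noise standard deviation (>= 0).
#' @param seed integer seed; identical specs produce identical image bytes.
#' @return a list of class `swatch_spec`.
#' @export
swatch_spec <- function(fg_color, bg_color = c(0, 1, 0), fg_fraction = 1,
                        width = 20L, height = 20L, noise_sd = 0,
                        seed = 1L) {
  fg_color <- as.numeric(fg_color); bg_color <- as.numeric(bg_color)
  stopifnot(length(fg_color) == 3L, length(bg_color) == 3L,
            all(fg_color >= 0 & fg_color <= 1),
            all(bg_color >= 0 & bg_color <= 1),
            fg_fraction > 0, fg_fraction <= 1,
            width >= 1, height >= 1, noise_sd >= 0)
  structure(list(fg_color = fg_color, bg_color = bg_color,
                 fg_fraction = fg_fraction, width = as.integer(width),
                 height = as.integer(height), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "swatch_spec")
}

#' Write a synthetic swatch image to PNG
#'
#' @param spec a [swatch_spec()].
#' @param out output PNG path.
#' @return `out`, invisibly.
#' @examples
#' p <- make_swatch_image(swatch_spec(c(0.8, 0.2, 0.2), fg_fraction = 0.6,
#'                                    width = 10, height = 10),
#'                        tempfile(fileext = ".png"))
#' nrow(mask_background(load_image(p)))   # 60 foreground pixels
#' @export
make_swatch_image <- function(spec, out = tempfile(fileext = ".png")) {
  stopifnot(inherits(spec, "swatch_spec"))
  w <- spec$width; h <- spec$height
  n_fg_cols <- ceiling(spec$fg_fraction * w)
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    img[, , k] <- spec$bg_color[k]
    img[, seq_len(n_fg_cols), k] <- spec$fg_color[k]
  }
  if (spec$noise_sd > 0) {
    # noise only on the foreground block, restorable via the seed
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    n <- h * n_fg_cols
    for (k in 1:3) {
      noise <- stats::rnorm(n, 0, spec$noise_sd)
      block <- img[, seq_len(n_fg_cols), k] + noise
      img[, seq_len(n_fg_cols), k] <- pmin(pmax(block, 0), 1)
    }
  }
  png::writePNG(img, out)
  invisible(out)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a miniature reference chart
#'
#' Constructs a [lookup_table] from `(name, lab, hue, pigments)` entries,
#' deriving the RGB columns via [lab_to_rgb()] (clipped to the sRGB gamut
#' where necessary) — or from RGB coordinates with LAB derived via
#' [rgb_to_lab()] when `rgb` is given instead of `lab` for an entry.
#'
#' @param entries a list; each element is a list with fields `name`,
#'   `hue`, optional `pigments` (character vector), and exactly one of
#'   `lab` or `rgb` (numeric triple).
#' @return a validated [lookup_table] with source `"fixture"`.
#' @seealso [fixture_lookup()] for the bundled default chart.
#' @export
make_fixture_table <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  n <- length(entries)
  lab <- matrix(NA_real_, n, 3)
  rgb <- matrix(NA_real_, n, 3)
  name <- character(n); hue <- character(n)
  pigments <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entries[[i]]
    name[i] <- e$name
    hue[i] <- e$hue
    pigments[[i]] <- if (is.null(e$pigments)) character(0) else e$pigments
    if (!is.null(e$lab)) {
      lab[i, ] <- e$lab
      rgb[i, ] <- lab_to_rgb(e$lab)[1, ]
    } else if (!is.null(e$rgb)) {
      rgb[i, ] <- e$rgb
      lab[i, ] <- rgb_to_lab(e$rgb)[1, ]
    } else {
      stop(sprintf("entry %d needs a 'lab' or 'rgb' field", i), call. = FALSE)
    }
  }
  lookup_table(name, lab, rgb, hue, pigments, source = "fixture")
}

#' The bundled miniature reference chart
#'
#' A 16-entry synthetic chart used throughout the tests and examples: one
#' entry sits exactly at each of the 8 default CIELAB bin centers
#' (L in \{25, 75\}, a, b in \{-50, 50\}) and one exactly at each of the 8
#' default RGB bin centers (channels in \{0.25, 0.75\}). Hues span the five
#' validation categories plus compound groups, and pigments span the
#' classic fungal pigment classes (azaphilones, naphthoquinone, xylindein,
#' melanin, carotenoid). The names are synthetic, not Rayner's.
#'
#' The same table ships as delimited text at
#' `system.file("extdata", "mini_rayner.csv", package = "mycocolor")`.
#'
#' @return a [lookup_table] with 16 entries.
#' @export
fixture_lookup <- function() {
  rgb_entries <- list(
    list(name = "Dusk Slate",      rgb = c(0.25, 0.25, 0.25),
         hue = "purple-blue", pigments = "melanin"),
    list(name = "Brick Red",       rgb = c(0.75, 0.25, 0.25),
         hue = "red", pigments = "azaphilones"),
    list(name = "Parrot Green",    rgb = c(0.25, 0.75, 0.25),
         hue = "green", pigments = character(0)),
    list(name = "Citrine Yellow",  rgb = c(0.75, 0.75, 0.25),
         hue = "yellow", pigments = "carotenoid"),
    list(name = "Gentian Blue",    rgb = c(0.25, 0.25, 0.75),
         hue = "blue", pigments = character(0)),
    list(name = "Orchid Purple",   rgb = c(0.75, 0.25, 0.75),
         hue = "purple", pigments = c("naphthoquinone", "polyketide")),
    list(name = "Verdigris",       rgb = c(0.25, 0.75, 0.75),
         hue = "blue-green", pigments = "xylindein"),
    list(name = "Pearl Plumbeous", rgb = c(0.75, 0.75, 0.75),
         hue = "purple-blue", pigments = character(0))
  )
  lab_entries <- list(
    list(name = "Abyss Teal",        lab = c(25, -50, -50),
         hue = "blue-green", pigments = "xylindein"),
    list(name = "Glacier Cyan",      lab = c(75, -50, -50),
         hue = "blue-green", pigments = "xylindein"),
    list(name = "Midnight Violet",   lab = c(25, 50, -50),
         hue = "purple-blue", pigments = "naphthoquinone"),
    list(name = "Light Phlox",       lab = c(75, 50, -50),
         hue = "purple", pigments = "naphthoquinone"),
    list(name = "Calliste Deep",     lab = c(25, -50, 50),
         hue = "green", pigments = character(0)),
    list(name = "Meadow Chartreuse", lab = c(75, -50, 50),
         hue = "green-yellow", pigments = "carotenoid"),
    list(name = "Mars Umber",        lab = c(25, 50, 50),
         hue = "yellow-red", pigments = "melanin"),
    list(name = "Apricot Buff",      lab = c(75, 50, 50),
         hue = "yellow-red", pigments = "carotenoid")
  )
  make_fixture_table(c(rgb_entries, lab_entries))
}

#' Generate a labelled synthetic dataset of swatch images
#'
#' Samples entries (with replacement) from a reference chart, writes one
#' noise-perturbed swatch image per draw with that entry's RGB color as
#' foreground on the chroma-key green background, and records the entry's
#' collapsed hue as the ground-truth label. Deterministic given `seed`.
#'
#' By default entries are drawn from the 8 RGB-bin-center colors of
#' [fixture_lookup()], whose stored LAB and RGB coordinates are exact
#' inverses of each other, so a zero-noise dataset is recovered perfectly
#' in either color space.
#'
#' @param n number of images (>= 1).
#' @param noise_sd per-channel Gaussian noise sd for the foreground.
#' @param seed integer seed controlling sampling and noise.
#' @param dir output directory (created if missing).
#' @param table chart to sample from.
#' @param entry_names names of the chart entries eligible for sampling;
#'   default the 8 RGB-derived fixture entries.
#' @param width,height,fg_fraction swatch geometry.
#' @param mapping hue-collapse overrides, see [collapse_hue()].
#' @return a data frame (the manifest) with columns `path`, `expected_hue`,
#'   and `color_name`; also written to `manifest.csv` inside `dir`.
#' @export
make_labeled_dataset <- function(n, noise_sd = 0, seed = 1L,
                                 dir = tempfile("swatches"),
                                 table = fixture_lookup(),
                                 entry_names = NULL,
                                 width = 16L, height = 16L,
                                 fg_fraction = 0.75, mapping = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  validate_lookup(table)
  if (is.null(entry_names)) {
    entry_names <- c("Dusk Slate", "Brick Red", "Parrot Green",
                     "Citrine Yellow", "Gentian Blue", "Orchid Purple",
                     "Verdigris", "Pearl Plumbeous")
    entry_names <- intersect(entry_names, table$Color)
    if (!length(entry_names)) entry_names <- table$Color
  }
  if (!all(entry_names %in% table$Color)) {
    stop("entry_names must all appear in the lookup table", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  picks <- sample(entry_names, n, replace = TRUE)
  img_seeds <- sample.int(.Machine$integer.max, n)

  rows <- match(picks, table$Color)
  paths <- file.path(dir, sprintf("swatch_%03d.png", seq_len(n)))
  for (i in seq_len(n)) {
    spec <- swatch_spec(
      fg_color = c(table$R[rows[i]], table$G[rows[i]], table$B.1[rows[i]]),
      fg_fraction = fg_fraction, width = width, height = height,
      noise_sd = noise_sd, seed = img_seeds[i]
    )
    make_swatch_image(spec, paths[i])
  }
  manifest <- data.frame(
    path = paths,
    expected_hue = collapse_hue(table$HueGroup[rows], mapping),
    color_name = picks,
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
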