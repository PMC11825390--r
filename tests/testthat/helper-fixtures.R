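# Shared fixtures for the test suite. Everything is generated in code; the
# only file fixture is the bundled miniature chart CSV.

mini_chart <- function() fixture_lookup()

mini_chart_path <- function() {
  system.file("extdata", "mini_rayner.csv", package = "mycocolor")
}

# A flat-color swatch PNG; returns its path.
swatch_png <- function(fg, fg_fraction = 1, width = 10, height = 10,
                       noise_sd = 0, seed = 1L, bg = c(0, 1, 0)) {
  make_swatch_image(
    swatch_spec(fg_color = fg, bg_color = bg, fg_fraction = fg_fraction,
                width = width, height = height, noise_sd = noise_sd,
                seed = seed),
    tempfile(fileext = ".png")
  )
}

# Write a chart CSV from a data frame of raw fields (for malformed-input
# tests that must bypass the validating constructor).
raw_chart_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  con <- file(path, "w")
  writeLines("Color,L,A,B,HueGroup,ClassOfCompounds,R,G,B", con)
  writeLines(apply(df, 1, paste, collapse = ","), con)
  close(con)
  path
}

# One valid raw chart row as a character vector, overridable per field.
raw_row <- function(name = "Swatch", L = 50, A = 0, B = 0, hue = "red",
                    pig = "", R = 0.5, G = 0.5, B2 = 0.5) {
  c(name, L, A, B, hue, pig, R, G, B2)
}

# Brute-force nearest-entry oracle: independent of the package's scan.
brute_nearest <- function(coords, table, space, metric) {
  m <- if (space == "lab") {
    cbind(table$L, table$A, table$B)
  } else {
    cbind(table$R, table$G, table$B.1)
  }
  d <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    x <- coords; y <- m[i, ]
    d[i] <- if (metric == "euclidean") {
      sqrt(sum((x - y)^2))
    } else {
      s <- 0
      for (k in 1:3) {
        den <- x[k] + y[k]
        if (den != 0) s <- s + (x[k] - y[k])^2 / den
      }
      s
    }
  }
  i <- which(d == min(d))[1]
  list(row = i, name = table$Color[i], distance = d[i])
}

# Brute-force per-channel interval finder for histogram bin assignment.
brute_bin <- function(coord, lo, hi, nb) {
  idx <- integer(3)
  for (k in 1:3) {
    edges <- seq(lo[k], hi[k], length.out = nb + 1)
    i <- NA_integer_
    for (j in seq_len(nb)) {
      # half-open [lo, hi), last bin closed on top
      if (coord[k] >= edges[j] &&
          (coord[k] < edges[j + 1] || (j == nb && coord[k] <= edges[j + 1]))) {
        i <- j - 1L
        break
      }
    }
    if (is.na(i)) i <- if (coord[k] < edges[1]) 0L else nb - 1L
    idx[k] <- i
  }
  as.integer(1L + idx[1] + nb * idx[2] + nb * nb * idx[3])
}
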