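# Image loading, chroma-key masking, and histogram binning.

test_that("PNG write/read is an identity on pixel values", {
  arr <- array(round(runif(48) * 255) / 255, dim = c(4, 4, 3))
  path <- tempfile(fileext = ".png")
  png::writePNG(arr, path)
  img <- load_image(path)
  expect_equal(img[, , 1:3], arr, tolerance = 1e-9, ignore_attr = TRUE)
  expect_null(attr(img, "alpha"))
})

test_that("RGBA and grayscale images are normalized to 3 channels + alpha", {
  rgba <- array(0.5, dim = c(3, 3, 4))
  rgba[, , 4] <- matrix(c(rep(1, 6), rep(0, 3)), 3, 3)
  path <- tempfile(fileext = ".png")
  png::writePNG(rgba, path)
  img <- load_image(path)
  expect_identical(dim(img), c(3L, 3L, 3L))
  expect_equal(attr(img, "alpha"), rgba[, , 4], tolerance = 1e-9)

  gray <- matrix(seq(0, 1, length.out = 9), 3, 3)
  path2 <- tempfile(fileext = ".png")
  png::writePNG(gray, path2)
  img2 <- load_image(path2)
  expect_identical(dim(img2), c(3L, 3L, 3L))
  expect_equal(img2[, , 1], img2[, , 3], tolerance = 1e-12)
})

test_that("unreadable or unsupported files raise input errors", {
  bad <- tempfile(fileext = ".png")
  writeBin(as.raw(1:20), bad)                    # truncated garbage
  expect_error(load_image(bad), "corrupted|valid PNG")
  txt <- tempfile(fileext = ".bmp")
  writeLines("x", txt)
  expect_error(load_image(txt), "unsupported image format")
  expect_error(load_image(tempfile(fileext = ".png")), "not found")
})

test_that("chroma-key masking separates foreground from green background", {
  # 10x10, left half pure green, right half reddish
  arr <- array(0, dim = c(10, 10, 3))
  arr[, 1:5, 2] <- 1
  arr[, 6:10, 1] <- 0.8
  arr[, 6:10, 2] <- 0.2
  arr[, 6:10, 3] <- 0.2
  fg <- mask_background(arr)
  expect_identical(nrow(fg), 50L)
  expect_true(all(abs(fg[, 1] - 0.8) < 1e-12))

  # degenerate interval lower = upper = (0,1,0) keeps everything not exactly green
  b <- background_bounds(lower = c(0, 1, 0), upper = c(0, 1, 0))
  arr2 <- array(runif(300, 0.1, 0.9), dim = c(10, 10, 3))
  expect_identical(nrow(mask_background(arr2, bounds = b)), 100L)
})

test_that("alpha below the cutoff is background; all-background errors", {
  arr <- array(0.5, dim = c(4, 4, 3))
  alpha <- matrix(1, 4, 4); alpha[, 1:2] <- 0
  attr(arr, "alpha") <- alpha
  expect_identical(nrow(mask_background(arr)), 8L)
  attr(arr, "alpha") <- matrix(0, 4, 4)
  expect_error(mask_background(arr), "no foreground pixels")
})

test_that("CIELAB histogram reports fixed centers for empty bins", {
  fg <- matrix(rep(c(0.9, 0.85, 0.4), 10), ncol = 3, byrow = TRUE)
  h <- build_histogram(fg, space = "lab")
  expect_identical(nrow(h), 8L)
  expect_equal(sum(h$Pct), 1, tolerance = 1e-12)
  # occupied bin: high L, a < 0, b > 0 -> index 6
  expect_identical(h$bin[h$count > 0], 6L)
  expect_equal(h$Pct[6], 1)
  # empty bins print their geometric centers
  expect_equal(h$L[1:5], c(25, 75, 25, 75, 25))
  expect_equal(h$a[1:4], c(-50, -50, 50, 50))
  expect_equal(h$b[1:5], c(-50, -50, -50, -50, 50))
  expect_equal(h$Pct[c(1:5, 7, 8)], rep(0, 7))
})

test_that("bin index ordering puts the first channel fastest", {
  # low-L, a>0, b>0 lands in row 7 (as in the worked 8-row output);
  # construct it from a color whose LAB sits at moderate L
  fg_low <- matrix(rep(c(0.62, 0.4, 0.1), 4), ncol = 3, byrow = TRUE)
  lab <- rgb_to_lab(fg_low[1, ])
  stopifnot(lab[1] < 50, lab[2] > 0, lab[3] > 0)
  h <- build_histogram(fg_low, space = "lab")
  expect_identical(h$bin[h$count > 0], 7L)
})

test_that("proportions count pixels and representatives are bin means", {
  fg <- rbind(
    matrix(rep(c(0.9, 0.85, 0.4), 60), ncol = 3, byrow = TRUE),  # bin 6
    matrix(rep(c(0.62, 0.4, 0.1), 40), ncol = 3, byrow = TRUE)   # bin 7
  )
  h <- build_histogram(fg, space = "lab")
  expect_equal(h$Pct[c(6, 7)], c(0.6, 0.4))
  expect_equal(sum(h$Pct), 1, tolerance = 1e-12)
  # single-color bin representative equals that color exactly
  expect_equal(unlist(h[6, c("L", "a", "b")]),
               rgb_to_lab(c(0.9, 0.85, 0.4))[1, ], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("bin assignment matches a brute-force interval oracle", {
  set.seed(11)
  for (space in c("lab", "rgb")) {
    for (nb in c(2L, 3L)) {
      fg <- matrix(runif(3 * 400), ncol = 3)
      h <- build_histogram(fg, space = space, bins_per_channel = nb)
      rng <- if (space == "lab") {
        list(lo = c(0, -100, -100), hi = c(100, 100, 100))
      } else {
        list(lo = c(0, 0, 0), hi = c(1, 1, 1))
      }
      coords <- if (space == "lab") rgb_to_lab(fg) else fg
      expected <- tabulate(
        vapply(seq_len(nrow(coords)),
               function(i) brute_bin(coords[i, ], rng$lo, rng$hi, nb),
               integer(1)),
        nbins = nb^3
      )
      expect_identical(h$count, expected)
    }
  }
})

test_that("boundary values go to the upper bin; edges stay in edge bins", {
  fg <- matrix(c(0.5, 0.25, 0.25), 1)   # first channel exactly on the boundary
  h <- build_histogram(fg, space = "rgb")
  expect_identical(h$bin[h$count > 0], 2L)   # upper bin of channel 1
  # channel value 1 stays in the last bin
  fg2 <- matrix(c(1, 1, 1), 1)
  h2 <- build_histogram(fg2, space = "rgb")
  expect_identical(h2$bin[h2$count > 0], 8L)
})

test_that("histograms are invariant to pixel order", {
  set.seed(3)
  fg <- matrix(runif(300), ncol = 3)
  h1 <- build_histogram(fg, space = "lab")
  h2 <- build_histogram(fg[sample(nrow(fg)), ], space = "lab")
  expect_equal(as.data.frame(h1), as.data.frame(h2), tolerance = 1e-12)
})

test_that("degenerate binning with one bin reports the overall mean", {
  set.seed(4)
  fg <- matrix(runif(60), ncol = 3)
  h <- build_histogram(fg, space = "rgb", bins_per_channel = 1L)
  expect_identical(nrow(h), 1L)
  expect_equal(h$Pct, 1)
  expect_equal(unlist(h[1, c("r", "g", "b")]), colMeans(fg),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("empty foreground is a precondition error", {
  expect_error(build_histogram(matrix(numeric(0), ncol = 3)),
               "no foreground pixels")
})
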