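# Distance metrics, nearest-entry search, and the three result views.

test_that("color_distance evaluates both metrics", {
  expect_identical(color_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(color_distance(c(1, 2, 2), c(0, 0, 0)), 3)
  expect_identical(color_distance(c(1, 0, 0), c(0, 1, 0), "chisq"), 2)
  # zero-denominator terms contribute 0
  expect_identical(color_distance(c(0, 0, 0), c(0, 0, 0), "chisq"), 0)
  # negative denominators (LAB coordinates) are computed as-is
  d <- color_distance(c(50, -60, 10), c(40, -20, 10), "chisq")
  expect_lt(d, 0)
  expect_error(color_distance(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("nearest_entry returns exact matches at distance 0", {
  tab <- mini_chart()
  hit <- nearest_entry(c(25, -50, -50), tab, space = "lab")
  expect_identical(hit$name, "Abyss Teal")
  expect_identical(hit$distance, 0)
  hit2 <- nearest_entry(c(0.75, 0.25, 0.25), tab, space = "rgb")
  expect_identical(hit2$name, "Brick Red")
  expect_identical(hit2$distance, 0)
})

test_that("nearest_entry agrees with a brute-force scan", {
  tab <- mini_chart()
  set.seed(19)
  for (i in 1:250) {
    space <- sample(c("lab", "rgb"), 1)
    metric <- sample(c("euclidean", "chisq"), 1)
    coords <- if (space == "lab") {
      c(runif(1, 0, 100), runif(2, -100, 100))
    } else {
      runif(3)
    }
    got <- nearest_entry(coords, tab, space, metric)
    want <- brute_nearest(coords, tab, space, metric)
    expect_identical(got$row, want$row)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("ties break to the earliest table row", {
  tab <- make_fixture_table(list(
    list(name = "First", lab = c(40, 10, 0), hue = "red"),
    list(name = "Second", lab = c(60, 10, 0), hue = "blue")
  ))
  hit <- nearest_entry(c(50, 10, 0), tab, space = "lab")
  expect_identical(hit$name, "First")
})

test_that("permuting table rows changes no labels away from ties", {
  tab <- mini_chart()
  set.seed(23)
  perm <- sample(nrow(tab))
  ptab <- lookup_table(tab$Color[perm],
                       cbind(tab$L, tab$A, tab$B)[perm, ],
                       cbind(tab$R, tab$G, tab$B.1)[perm, ],
                       tab$HueGroup[perm], tab$ClassOfCompounds[perm])
  for (i in 1:100) {
    coords <- c(runif(1, 0, 100), runif(2, -100, 100))
    expect_identical(nearest_entry(coords, tab, "lab")$name,
                     nearest_entry(coords, ptab, "lab")$name)
  }
})

test_that("the pipeline yields an 8-row table with Pct summing to 1", {
  p <- swatch_png(c(0.75, 0.25, 0.25), fg_fraction = 0.6)
  fit <- match_colors(p, space = "rgb", table = mini_chart())
  expect_s3_class(fit, "color_match")
  expect_identical(nrow(fit$matches), 8L)
  expect_equal(sum(fit$matches$Pct), 1, tolerance = 1e-12)
  # the foreground sits exactly on a chart color
  i <- which.max(fit$matches$Pct)
  expect_identical(fit$matches$ColorName[i], "Brick Red")
  expect_equal(fit$matches$Pct[i], 1)
  # PNG pixels are 8-bit, so the representative sits within one
  # quantization step of the chart color
  expect_lt(fit$matches$Distance[i], 2 / 255)
  # empty bins are matched from their centers, present with Pct 0
  expect_equal(sum(fit$matches$Pct == 0), 7L)
})

test_that("result rows stay in bin order, not sorted by Pct", {
  p <- swatch_png(c(0.9, 0.85, 0.4))
  df <- rayner_color(p, space = "lab", table = mini_chart())
  expect_equal(df$Pct[6], 1)         # occupied row sits at its bin position
  expect_equal(df$Pct[1:5], rep(0, 5))
  expect_equal(df$L[1:2], c(25, 75))
})

test_that("the three result views agree through hue_of/pigments_of", {
  tab <- mini_chart()
  set.seed(31)
  for (fg in list(c(0.75, 0.25, 0.75), c(0.2, 0.7, 0.3), runif(3))) {
    p <- swatch_png(fg, fg_fraction = 0.8)
    colors <- rayner_color(p, space = "lab", table = tab)
    hues <- hue_groups(p, space = "lab", table = tab)
    pigs <- fungal_pigments(p, space = "lab", table = tab)
    expect_identical(hues$HueGroup,
                     vapply(colors$ColorName, hue_of, character(1),
                            table = tab, USE.NAMES = FALSE))
    expect_identical(pigs$Pigments,
                     vapply(colors$ColorName, function(nm) {
                       paste(pigments_of(tab, nm), collapse = "; ")
                     }, character(1), USE.NAMES = FALSE))
    expect_identical(colors[, c("L", "a", "b", "Pct")],
                     hues[, c("L", "a", "b", "Pct")])
  }
})

test_that("entries with no pigments yield an empty label, not an error", {
  p <- swatch_png(c(0.25, 0.25, 0.75))   # Gentian Blue: no pigments
  pigs <- fungal_pigments(p, space = "rgb", table = mini_chart())
  i <- which.max(pigs$Pct)
  expect_identical(pigs$Pigments[i], "")
})

test_that("chisq and euclidean pick the same labels on well-separated RGB", {
  tab <- mini_chart()
  for (fg in list(c(0.75, 0.25, 0.25), c(0.25, 0.75, 0.75),
                  c(0.7, 0.7, 0.2))) {
    p <- swatch_png(fg)
    a <- rayner_color(p, space = "rgb", metric = "euclidean", table = tab)
    b <- rayner_color(p, space = "rgb", metric = "chisq", table = tab)
    expect_identical(a$ColorName, b$ColorName)
  }
})

test_that("more foreground pixels of a chart color raise its reported Pct", {
  tab <- mini_chart()
  pcts <- vapply(c(0.2, 0.5, 0.9), function(f) {
    p <- swatch_png(c(0.75, 0.75, 0.25), fg_fraction = f, width = 20,
                    height = 20, bg = c(0.1, 0.98, 0.1))
    fit <- match_colors(p, space = "rgb", table = tab)
    fit$matches$Pct[fit$matches$ColorName == "Citrine Yellow"]
  }, numeric(1))
  expect_identical(pcts, c(1, 1, 1))  # background masked: always full share

  # with an unmasked second color sharing the image, Pct grows with fraction
  pcts2 <- vapply(c(0.25, 0.5, 0.75), function(f) {
    p <- swatch_png(c(0.75, 0.75, 0.25), fg_fraction = f, width = 20,
                    height = 20, bg = c(0.75, 0.25, 0.25))
    fit <- match_colors(p, space = "rgb", table = tab)
    fit$matches$Pct[fit$matches$ColorName == "Citrine Yellow"]
  }, numeric(1))
  expect_true(all(diff(pcts2) > 0))
})

test_that("empty-foreground and bad-image errors propagate", {
  p <- swatch_png(c(0, 1, 0))   # foreground is itself chroma-key green
  expect_error(match_colors(p, space = "lab"), "no foreground")
  expect_error(match_colors(tempfile(fileext = ".png")), "not found")
})

test_that("print/summary/plot methods run and as.data.frame flattens", {
  p <- swatch_png(c(0.9, 0.85, 0.4))
  fit <- match_colors(p, space = "lab", table = mini_chart())
  expect_output(print(fit), "Citrine Yellow")
  expect_output(summary(fit), "Dominant color")
  df <- as.data.frame(fit)
  expect_true(is.character(df$Pigments))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("write_result rounds only at serialization", {
  p <- swatch_png(c(0.9, 0.85, 0.4))
  df <- rayner_color(p, space = "lab", table = mini_chart())
  out <- tempfile(fileext = ".csv")
  write_result(df, out)
  back <- read.csv(out)
  expect_identical(sprintf("%.3f", df$Pct), sprintf("%.3f", back$Pct))
  expect_identical(names(back), names(df))
})
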