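# Interrater validation machinery: hue confusion matrices, one-vs-rest
# accuracy, Cohen's kappa, replicate summaries, and the manifest-driven
# benchmark that ties them to the image pipeline.

#' Default hue categories for validation
#'
#' The five coarse hue categories used for interrater scoring.
#' @return character vector `c("yellow", "green", "red", "blue", "purple")`.
#' @export
hue_categories <- function() c("yellow", "green", "red", "blue", "purple")

#' Collapse chart hue groups to the coarse validation categories
#'
#' Reference charts use compound hue groups ("purple-blue", "blue-green",
#' "yellow-red", "green-yellow", ...). For 5-category scoring each compound
#' collapses to its first component ("purple-blue" -> "purple"); an explicit
#' `mapping` (named character vector, `c("blue-green" = "green")` style)
#' overrides that rule per label.
#'
#' @param hue character vector of hue-group labels.
#' @param mapping optional named character vector of overrides.
#' @return character vector of collapsed labels.
#' @examples
#' collapse_hue(c("purple-blue", "red", "green-yellow"))
#' @export
collapse_hue <- function(hue, mapping = NULL) {
  hue <- as.character(hue)
  out <- sub("-.*$", "", trimws(hue))
  if (!is.null(mapping)) {
    hit <- match(hue, names(mapping))
    out[!is.na(hit)] <- unname(mapping[hit[!is.na(hit)]])
  }
  out
}

#' Build a multiclass confusion matrix of hue labels
#'
#' Rows are the expected labels (rater 1: published descriptions), columns
#' the predicted labels (rater 2: the pipeline), in the order of
#' `categories`.
#'
#' @param expected,predicted equal-length character vectors of labels, each
#'   present in `categories`.
#' @param categories ordered label vocabulary (default [hue_categories()]).
#' @return an object of class `confusion_matrix` (an integer matrix with
#'   dimnames `expected` x `predicted`).
#' @examples
#' build_confusion(c("red", "blue"), c("red", "red"))
#' @export
build_confusion <- function(expected, predicted,
                            categories = hue_categories()) {
  expected <- as.character(expected)
  predicted <- as.character(predicted)
  if (length(expected) != length(predicted)) {
    stop("expected and predicted must have the same length", call. = FALSE)
  }
  unknown <- setdiff(unique(c(expected, predicted)), categories)
  if (length(unknown)) {
    stop(sprintf("label(s) not in categories: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cm <- table(factor(expected, levels = categories),
              factor(predicted, levels = categories))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(expected = categories, predicted = categories)
  class(cm) <- c("confusion_matrix", "matrix")
  cm
}

.check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (sum(cm) < 1) {
    stop("statistic undefined for an empty confusion matrix", call. = FALSE)
  }
  invisible(cm)
}

#' One-vs-rest accuracy for a confusion-matrix category
#'
#' Collapses the multiclass matrix to category-vs-rest and returns
#' `(TP + TN) / (TP + TN + FP + FN)`: TP is the diagonal cell, FN the rest
#' of its row, FP the rest of its column, TN everything else.
#'
#' @param cm a square confusion matrix (rows expected, columns predicted).
#' @param category row/column name or index of the target category.
#' @return accuracy in \[0, 1\].
#' @examples
#' cm <- matrix(c(3, 2, 1, 4), 2, dimnames = list(c("A","B"), c("A","B")))
#' category_accuracy(cm, "A")   # (3 + 4) / 10
#' @export
category_accuracy <- function(cm, category) {
  .check_cm(cm)
  if (is.character(category)) {
    i <- match(category, rownames(cm))
    if (is.na(i)) {
      stop(sprintf("category '%s' not in confusion matrix", category),
           call. = FALSE)
    }
  } else {
    i <- as.integer(category)
  }
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  (tp + tn) / (tp + tn + fp + fn)
}

#' Cohen's kappa for a confusion matrix
#'
#' Chance-corrected agreement between the two raters:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = sum(diag) / n` and chance agreement
#' `p_e = sum(row_i * col_i) / n^2`. When `p_e = 1` (both raters degenerate
#' on one category) kappa is 1 if agreement is also perfect and undefined
#' otherwise.
#'
#' @param cm a square confusion matrix.
#' @return kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(matrix(c(20, 10, 5, 15), 2))   # 0.4
#' @export
cohens_kappa <- function(cm) {
  .check_cm(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    if (isTRUE(all.equal(po, 1))) return(1)
    stop("kappa undefined: chance agreement is 1 but observed is not",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Banded interpretation of a kappa value
#'
#' Standard agreement bands: below 0 "poor"; 0--0.20 "none/slight";
#' 0.21--0.40 "fair"; 0.41--0.60 "moderate"; 0.61--0.80 "substantial";
#' above 0.80 "almost perfect". The band edges are configurable because
#' published reports sometimes band differently (e.g. calling ~0.65
#' "moderate").
#'
#' @param kappa scalar in \[-1, 1\].
#' @param breaks increasing upper band edges within (0, 1).
#' @param labels band names, one more than `breaks` plus the "poor" band.
#' @return the band label.
#' @examples
#' interpret_kappa(0.035)   # "none/slight"
#' interpret_kappa(1)       # "almost perfect"
#' @export
interpret_kappa <- function(kappa,
                            breaks = c(0.20, 0.40, 0.60, 0.80),
                            labels = c("none/slight", "fair", "moderate",
                                       "substantial", "almost perfect")) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  if (length(labels) != length(breaks) + 1L) {
    stop("labels must have one more element than breaks", call. = FALSE)
  }
  if (kappa < 0) return("poor")
  labels[findInterval(kappa, c(breaks, 1), left.open = TRUE,
                      rightmost.closed = TRUE) + 1L]
}

#' Mean and sample standard deviation across replicate runs
#'
#' The "mean +/- sd" summary used when an analysis is repeated to establish
#' reliability. Uses the sample (n - 1) standard deviation.
#'
#' @param values numeric vector of at least two replicate values.
#' @return named numeric vector `c(mean, sd)`.
#' @export
replicate_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("replicate_summary() needs at least two values", call. = FALSE)
  }
  c(mean = mean(values), sd = stats::sd(values))
}

#' Predicted hue of one image
#'
#' Collapses an 8-row match result to a single hue label. The default
#' `"dominant"` rule takes the hue of the highest-`Pct` bin (earliest bin
#' on ties); `"weighted"` sums `Pct` over hues and takes the largest total.
#' Either way the chart hue group is collapsed to the coarse categories via
#' [collapse_hue()].
#'
#' @param fit a `color_match` from [match_colors()].
#' @param method `"dominant"` or `"weighted"`.
#' @param mapping optional hue-collapse overrides, see [collapse_hue()].
#' @return a single hue label.
#' @export
predict_hue <- function(fit, method = c("dominant", "weighted"),
                        mapping = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "color_match"))
  hues <- collapse_hue(fit$matches$HueGroup, mapping)
  if (method == "dominant") {
    hues[which.max(fit$matches$Pct)]
  } else {
    w <- tapply(fit$matches$Pct, hues, sum)
    names(w)[which.max(w)]
  }
}

#' Score hue agreement between expected labels and pipeline predictions
#'
#' Runs the matching pipeline over a labelled set of images (or consumes
#' precomputed predictions) and scores agreement against the expected hue
#' labels: the multiclass confusion matrix, per-category one-vs-rest
#' accuracy, Cohen's kappa and its banded interpretation.
#'
#' `manifest` is a data frame with columns `path` and `expected_hue`, or
#' `expected_hue` and `predicted_hue` (in which case no images are read);
#' a path to a CSV with those columns is also accepted.
#'
#' @param manifest data frame or CSV path as above.
#' @param space,metric,table,bounds,alpha_cutoff passed to [match_colors()]
#'   when predictions must be computed.
#' @param method,mapping per-image hue collapse, see [predict_hue()].
#' @param categories scoring vocabulary (default [hue_categories()]).
#' @return an object of class `hue_agreement`: list with `confusion`
#'   (a `confusion_matrix`), `accuracy` (named per-category vector),
#'   `kappa`, `interpretation`, `n`, and the `predicted`/`expected` labels.
#' @examples
#' \donttest{
#' set.seed(1)
#' ds <- make_labeled_dataset(10, noise_sd = 0, seed = 7, dir = tempdir())
#' score_hue_agreement(ds, space = "rgb")
#' }
#' @export
score_hue_agreement <- function(manifest, space = c("lab", "rgb"),
                                metric = c("euclidean", "chisq"),
                                table = fixture_lookup(),
                                bounds = background_bounds(),
                                alpha_cutoff = 0.5,
                                method = c("dominant", "weighted"),
                                mapping = NULL,
                                categories = hue_categories()) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!("expected_hue" %in% names(manifest))) {
    stop("manifest needs an 'expected_hue' column", call. = FALSE)
  }
  expected <- collapse_hue(manifest$expected_hue, mapping)
  if ("predicted_hue" %in% names(manifest)) {
    predicted <- collapse_hue(manifest$predicted_hue, mapping)
  } else {
    if (!("path" %in% names(manifest))) {
      stop("manifest needs a 'path' or 'predicted_hue' column", call. = FALSE)
    }
    predicted <- vapply(manifest$path, function(p) {
      fit <- match_colors(p, space = space, metric = metric, table = table,
                          bounds = bounds, alpha_cutoff = alpha_cutoff)
      predict_hue(fit, method = method, mapping = mapping)
    }, character(1), USE.NAMES = FALSE)
  }
  cm <- build_confusion(expected, predicted, categories)
  acc <- vapply(categories, function(cat) category_accuracy(cm, cat),
                numeric(1))
  kap <- cohens_kappa(cm)
  structure(
    list(confusion = cm, accuracy = acc, kappa = kap,
         interpretation = interpret_kappa(kap), n = length(expected),
         expected = expected, predicted = predicted),
    class = "hue_agreement"
  )
}

#' @export
print.hue_agreement <- function(x, ...) {
  cat(sprintf("Hue agreement over %d images\n\n", x$n))
  cat("Confusion matrix (rows expected, columns predicted):\n")
  print(unclass(x$confusion))
  cat("\nPer-category one-vs-rest accuracy:\n")
  print(round(x$accuracy, 3))
  cat(sprintf("\nCohen's kappa: %.3f (%s)\n", x$kappa, x$interpretation))
  invisible(x)
}
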