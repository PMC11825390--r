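# The reference lookup table: named chart colors with CIELAB and sRGB
# coordinates, a hue group, and associated pigment classes. All matching is
# performed against an object of class "lookup_table".

.LOOKUP_COLUMNS <- c("Color", "L", "A", "B", "HueGroup", "ClassOfCompounds",
                     "R", "G", "B.1")

#' Construct a reference lookup table
#'
#' Builds and validates a `lookup_table` from its columns. Most users will
#' load one from disk with [read_lookup()] instead; this constructor is the
#' common validation point for both paths.
#'
#' A lookup table holds one row per named chart color: CIELAB coordinates
#' (`L` in \[0, 100\], `a` and `b` in \[-100, 100\]), sRGB coordinates in
#' \[0, 1\], a free-text hue group (e.g. "red", "blue-green"), and a
#' possibly empty character vector of pigment classes. Row order is
#' preserved and significant: nearest-neighbor ties are broken by the
#' earliest row.
#'
#' @param name character vector of unique, non-empty color names.
#' @param lab numeric n x 3 matrix of CIELAB coordinates.
#' @param rgb numeric n x 3 matrix of sRGB coordinates in \[0, 1\]; values on
#'   a 0--255 scale are detected (any channel > 1) and rescaled.
#' @param hue_group character vector of hue-group labels, kept verbatim.
#' @param pigments list of character vectors (possibly empty) of pigment
#'   class names, one element per color.
#' @param source provenance string recorded on the object (file path or
#'   `"fixture"`).
#' @return an object of class `lookup_table`: a data frame with columns
#'   `Color`, `L`, `A`, `B`, `HueGroup`, `ClassOfCompounds` (list column),
#'   `R`, `G`, `B.1` and attribute `source`.
#' @seealso [read_lookup()], [write_lookup()], [fixture_lookup()]
#' @export
lookup_table <- function(name, lab, rgb, hue_group, pigments = NULL,
                         source = "constructed") {
  name <- as.character(name)
  lab <- .as_color_matrix(lab, c("L", "a", "b"))
  rgb <- .as_color_matrix(rgb, c("r", "g", "b"))
  hue_group <- as.character(hue_group)
  n <- length(name)
  if (nrow(lab) != n || nrow(rgb) != n || length(hue_group) != n) {
    stop("lookup_table(): name, lab, rgb and hue_group lengths differ",
         call. = FALSE)
  }
  if (is.null(pigments)) pigments <- rep(list(character(0)), n)
  if (!is.list(pigments) || length(pigments) != n) {
    stop("lookup_table(): pigments must be a list with one element per color",
         call. = FALSE)
  }
  pigments <- lapply(pigments, as.character)

  # Sources sometimes carry RGB on 0..255; detect and rescale once.
  if (any(rgb > 1, na.rm = TRUE)) rgb <- rgb / 255

  tab <- data.frame(
    Color = name, L = lab[, 1], A = lab[, 2], B = lab[, 3],
    HueGroup = hue_group, R = rgb[, 1], G = rgb[, 2], B.1 = rgb[, 3],
    stringsAsFactors = FALSE
  )
  tab$ClassOfCompounds <- pigments
  tab <- tab[, .LOOKUP_COLUMNS]
  attr(tab, "source") <- source
  class(tab) <- c("lookup_table", "data.frame")
  validate_lookup(tab)
  tab
}

#' @rdname lookup_table
#' @param table object to validate.
#' @export
validate_lookup <- function(table) {
  if (!inherits(table, "lookup_table")) {
    stop("not a lookup_table object", call. = FALSE)
  }
  if (nrow(table) < 1L) {
    stop("lookup table must contain at least one entry", call. = FALSE)
  }
  if (any(!nzchar(table$Color) | is.na(table$Color))) {
    i <- which(!nzchar(table$Color) | is.na(table$Color))[1]
    stop(sprintf("empty color name at row %d", i), call. = FALSE)
  }
  dup <- duplicated(table$Color)
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate color name '%s' at row %d", table$Color[i], i),
         call. = FALSE)
  }
  .check_range(table, "L", 0, 100)
  .check_range(table, "A", -100, 100)
  .check_range(table, "B", -100, 100)
  .check_range(table, "R", 0, 1)
  .check_range(table, "G", 0, 1)
  .check_range(table, "B.1", 0, 1)
  invisible(table)
}

.check_range <- function(table, col, lo, hi) {
  x <- table[[col]]
  bad <- which(is.na(x) | x < lo | x > hi)
  if (length(bad)) {
    shown <- if (col == "B.1") "B (rgb)" else col
    stop(sprintf("%s=%g outside [%g,%g] at row %d", shown, x[bad[1]],
                 lo, hi, bad[1]), call. = FALSE)
  }
  invisible(NULL)
}

#' Read a reference lookup table from delimited text
#'
#' Reads a 9-column chart file with header
#' `Color,L,A,B,HueGroup,ClassOfCompounds,R,G,B`: the color name, its CIELAB
#' coordinates, hue group, pigment classes, and sRGB coordinates. The field
#' separator is taken from the file extension (`.tsv` = tab, otherwise
#' comma) unless `sep` is given. Pigment cells holding several classes are
#' split on `pigment_sep`; empty cells become zero-length vectors. RGB
#' columns on a 0--255 scale are rescaled to \[0, 1\].
#'
#' @param path path to a CSV/TSV file.
#' @param sep field separator; `NULL` (default) chooses by extension.
#' @param pigment_sep delimiter between pigment classes inside one cell.
#' @return a validated [lookup_table].
#' @examples
#' tab <- read_lookup(system.file("extdata", "mini_rayner.csv",
#'                                package = "mycocolor"))
#' nrow(tab)
#' @export
read_lookup <- function(path, sep = NULL, pigment_sep = ";") {
  if (!file.exists(path)) {
    stop(sprintf("lookup table file not found: %s", path), call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  missing <- setdiff(.LOOKUP_COLUMNS, names(raw))
  if (length(missing)) {
    shown <- sub("^B\\.1$", "B (rgb)", missing)
    stop(sprintf("lookup table is missing column(s): %s",
                 paste(shown, collapse = ", ")), call. = FALSE)
  }
  for (col in c("L", "A", "B", "R", "G", "B.1")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  pig <- as.character(raw$ClassOfCompounds)
  pig[is.na(pig)] <- ""
  pigments <- lapply(strsplit(pig, pigment_sep, fixed = TRUE),
                     function(p) trimws(p[nzchar(trimws(p))]))
  lookup_table(
    name = raw$Color,
    lab = as.matrix(raw[, c("L", "A", "B")]),
    rgb = as.matrix(raw[, c("R", "G", "B.1")]),
    hue_group = as.character(raw$HueGroup),
    pigments = pigments,
    source = path
  )
}

#' Write a lookup table back to delimited text
#'
#' Serializes a [lookup_table] in the same 9-column layout accepted by
#' [read_lookup()], so that a write/read round trip reproduces the table.
#'
#' @param table a [lookup_table].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param pigment_sep delimiter joining pigment classes inside one cell.
#' @return `path`, invisibly.
#' @export
write_lookup <- function(table, path, sep = ",", pigment_sep = ";") {
  validate_lookup(table)
  out <- data.frame(
    Color = table$Color,
    L = sprintf("%.10g", table$L),
    A = sprintf("%.10g", table$A),
    B = sprintf("%.10g", table$B),
    HueGroup = table$HueGroup,
    ClassOfCompounds = vapply(table$ClassOfCompounds, paste,
                              character(1), collapse = pigment_sep),
    R = sprintf("%.10g", table$R),
    G = sprintf("%.10g", table$G),
    B.1 = sprintf("%.10g", table$B.1),
    stringsAsFactors = FALSE
  )
  names(out)[9] <- "B"
  # write.table would mangle the duplicated B header; emit it directly
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = sep), con)
  body <- apply(out, 1, paste, collapse = sep)
  writeLines(body, con)
  invisible(path)
}

#' Look up the hue group of a named chart color
#'
#' @param table a [lookup_table].
#' @param name color name, matched case-sensitively.
#' @return the hue-group label, verbatim as stored (no normalization).
#' @examples
#' tab <- fixture_lookup()
#' hue_of(tab, tab$Color[1])
#' @export
hue_of <- function(table, name) {
  i <- .lookup_row(table, name)
  table$HueGroup[i]
}

#' Look up the pigment classes associated with a named chart color
#'
#' @inheritParams hue_of
#' @return character vector of pigment class names; empty when the hue has
#'   no known associated pigments.
#' @export
pigments_of <- function(table, name) {
  i <- .lookup_row(table, name)
  table$ClassOfCompounds[[i]]
}

.lookup_row <- function(table, name) {
  validate_lookup(table)
  stopifnot(is.character(name), length(name) == 1L)
  i <- match(name, table$Color)
  if (is.na(i)) {
    stop(sprintf("color name '%s' not found in lookup table", name),
         call. = FALSE)
  }
  i
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("Reference lookup table: %d colors (source: %s)\n",
              nrow(x), attr(x, "source")))
  cat(sprintf("Hue groups: %s\n",
              paste(sort(unique(x$HueGroup)), collapse = ", ")))
  show <- utils::head(as.data.frame(x)[, c("Color", "L", "A", "B",
                                           "HueGroup")], 6L)
  print(show, ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
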