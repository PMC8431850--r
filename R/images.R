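#' Intensity image
#'
#' An intensity image is a 2D or 3D numeric grid with all values in `[0, 1]`,
#' together with the number of distinct representable grey levels of its
#' source (256 for 8-bit sources, 65536 for 16-bit). Axis order is `(z,) y, x`
#' with 0-based pixel-center coordinates throughout the package.
#'
#' @param values Numeric matrix (2D) or 3D array with finite values in `[0, 1]`.
#' @param grey_levels Positive integer, number of representable grey levels
#'   (>= 2). Threshold searches use this as the candidate grid resolution.
#' @return An object of class `mq_intensity` with fields `values`,
#'   `grey_levels` and `ndim`.
#' @export
#' @examples
#' img <- intensity_image(matrix(seq(0, 1, length.out = 16), 4, 4))
intensity_image <- function(values, grey_levels = 256L) {
  if (!is.array(values) && !is.matrix(values))
    stop_mq("values must be a matrix or array", "mq_format_error")
  nd <- length(dim(values))
  if (!nd %in% 2:3)
    stop_mq("intensity image must be 2D or 3D", "mq_format_error")
  if (!all(is.finite(values)))
    stop_mq("intensity values must be finite", "mq_format_error")
  if (min(values) < 0 || max(values) > 1)
    stop_mq("intensity values must lie in [0, 1]", "mq_format_error")
  grey_levels <- as.integer(grey_levels)
  if (is.na(grey_levels) || grey_levels < 2L)
    stop_mq("grey_levels must be an integer >= 2", "mq_format_error")
  structure(list(values = values, grey_levels = grey_levels, ndim = nd),
            class = "mq_intensity")
}

#' Label image
#'
#' A label image is a 2D or 3D integer grid where 0 denotes background and
#' each positive integer identifies one object. Objects in a single label
#' image cannot overlap.
#'
#' @param labels Integer matrix or 3D array with non-negative entries.
#' @return An object of class `mq_label` with fields `labels` and `ndim`.
#' @export
label_image <- function(labels) {
  if (!is.array(labels) && !is.matrix(labels))
    stop_mq("labels must be a matrix or array", "mq_format_error")
  nd <- length(dim(labels))
  if (!nd %in% 2:3)
    stop_mq("label image must be 2D or 3D", "mq_format_error")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop_mq("labels must be non-negative integers", "mq_format_error")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, ndim = nd), class = "mq_label")
}

#' @export
print.mq_intensity <- function(x, ...) {
  cat("<intensity image> ", paste(dim(x$values), collapse = " x "),
      ", grey levels ", x$grey_levels,
      ", range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.mq_label <- function(x, ...) {
  cat("<label image> ", paste(dim(x$labels), collapse = " x "),
      ", ", length(object_ids(x)), " objects\n", sep = "")
  invisible(x)
}

#' Object ids present in a label image
#' @param labels A [label_image()].
#' @return Sorted integer vector of positive object ids.
#' @export
object_ids <- function(labels) {
  u <- sort(unique(as.vector(labels$labels)))
  u[u > 0L]
}

is_intensity <- function(x) inherits(x, "mq_intensity")
is_label <- function(x) inherits(x, "mq_label")

stack_pages <- function(pages) {
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L) {
    p <- pages[[1L]]
    return(array(as.vector(p), dim(p)))  # drop TIFF info attributes
  }
  dims <- dim(pages[[1L]])
  arr <- array(0, dim = c(length(pages), dims))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Read a TIFF image as an intensity or label image
#'
#' Single-channel 2D TIFFs or z-stacks (multi-page TIFFs, stacked as the
#' leading `z` axis). Integer intensity data are rescaled to `[0, 1]` by the
#' maximum of their declared bit depth; float data are assumed pre-scaled to
#' `[0, 1]` and values outside that range are clipped with a warning.
#'
#' @param path Path to a TIFF file.
#' @param kind `"intensity"` or `"label"`.
#' @param grey_levels_hint Optional override for the grey-level count
#'   (defaults to `2^bits` for integer sources and 256 for float sources).
#' @return An [intensity_image()] or [label_image()].
#' @export
read_image <- function(path, kind = c("intensity", "label"),
                       grey_levels_hint = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_mq(paste0("no such file: ", path), "mq_io_error")
  raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  first <- raw[[1L]]
  if (length(dim(first)) == 3L)
    stop_mq(paste0("RGB/multi-channel TIFF not supported; extract one channel",
                   " per file and read each channel separately"),
            "mq_format_error")
  bits <- attr(first, "bits.per.sample")
  fmt <- attr(first, "sample.format")
  is_float <- identical(fmt, "float") || is.double(first)
  arr <- stack_pages(raw)
  if (kind == "label") {
    if (is_float)
      stop_mq("label TIFF must have an integer sample format", "mq_format_error")
    return(label_image(arr))
  }
  if (is_float) {
    gl <- if (is.null(grey_levels_hint)) 256L else as.integer(grey_levels_hint)
    if (min(arr) < 0 || max(arr) > 1) {
      warning("float intensity values outside [0, 1] were clipped")
      arr <- pmin(pmax(arr, 0), 1)
      dim(arr) <- dim(stack_pages(raw))
    }
    return(intensity_image(arr, gl))
  }
  if (is.null(bits)) bits <- if (max(arr) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stop_mq(paste0("unsupported TIFF bit depth: ", bits), "mq_format_error")
  gl <- if (is.null(grey_levels_hint)) as.integer(2^bits) else
    as.integer(grey_levels_hint)
  intensity_image(arr / (2^bits - 1), gl)
}

#' Write an intensity or label image to TIFF
#'
#' Intensity images are written at the requested bit depth; label images are
#' written as 16-bit integers (ids must not exceed 65535). 3D arrays are
#' written as multi-page TIFFs.
#'
#' @param image An [intensity_image()] or [label_image()].
#' @param path Output path.
#' @param bits Bits per sample for intensity output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  if (is_label(image)) {
    lab <- image$labels
    if (max(lab) > 65535L)
      stop_mq("label ids exceed 16-bit range", "mq_format_error")
    vals <- lab / 65535
    bits <- 16L
  } else if (is_intensity(image)) {
    vals <- image$values
    if (!bits %in% c(8L, 16L))
      stop_mq("bits must be 8 or 16", "mq_format_error")
  } else stop_mq("image must be an intensity or label image", "mq_format_error")
  d <- dim(vals)
  pages <- if (length(d) == 3L)
    lapply(seq_len(d[1L]), function(z) vals[z, , ]) else vals
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                 error = function(e) stop_mq(conditionMessage(e), "mq_io_error"))
  invisible(path)
}

#' Create a feature table
#'
#' A feature table has one row per object id and named numeric measurement
#' columns; it is the return type of all measurement operations.
#'
#' @param object_id Integer vector of object ids.
#' @param ... Named numeric columns, each the same length as `object_id`.
#' @return A `data.frame` with `object_id` as its first column.
#' @export
feature_table <- function(object_id, ...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1L]]) && !is.data.frame(cols[[1L]]) &&
      is.null(names(cols)))
    cols <- cols[[1L]]
  df <- data.frame(object_id = as.integer(object_id))
  for (nm in names(cols)) df[[nm]] <- as.numeric(cols[[nm]])
  df
}

#' Write a feature table to CSV
#'
#' Rows are ordered by ascending object id and columns lexicographically
#' after `object_id`, so output is deterministic. Values are written with 15
#' significant digits and round-trip through [read_table()] to at least 12
#' significant digits.
#'
#' @param table A feature table (`data.frame` with an `object_id` column).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table) || !"object_id" %in% names(table))
    stop_mq("table must be a data.frame with an object_id column",
            "mq_format_error")
  other <- sort(setdiff(names(table), "object_id"))
  table <- table[order(table$object_id), c("object_id", other), drop = FALSE]
  out <- table
  for (nm in other)
    out[[nm]] <- formatC(table[[nm]], digits = 15, format = "g")
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop_mq(conditionMessage(e), "mq_io_error"))
  invisible(path)
}

#' Read a feature table written by [write_table()]
#' @param path CSV path.
#' @return A `data.frame` with an integer `object_id` column.
#' @export
read_table <- function(path) {
  df <- utils::read.csv(path)
  df$object_id <- as.integer(df$object_id)
  df
}
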