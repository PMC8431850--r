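#' Threshold results
#'
#' A threshold result is either a single global scalar threshold or a
#' per-pixel threshold surface, together with the method and parameters that
#' produced it. [apply_threshold()] accepts either kind.
#'
#' @param value Scalar in `[0, 1]` (global) or numeric array (surface).
#' @param method Method name string.
#' @param params Named list of parameters.
#' @return An object of class `mq_threshold`.
#' @export
threshold_result <- function(value, method, params = list()) {
  kind <- if (length(value) == 1L) "global" else "surface"
  if (min(value) < 0 || max(value) > 1)
    stop_mq("threshold values must lie in [0, 1]", "mq_value_error")
  structure(list(kind = kind, value = value, method = method, params = params),
            class = "mq_threshold")
}

#' @export
print.mq_threshold <- function(x, ...) {
  if (x$kind == "global")
    cat("<threshold> global ", format(x$value, digits = 6), " (", x$method,
        ")\n", sep = "")
  else
    cat("<threshold> surface ", paste(dim(x$value), collapse = " x "),
        " (", x$method, "), range [", format(min(x$value), digits = 4), ", ",
        format(max(x$value), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Otsu global threshold
#'
#' Two-class Otsu threshold: the histogram bin edge maximizing the
#' between-class variance of the two classes it separates. The histogram
#' spans `[min, max]` of the image with `nbins` equal bins; the returned
#' threshold is an interior bin edge and therefore lies strictly between the
#' image minimum and maximum. Ties take the lowest qualifying edge.
#'
#' @param image An [intensity_image()] (or bare numeric array).
#' @param nbins Number of histogram bins; defaults to
#'   `min(grey_levels, 256)`.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(image, nbins = NULL) {
  v <- if (is_intensity(image)) as.vector(image$values) else as.vector(image)
  gl <- if (is_intensity(image)) image$grey_levels else 256L
  if (is.null(nbins)) nbins <- min(gl, 256L)
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop_mq("nbins must be >= 2", "mq_value_error")
  mn <- min(v); mx <- max(v)
  if (mx <= mn)
    stop_mq("constant image: Otsu threshold undefined", "mq_degenerate_error")
  bin <- pmin(floor((v - mn) / (mx - mn) * nbins) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  mids <- mn + (seq_len(nbins) - 0.5) * (mx - mn) / nbins
  n <- length(v)
  cw <- cumsum(counts)                    # pixels in bins 1..k
  cs <- cumsum(counts * mids)             # intensity mass in bins 1..k
  tot <- cs[nbins]
  k <- seq_len(nbins - 1L)
  w0 <- cw[k] / n
  valid <- w0 > 0 & w0 < 1
  mu0 <- cs[k] / cw[k]
  mu1 <- (tot - cs[k]) / (n - cw[k])
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  bcv[!valid] <- -Inf
  if (!any(valid))
    stop_mq("degenerate histogram: Otsu threshold undefined",
            "mq_degenerate_error")
  kbest <- which.max(bcv)
  mn + kbest * (mx - mn) / nbins
}

#' Log-transform wrapper for global threshold methods
#'
#' Wraps any global threshold method so that it is computed on
#' log-transformed intensities and mapped back to the original scale. The
#' transform is `x -> log(x + eps)` rescaled to `[0, 1]`, with
#' `eps = 1/grey_levels`; the returned threshold is the exact inverse image
#' of the wrapped method's threshold.
#'
#' @param method A function `(image, ...) -> scalar threshold`.
#' @return A function with the same signature computing the log-domain
#'   threshold.
#' @export
log_wrap <- function(method) {
  function(image, ...) {
    stopifnot(is_intensity(image))
    eps <- 1 / image$grey_levels
    lo <- log(eps); hi <- log(1 + eps)
    tr <- (log(image$values + eps) - lo) / (hi - lo)
    timg <- intensity_image(tr, image$grey_levels)
    t2 <- method(timg, ...)
    exp(t2 * (hi - lo) + lo) - eps
  }
}

#' Sauvola local threshold surface
#'
#' Per-pixel threshold `T = m * (1 + k * (s / R - 1))` with `m`, `s` the
#' local mean and standard deviation over an odd square (cube) window,
#' computed with reflective border padding.
#'
#' @param image An [intensity_image()].
#' @param window Odd window edge length (>= 3). Default 25.
#' @param k Sensitivity parameter. Default 0.2.
#' @param R Dynamic range of the standard deviation. Default 0.5 (half of
#'   the 0-1 intensity range).
#' @return A surface [threshold_result()].
#' @export
sauvola_surface <- function(image, window = 25L, k = 0.2, R = 0.5) {
  stopifnot(is_intensity(image))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop_mq("window must be an odd integer >= 3", "mq_value_error")
  if (R <= 0) stop_mq("R must be positive", "mq_value_error")
  x <- image$values
  m <- box_mean(x, window)
  m2 <- box_mean(x * x, window)
  s <- sqrt(pmax(m2 - m * m, 0))
  surf <- m * (1 + k * (s / R - 1))
  surf <- pmin(pmax(surf, 0), 1)
  threshold_result(surf, "sauvola",
                   list(window = window, k = k, R = R))
}

# Sliding-window mean over an odd window with reflective (symmetric) border
# padding, separable along axes.
box_mean <- function(x, window) {
  r <- (window - 1L) %/% 2L
  dims <- dim(x)
  nd <- length(dims)
  for (ax in seq_len(nd)) {
    n <- dims[ax]
    pad_idx <- c(rev(seq_len(min(r, n))), seq_len(n),
                 rev(n + 1L - seq_len(min(r, n))))
    while (length(pad_idx) < n + 2L * r) # degenerate tiny axes: re-reflect
      pad_idx <- c(pad_idx[1L], pad_idx, pad_idx[length(pad_idx)])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    g <- aperm(x, perm)
    gd <- dim(g)
    gm <- matrix(g, nrow = n)
    gp <- gm[pad_idx, , drop = FALSE]
    cs <- rbind(0, apply(gp, 2L, cumsum))
    sm <- (cs[seq_len(n) + 2L * r + 1L, , drop = FALSE] -
             cs[seq_len(n), , drop = FALSE]) / window
    x <- aperm(array(sm, gd), order(perm))
  }
  x
}

#' Adaptive (blockwise) threshold surface from any global method
#'
#' Tiles the image into blocks of edge `window`, applies the global `method`
#' per block (blocks where the method is degenerate inherit the whole-image
#' global threshold), interpolates the block-center thresholds multilinearly
#' to a per-pixel surface (edge-clamped), and clamps the surface to
#' `[global * bounds[1], global * bounds[2]]` where `global` is the method
#' applied to the whole image.
#'
#' @param image An [intensity_image()].
#' @param method A function `(image) -> scalar threshold`; default Otsu.
#' @param window Block edge length in pixels (>= 8); every image axis must
#'   exceed it.
#' @param bounds Length-2 numeric `(low_factor, high_factor)` clamp around
#'   the global threshold. Default `c(0.7, 1.5)`.
#' @return A surface [threshold_result()].
#' @export
adaptive_surface <- function(image, method = otsu_threshold, window = 64L,
                             bounds = c(0.7, 1.5)) {
  stopifnot(is_intensity(image))
  window <- as.integer(window)
  if (window < 8L) stop_mq("window must be >= 8 pixels", "mq_value_error")
  dims <- dim(image$values)
  if (any(dims <= window))
    stop_mq("image is not larger than one window in every axis; use the global method instead",
            "mq_value_error")
  if (length(bounds) != 2L || bounds[1] > bounds[2])
    stop_mq("bounds must be (low_factor, high_factor) with low <= high",
            "mq_value_error")
  global <- method(image)
  nd <- length(dims)
  starts <- lapply(dims, function(n) seq(1L, n, by = window))
  nb <- vapply(starts, length, integer(1))
  centers <- vector("list", nd)
  for (ax in seq_len(nd)) {
    st <- starts[[ax]]
    en <- pmin(st + window - 1L, dims[ax])
    centers[[ax]] <- (st + en) / 2 - 1  # 0-based pixel-center coordinate
  }
  tgrid <- array(global, nb)
  bidx <- as.matrix(do.call(expand.grid, lapply(nb, seq_len)))
  for (r in seq_len(nrow(bidx))) {
    sub_idx <- vector("list", nd)
    for (ax in seq_len(nd)) {
      st <- starts[[ax]][bidx[r, ax]]
      sub_idx[[ax]] <- st:min(st + window - 1L, dims[ax])
    }
    block <- index_array(image$values, sub_idx)
    tgrid[matrix(bidx[r, ], 1)] <- tryCatch(
      method(intensity_image(block, image$grey_levels)),
      mq_degenerate_error = function(e) global)
  }
  surf <- interp_grid(tgrid, centers, dims)
  surf <- pmin(pmax(surf, global * bounds[1]), global * bounds[2])
  surf <- pmin(pmax(surf, 0), 1)
  threshold_result(surf, "adaptive",
                   list(window = window, bounds = bounds, global = global))
}

# Multilinear interpolation of values on a rectilinear grid of block centers
# onto every pixel of an image; coordinates outside the center range clamp
# to the nearest center.
interp_grid <- function(tgrid, centers, dims) {
  nd <- length(dims)
  lo <- vector("list", nd)
  w <- vector("list", nd)
  for (ax in seq_len(nd)) {
    cc <- centers[[ax]]
    p <- seq_len(dims[ax]) - 1  # pixel-center coordinates
    if (length(cc) == 1L) {
      lo[[ax]] <- rep(1L, dims[ax])
      w[[ax]] <- rep(0, dims[ax])
      next
    }
    i <- findInterval(p, cc, all.inside = TRUE)
    frac <- (p - cc[i]) / (cc[i + 1L] - cc[i])
    lo[[ax]] <- i
    w[[ax]] <- pmin(pmax(frac, 0), 1)  # edge clamp
  }
  surf <- array(0, dims)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  nbdim <- dim(tgrid)
  for (r in seq_len(nrow(corners))) {
    idx_ax <- vector("list", nd)
    wt_ax <- vector("list", nd)
    for (ax in seq_len(nd)) {
      off <- corners[r, ax]
      idx <- pmin(lo[[ax]] + off, nbdim[ax])
      idx_ax[[ax]] <- idx
      wt_ax[[ax]] <- if (off == 1L) w[[ax]] else 1 - w[[ax]]
    }
    # outer product of per-axis index/weight vectors
    if (nd == 2L) {
      vals <- tgrid[cbind(rep(idx_ax[[1]], times = dims[2]),
                          rep(idx_ax[[2]], each = dims[1]))]
      wts <- rep(wt_ax[[1]], times = dims[2]) * rep(wt_ax[[2]], each = dims[1])
    } else {
      vals <- tgrid[cbind(rep(idx_ax[[1]], times = dims[2] * dims[3]),
                          rep(rep(idx_ax[[2]], each = dims[1]), times = dims[3]),
                          rep(idx_ax[[3]], each = dims[1] * dims[2]))]
      wts <- rep(wt_ax[[1]], times = dims[2] * dims[3]) *
        rep(rep(wt_ax[[2]], each = dims[1]), times = dims[3]) *
        rep(wt_ax[[3]], each = dims[1] * dims[2])
    }
    surf <- surf + array(vals * wts, dims)
  }
  surf
}

#' Apply a threshold to an image
#'
#' Foreground is defined by the strict comparison `value > threshold`, for
#' both global thresholds and per-pixel surfaces.
#'
#' @param image An [intensity_image()].
#' @param result An [threshold_result()] or bare scalar/array.
#' @return Logical array of the image's shape.
#' @export
apply_threshold <- function(image, result) {
  stopifnot(is_intensity(image))
  thr <- if (inherits(result, "mq_threshold")) result$value else result
  if (length(thr) > 1L && !identical(dim(thr), dim(image$values)))
    stop_mq("threshold surface shape must match the image", "mq_dim_error")
  image$values > thr
}
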