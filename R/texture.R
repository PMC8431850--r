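#' Texture measurement parameters
#'
#' @param levels Number of quantization levels (>= 2, default 8).
#' @param scale Pixel offset distance for co-occurrence (>= 1, default 3).
#' @param directions Optional integer matrix of displacement vectors (one
#'   row per direction, columns in `(z,)y,x` order). Defaults to the four
#'   classical 2D directions at distance `scale`
#'   (`(0,1), (1,0), (1,1), (1,-1)` scaled), with the axial z offset added
#'   for 3D images.
#' @return A `mq_texture_params` list.
#' @export
texture_params <- function(levels = 8L, scale = 3L, directions = NULL) {
  levels <- as.integer(levels); scale <- as.integer(scale)
  if (levels < 2L) stop_mq("levels must be >= 2", "mq_value_error")
  if (scale < 1L) stop_mq("scale must be >= 1", "mq_value_error")
  structure(list(levels = levels, scale = scale, directions = directions),
            class = "mq_texture_params")
}

default_directions <- function(ndim, scale) {
  if (ndim == 2L) {
    scale * rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  } else {
    scale * rbind(c(0L, 0L, 1L), c(0L, 1L, 0L), c(0L, 1L, 1L),
                  c(0L, 1L, -1L), c(1L, 0L, 0L))
  }
}

#' Quantize masked intensities into grey bins
#'
#' Linear quantization of the masked values into `0 .. levels-1` using the
#' object's own min/max; the top bin edge is closed (the maximum maps to
#' `levels - 1`) and constant objects map entirely to bin 0.
#'
#' @param image An [intensity_image()] (or bare numeric array).
#' @param mask Logical array; must be non-empty.
#' @param levels Number of bins.
#' @return Integer array of the mask's shape with bins inside the mask and
#'   `NA` outside.
#' @export
quantize_object <- function(image, mask, levels) {
  x <- if (is_intensity(image)) image$values else image
  if (!any(mask)) stop_mq("mask is empty", "mq_value_error")
  v <- x[mask]
  mn <- min(v); mx <- max(v)
  q <- array(NA_integer_, dim(x))
  if (mx <= mn) {
    q[mask] <- 0L
  } else {
    bins <- pmin(as.integer(floor((v - mn) / (mx - mn) * levels)),
                 levels - 1L)
    q[mask] <- bins
  }
  q
}

#' Grey-level co-occurrence matrix over a mask
#'
#' Counts quantized value pairs `(p, p + offset)` where both pixels lie
#' inside the mask, symmetrizes (adds the transpose) and normalizes to unit
#' mass. If no valid pair exists the empty-GLCM state is returned: a zero
#' matrix with attribute `empty = TRUE` (all features are defined as 0).
#'
#' @param quantized Integer array from [quantize_object()] (NA outside mask).
#' @param mask Logical array.
#' @param offset Integer displacement vector (`(z,)y,x`), non-zero.
#' @param levels Number of grey levels of the quantization.
#' @return `levels x levels` numeric matrix summing to 1 (or the empty
#'   state).
#' @export
glcm_masked <- function(quantized, mask, offset, levels) {
  if (all(offset == 0L)) stop_mq("offset must be non-zero", "mq_value_error")
  dims <- dim(mask)
  sh <- shift_overlap(dims, offset)
  counts <- matrix(0, levels, levels)
  if (!is.null(sh)) {
    m1 <- index_array(mask, sh$from)
    m2 <- index_array(mask, sh$to)
    sel <- m1 & m2
    if (any(sel)) {
      q1 <- index_array(quantized, sh$from)[sel]
      q2 <- index_array(quantized, sh$to)[sel]
      idx <- q1 * levels + q2 + 1L
      tab <- tabulate(idx, levels * levels)
      counts <- matrix(tab, levels, levels, byrow = TRUE)
    }
  }
  g <- counts + t(counts)
  tot <- sum(g)
  if (tot == 0) {
    attr(g, "empty") <- TRUE
    return(g)
  }
  g / tot
}

haralick_names <- c(
  "AngularSecondMoment", "Contrast", "Correlation", "Variance",
  "InverseDifferenceMoment", "SumAverage", "SumVariance", "SumEntropy",
  "Entropy", "DifferenceVariance", "DifferenceEntropy", "InfoMeas1",
  "InfoMeas2")

#' The 13 classical Haralick texture statistics of a GLCM
#'
#' Angular second moment, contrast, correlation, sum-of-squares variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy and the two information
#' measures of correlation. Entropies use log base 2 with `0 * log 0 = 0`;
#' grey levels are indexed from 0. A degenerate (one-hot) GLCM has
#' correlation reported as 0 (zero-variance convention), and the empty GLCM
#' state yields all-zero features.
#'
#' @param g GLCM matrix from [glcm_masked()].
#' @return Named numeric vector of length 13.
#' @export
haralick_features <- function(g) {
  L <- nrow(g)
  out <- stats::setNames(numeric(13L), haralick_names)
  if (isTRUE(attr(g, "empty")) || sum(g) == 0) return(out)
  i <- matrix(0:(L - 1L), L, L)            # row index (first pixel level)
  j <- t(i)
  lg2 <- function(p) ifelse(p > 0, log2(p), 0)
  px <- rowSums(g); py <- colSums(g)
  lev <- 0:(L - 1L)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  # p_{x+y}(k), k = 0..2L-2 and p_{x-y}(k), k = 0..L-1
  psum <- vapply(0:(2L * L - 2L), function(k) sum(g[i + j == k]), numeric(1))
  pdif <- vapply(0:(L - 1L), function(k) sum(g[abs(i - j) == k]), numeric(1))
  ks <- 0:(2L * L - 2L); kd <- 0:(L - 1L)

  out["AngularSecondMoment"] <- sum(g^2)
  out["Contrast"] <- sum(kd^2 * pdif)
  out["Correlation"] <- if (sdx == 0 || sdy == 0) 0 else
    (sum(i * j * g) - mux * muy) / (sdx * sdy)
  out["Variance"] <- sum((i - mux)^2 * g)
  out["InverseDifferenceMoment"] <- sum(g / (1 + (i - j)^2))
  sa <- sum(ks * psum)
  out["SumAverage"] <- sa
  out["SumVariance"] <- sum((ks - sa)^2 * psum)
  out["SumEntropy"] <- -sum(psum * lg2(psum))
  ent <- -sum(g * lg2(g))
  out["Entropy"] <- ent
  dmean <- sum(kd * pdif)
  out["DifferenceVariance"] <- sum((kd - dmean)^2 * pdif)
  out["DifferenceEntropy"] <- -sum(pdif * lg2(pdif))
  pxy <- outer(px, py)
  hxy1 <- -sum(g * lg2(pxy))
  hxy2 <- -sum(pxy * lg2(pxy))
  hx <- -sum(px * lg2(px)); hy <- -sum(py * lg2(py))
  out["InfoMeas1"] <- if (max(hx, hy) == 0) 0 else (ent - hxy1) / max(hx, hy)
  out["InfoMeas2"] <- sqrt(pmax(1 - exp(-2 * (hxy2 - ent)), 0))
  out
}

object_bbox <- function(idx, dims) {
  co <- arrayInd(idx, dims)
  list(min = apply(co, 2L, min), max = apply(co, 2L, max))
}

#' Per-object Haralick texture features
#'
#' For each object, intensities are quantized over the object mask (its own
#' min/max), co-occurrence matrices are built at the configured offsets, and
#' the 13 Haralick statistics are averaged over directions. In `cropped`
#' mode the computation runs inside the object's bounding box expanded by
#' `scale` pixels (so every within-mask pair at the offset is representable
#' in the crop); in `full` mode it runs on the full-size masked arrays.
#' The two modes are exactly equivalent: quantization depends only on masked
#' values and co-occurrence counts only on within-mask pairs, so the tables
#' agree bit for bit.
#'
#' Objects too small to form any pair at the configured offsets get all-zero
#' features and are flagged in the `Texture_EmptyGLCM` column.
#'
#' @param image An [intensity_image()].
#' @param labels A [label_image()] of the same shape.
#' @param params A [texture_params()].
#' @param mode `"cropped"` (default) or `"full"`.
#' @return A feature table with one row per object: `Texture_<name>` columns
#'   averaged over directions plus `Texture_EmptyGLCM`.
#' @export
per_object_texture <- function(image, labels, params = texture_params(),
                               mode = c("cropped", "full")) {
  mode <- match.arg(mode)
  x <- image$values
  lab <- labels$labels
  if (!identical(dim(x), dim(lab)))
    stop_mq("image and labels must have identical shape", "mq_dim_error")
  dims <- dim(x)
  nd <- length(dims)
  dirs <- params$directions
  if (is.null(dirs)) dirs <- default_directions(nd, params$scale)
  ids <- object_ids(labels)
  nfeat <- length(haralick_names)
  res <- matrix(0, length(ids), nfeat + 1L)
  colnames(res) <- c(haralick_names, "EmptyGLCM")
  for (oi in seq_along(ids)) {
    idx <- which(lab == ids[oi])
    if (mode == "cropped") {
      bb <- object_bbox(idx, dims)
      pad <- max(abs(dirs))  # every within-mask pair stays inside the crop
      sub_idx <- lapply(seq_len(nd), function(ax)
        max(1L, bb$min[ax] - pad):min(dims[ax], bb$max[ax] + pad))
      xs <- index_array(x, sub_idx)
      ms <- index_array(lab, sub_idx) == ids[oi]
    } else {
      xs <- x
      ms <- lab == ids[oi]
    }
    q <- quantize_object(xs, ms, params$levels)
    acc <- numeric(nfeat)
    n_empty <- 0L
    for (d in seq_len(nrow(dirs))) {
      g <- glcm_masked(q, ms, dirs[d, ], params$levels)
      if (isTRUE(attr(g, "empty"))) n_empty <- n_empty + 1L
      acc <- acc + haralick_features(g)
    }
    res[oi, seq_len(nfeat)] <- acc / nrow(dirs)
    res[oi, nfeat + 1L] <- as.numeric(n_empty == nrow(dirs))
  }
  cols <- stats::setNames(lapply(seq_len(ncol(res)), function(cc) res[, cc]),
                          paste0("Texture_", colnames(res)))
  feature_table(ids, cols)
}
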