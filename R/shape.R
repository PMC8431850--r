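#' Euler number of a binary object
#'
#' Euler-Poincare characteristic of the cubical complex induced by the
#' foreground, computed by topological cell counting (never lookup tables):
#'
#' * full connectivity (8-connected in 2D, 26 in 3D; the default): pixels
#'   are closed unit squares/cubes; the characteristic is
#'   `V - E + F (- C)` over the distinct vertices, edges, faces (and cubes)
#'   of their union.
#' * face connectivity (4 / 6): the adjacency complex whose vertices are
#'   the pixels, edges the face-adjacent pairs, squares the fully-foreground
#'   `2x2` blocks and cubes the fully-foreground `2x2x2` blocks.
#'
#' In 2D this equals components minus holes; in 3D components minus tunnels
#' plus cavities. It is additive over disjoint objects.
#'
#' @param mask Non-empty logical array (2D or 3D).
#' @param connectivity `"full"` (default) or `"face"`.
#' @return Integer Euler number.
#' @export
euler_number <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  if (!any(mask)) stop_mq("mask is empty", "mq_value_error")
  dims <- dim(mask)
  nd <- length(dims)
  if (connectivity == "full") {
    # closed-pixel complex: a k-cell of the grid complex is present if any
    # incident pixel is foreground
    cell_count <- function(axes_spanned) {
      # cells spanning `axes_spanned` (logical per axis): count distinct
      # cells touched by the foreground via a logical OR of shifts
      grid_dims <- dims + ifelse(axes_spanned, 0L, 1L)
      acc <- array(FALSE, grid_dims)
      offsets <- do.call(expand.grid, lapply(seq_len(nd), function(ax)
        if (axes_spanned[ax]) 0L else 0:1))
      for (r in seq_len(nrow(offsets))) {
        to <- lapply(seq_len(nd), function(ax)
          seq_len(dims[ax]) + offsets[r, ax])
        acc <- assign_array(acc, to, index_array(acc, to) | mask)
      }
      sum(acc)
    }
    total <- 0L
    spans <- as.matrix(do.call(expand.grid, rep(list(c(FALSE, TRUE)), nd)))
    for (r in seq_len(nrow(spans))) {
      k <- sum(spans[r, ])
      total <- total + (-1L)^k * cell_count(spans[r, ])
    }
    return(as.integer(total))
  }
  # face connectivity: adjacency complex on pixels
  block_count <- function(axes_spanned) {
    acc <- mask
    for (ax in which(axes_spanned)) {
      n <- dims[ax]
      lo <- lapply(seq_len(nd), function(a2)
        if (a2 == ax) seq_len(n - 1L) else seq_len(dim(acc)[a2]))
      hi <- lapply(seq_len(nd), function(a2)
        if (a2 == ax) seq_len(n - 1L) + 1L else seq_len(dim(acc)[a2]))
      acc <- index_array(acc, lo) & index_array(acc, hi)
    }
    sum(acc)
  }
  total <- 0L
  spans <- as.matrix(do.call(expand.grid, rep(list(c(FALSE, TRUE)), nd)))
  for (r in seq_len(nrow(spans))) {
    k <- sum(spans[r, ])
    total <- total + (-1L)^k * block_count(spans[r, ])
  }
  as.integer(total)
}

#' Solidity of a binary object
#'
#' Object size divided by the number of pixels of its filled convex hull.
#' The hull is taken over the corner points of the object's pixels and
#' filled by boundary-inclusive pixel-center testing, in 2D or 3D; convex
#' digital shapes therefore have solidity exactly 1. Degenerate
#' (collinear/coplanar) objects are hulled in their affine span, and objects
#' of at most 2 pixels have solidity 1.
#'
#' @param mask Non-empty logical array (2D or 3D).
#' @return Solidity in `(0, 1]`.
#' @export
solidity <- function(mask) {
  if (!any(mask)) stop_mq("mask is empty", "mq_value_error")
  n <- sum(mask)
  n / hull_fill_count(mask)
}

# 2D perimeter as total crack length: the number of unit pixel edges
# exposed to background or to the image border.
crack_perimeter <- function(mask) {
  dims <- dim(mask)
  total <- 0L
  for (ax in 1:2) {
    n <- dims[ax]
    lo <- lapply(1:2, function(a2) if (a2 == ax) seq_len(n - 1L) else
      seq_len(dims[a2]))
    hi <- lapply(1:2, function(a2) if (a2 == ax) seq_len(n - 1L) + 1L else
      seq_len(dims[a2]))
    inner <- sum(xor(index_array(mask, lo), index_array(mask, hi)))
    first <- lapply(1:2, function(a2) if (a2 == ax) 1L else seq_len(dims[a2]))
    last <- lapply(1:2, function(a2) if (a2 == ax) n else seq_len(dims[a2]))
    border <- sum(index_array(mask, first)) + sum(index_array(mask, last))
    total <- total + inner + border
  }
  total
}

shape_feature_groups <- c("size", "bbox", "centroid", "moments", "inertia",
                          "eccentricity", "extent", "perimeter",
                          "form_factor", "solidity", "euler")

#' Per-object 2D/3D shape measurements
#'
#' One row per object. Geometry uses 0-based pixel-center coordinates, axes
#' `(z,)y,x`, and half-open bounding boxes `[min, max)`. Features:
#'
#' * `size`: pixel/voxel count; `bbox_min_*`, `bbox_max_*`; `centroid_*`.
#' * `moments`: central moments `mu_<powers>` up to total order 3 (powers in
#'   axis order, e.g. `mu_21` in 2D, `mu_021` in 3D) and normalized moments
#'   `eta_<powers>` (`eta = mu / size^(1 + order/ndim)`).
#' * `inertia`: the second-central-moment (covariance) tensor of the pixel
#'   coordinates, `T_ab = sum (c_a - mean_a)(c_b - mean_b) / size`, its
#'   entries `inertia_<ab>` and eigenvalues `inertia_eigval_<k>` sorted
#'   descending.
#' * `eccentricity` (2D): `sqrt(1 - lambda_min / lambda_max)`.
#' * `extent`: size / bounding-box volume. `perimeter` (2D): crack length
#'   (exposed unit pixel edges). `form_factor` (2D):
#'   `4 * pi * size / perimeter^2`. [solidity()] and [euler_number()]
#'   (full connectivity).
#'
#' @param labels A [label_image()] with at least one object.
#' @param which Character vector of feature groups (see above), or `"all"`.
#' @return A feature table.
#' @export
measure_shapes <- function(labels, which = "all") {
  if (identical(which, "all")) which <- shape_feature_groups
  bad <- setdiff(which, shape_feature_groups)
  if (length(bad))
    stop_mq(paste0("unknown feature name(s): ", paste(bad, collapse = ", "),
                   "; valid names: ", paste(shape_feature_groups, collapse = ", ")),
            "mq_value_error")
  lab <- labels$labels
  dims <- dim(lab)
  nd <- length(dims)
  ax <- axis_names(nd)
  ids <- object_ids(labels)
  if (length(ids) == 0L) stop_mq("label image has no objects", "mq_value_error")
  if (nd == 3L && any(c("eccentricity", "perimeter", "form_factor") %in% which))
    stop_mq("eccentricity, perimeter and form_factor are 2D-only features",
            "mq_value_error")
  rows <- vector("list", length(ids))
  for (oi in seq_along(ids)) {
    m <- lab == ids[oi]
    co <- which_coords(m)  # 0-based, (z,)y,x columns
    n <- nrow(co)
    f <- list()
    if ("size" %in% which) f$size <- n
    if ("bbox" %in% which) {
      for (a in seq_len(nd)) {
        f[[paste0("bbox_min_", ax[a])]] <- min(co[, a])
        f[[paste0("bbox_max_", ax[a])]] <- max(co[, a]) + 1  # half-open
      }
    }
    ctr <- colMeans(co)
    if ("centroid" %in% which)
      for (a in seq_len(nd)) f[[paste0("centroid_", ax[a])]] <- ctr[a]
    cc <- sweep(co, 2L, ctr)
    if ("moments" %in% which) {
      pows <- as.matrix(do.call(expand.grid, rep(list(0:3), nd)))
      pows <- pows[rowSums(pows) <= 3L, , drop = FALSE]
      pows <- pows[order(rowSums(pows),
                         apply(pows, 1L, paste, collapse = "")), , drop = FALSE]
      for (r in seq_len(nrow(pows))) {
        p <- pows[r, ]
        tag <- paste(p, collapse = "")
        mu <- sum(apply(sweep(cc, 2L, p, function(x, k) x^k), 1L, prod))
        f[[paste0("mu_", tag)]] <- mu
        ord <- sum(p)
        f[[paste0("eta_", tag)]] <- mu / n^(1 + ord / nd)
      }
    }
    if (any(c("inertia", "eccentricity") %in% which)) {
      Tm <- crossprod(cc) / n
      if ("inertia" %in% which) {
        for (a in seq_len(nd)) for (b in a:nd)
          f[[paste0("inertia_", ax[a], ax[b])]] <- Tm[a, b]
        ev <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
        ev <- pmax(ev, 0)
        for (k in seq_len(nd)) f[[paste0("inertia_eigval_", k)]] <- ev[k]
      }
      if ("eccentricity" %in% which) {
        ev <- sort(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values,
                   decreasing = TRUE)
        ev <- pmax(ev, 0)
        f$eccentricity <- if (ev[1] <= 0) 0 else sqrt(1 - ev[nd] / ev[1])
      }
    }
    if ("extent" %in% which) {
      bbvol <- prod(apply(co, 2L, function(v) max(v) - min(v) + 1))
      f$extent <- n / bbvol
    }
    if ("perimeter" %in% which || "form_factor" %in% which) {
      per <- crack_perimeter(m)
      if ("perimeter" %in% which) f$perimeter <- per
      if ("form_factor" %in% which) f$form_factor <- 4 * pi * n / per^2
    }
    if ("solidity" %in% which) f$solidity <- solidity(m)
    if ("euler" %in% which) f$euler <- euler_number(m)
    rows[[oi]] <- f
  }
  cols <- names(rows[[1L]])
  feature_table(ids, stats::setNames(
    lapply(cols, function(cn) vapply(rows, function(r) r[[cn]], numeric(1))),
    cols))
}
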