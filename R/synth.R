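#' Synthetic fixture specification
#'
#' Bundles the parameters of the deterministic fixture generators. The seed
#' fixes all randomness; identical specs produce identical fixtures.
#'
#' @param shape Integer vector of image extents (length 2 or 3, each >= 16).
#' @param n_objects Number of objects (blob generators).
#' @param radius Length-2 numeric range of blob radii.
#' @param overlap Target intersection-over-union in `[0, 1]` for
#'   [make_object_pair()].
#' @param rho Target Pearson correlation in `[-1, 1]` for
#'   [make_correlated_pair()].
#' @param bit_depth 8 or 16.
#' @param seed Integer seed.
#' @return A `mq_fixture_spec` list.
#' @export
fixture_spec <- function(shape = c(64L, 64L), n_objects = 5L,
                         radius = c(4, 7), overlap = 0.5, rho = 0.5,
                         bit_depth = 8L, seed = 1L) {
  shape <- as.integer(shape)
  if (!length(shape) %in% 2:3 || any(shape < 16L))
    stop_mq("shape must be 2 or 3 extents, each >= 16", "mq_value_error")
  if (overlap < 0 || overlap > 1)
    stop_mq("overlap must be in [0, 1]", "mq_value_error")
  if (rho < -1 || rho > 1) stop_mq("rho must be in [-1, 1]", "mq_value_error")
  if (!bit_depth %in% c(8L, 16L))
    stop_mq("bit_depth must be 8 or 16", "mq_value_error")
  structure(list(shape = shape, n_objects = as.integer(n_objects),
                 radius = as.numeric(radius), overlap = overlap, rho = rho,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "mq_fixture_spec")
}

# Rasterize a disc/sphere into a label array (0-based center coordinates).
paint_blob <- function(lab, center, radius, id) {
  dims <- dim(lab)
  nd <- length(dims)
  rg <- lapply(seq_len(nd), function(ax)
    max(1L, floor(center[ax] - radius) + 1L):min(dims[ax], ceiling(center[ax] + radius) + 1L))
  co <- as.matrix(do.call(expand.grid, rg))
  d2 <- rowSums(sweep(co - 1, 2L, center)^2)
  sel <- d2 <= radius^2
  lab[co[sel, , drop = FALSE]] <- id
  lab
}

#' Random blob label image
#'
#' Places `n_objects` random discs (2D) or spheres (3D). With
#' `touching = FALSE` (default) blobs are rejected until pairwise disjoint
#' with at least one background pixel between them, so the image has exactly
#' `n_objects` connected components; with `touching = TRUE` blobs may
#' overlap and later blobs overwrite earlier ones. With
#' `at_border = TRUE` centers may fall near the image edge so objects are
#' clipped by the border.
#'
#' @param spec A [fixture_spec()].
#' @param touching Allow blobs to touch/overlap.
#' @param at_border Allow blobs clipped at the image border.
#' @return A [label_image()].
#' @export
make_blob_labels <- function(spec, touching = FALSE, at_border = FALSE) {
  dims <- spec$shape
  rmax <- max(spec$radius)
  if (!touching &&
      spec$n_objects * (2 * rmax)^length(dims) >= prod(dims))
    stop_mq("infeasible packing: too many/large objects for the image",
            "mq_value_error")
  with_seed(spec$seed, {
    lab <- array(0L, dims)
    centers <- matrix(numeric(0), 0, length(dims))
    radii <- numeric(0)
    placed <- 0L
    tries <- 0L
    while (placed < spec$n_objects) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, spec$n_objects))
        stop_mq("infeasible packing: could not place objects", "mq_value_error")
      r <- stats::runif(1, spec$radius[1], spec$radius[2])
      margin <- if (at_border) 0 else r + 1
      ctr <- vapply(dims, function(n) stats::runif(1, margin, n - 1 - margin),
                    numeric(1))
      if (!touching && placed > 0L) {
        gaps <- sqrt(rowSums(sweep(centers, 2L, ctr)^2)) - radii - r
        if (any(gaps < 2)) next
      }
      placed <- placed + 1L
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
      lab <- paint_blob(lab, ctr, r, placed)
    }
    # overwriting can in principle empty an earlier object: relabel
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) && !identical(ids, seq_along(ids))) {
      remap <- integer(max(ids) + 1L)
      remap[ids + 1L] <- seq_along(ids)
      lab[lab > 0L] <- remap[lab[lab > 0L] + 1L]
    }
    label_image(lab)
  })
}

# Center distance giving a target IoU for two equal discs/spheres of
# radius r (continuous geometry), found by bisection.
iou_distance <- function(r, target, ndim) {
  if (target >= 1) return(0)
  if (target <= 0) return(2 * r + 4)
  inter <- function(d) {
    if (d >= 2 * r) return(0)
    if (ndim == 2) {
      2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
    } else {
      (pi / 12) * (4 * r + d) * (2 * r - d)^2
    }
  }
  vol <- if (ndim == 2) pi * r^2 else (4 / 3) * pi * r^3
  iou <- function(d) { A <- inter(d); A / (2 * vol - A) }
  lo <- 0; hi <- 2 * r
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (iou(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Paired object sets with controlled overlap
#'
#' Generates two label images with `n_objects` paired discs/spheres of
#' equal radius: the second set's objects are shifted copies of the first,
#' with the shift chosen so each pair's intersection-over-union
#' approximates `spec$overlap` (continuous-geometry inversion; pixelation
#' keeps the realized IoU within about 0.1 of the target for radii >= 4).
#' Pairs are laid out on a coarse grid so different pairs never interact.
#'
#' @param spec A [fixture_spec()].
#' @return List of two [label_image()]s, `initial` and `addition`.
#' @export
make_object_pair <- function(spec) {
  dims <- spec$shape
  nd <- length(dims)
  with_seed(spec$seed, {
    r <- mean(spec$radius)
    d <- iou_distance(r, spec$overlap, nd)
    # pairs are elongated along one axis, so tile with cells that are long
    # along the pair axis and narrow across it
    axis <- sample.int(nd, 1L)
    cell <- rep(ceiling(2 * r + 3), nd)
    cell[axis] <- ceiling(2 * r + d + 3)
    ncell <- pmax(floor((dims - 2) / cell), 0L)
    if (prod(ncell) < spec$n_objects)
      stop_mq("infeasible packing for paired objects", "mq_value_error")
    cells <- sample(prod(ncell), spec$n_objects)
    A <- array(0L, dims); B <- array(0L, dims)
    for (i in seq_len(spec$n_objects)) {
      ci <- arrayInd(cells[i], ncell) - 1L
      base <- as.numeric(ci) * cell + cell / 2
      dir <- rep(0, nd)
      dir[axis] <- sample(c(-1, 1), 1L)
      ctrA <- base - dir * d / 2
      ctrB <- base + dir * d / 2
      A <- paint_blob(A, ctrA, r, i)
      B <- paint_blob(B, ctrB, r, i)
    }
    list(initial = label_image(A), addition = label_image(B))
  })
}

# Separable Gaussian smoothing with symmetric (reflective) padding.
gauss_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  dims <- dim(x)
  nd <- length(dims)
  for (ax in seq_len(nd)) {
    n <- dims[ax]
    pad_idx <- c(rev(seq_len(min(r, n))), seq_len(n),
                 rev(n + 1L - seq_len(min(r, n))))
    perm <- c(ax, setdiff(seq_len(nd), ax))
    g <- aperm(x, perm)
    gd <- dim(g)
    gm <- matrix(g, nrow = n)
    gp <- gm[pad_idx, , drop = FALSE]
    sm <- matrix(0, n, ncol(gm))
    for (kk in seq_along(kern))
      sm <- sm + kern[kk] * gp[seq_len(n) + (kk - 1L), , drop = FALSE]
    x <- aperm(array(sm, gd), order(perm))
  }
  x
}

# A fluorescence-like field: sparse bright spots over a dim,
# spatially-correlated noise background. Spots are Gaussian bumps truncated
# at 3 sigma (compact support), so outside its spots a field is exactly
# background: structures end, as in real images, rather than having
# infinite skirts. Most pixels are dim background, with a bright tail from
# the spots.
fluor_field <- function(dims, n_spots = 8L, spot_sigma = 3, noise_amp = 0.1,
                        noise_sigma = 1.5) {
  nd <- length(dims)
  f <- noise_amp * gauss_smooth(array(stats::rnorm(prod(dims)), dims),
                                noise_sigma)
  co <- which_coords(array(TRUE, dims))
  for (i in seq_len(n_spots)) {
    ctr <- vapply(dims, function(n) stats::runif(1, 2, n - 3), numeric(1))
    amp <- stats::runif(1, 0.5, 1)
    d2 <- rowSums(sweep(co, 2L, ctr)^2)
    bump <- amp * (exp(-d2 / (2 * spot_sigma^2)) - exp(-4.5))
    bump[d2 > (3 * spot_sigma)^2] <- 0
    f <- f + array(pmax(bump, 0), dims)
  }
  f
}

#' Correlated intensity image pair
#'
#' Builds two fluorescence-like channels (sparse bright spots over a dim
#' correlated-noise background) from a shared structure field plus
#' independent fields. The shared field carries colocalized structures only
#' (no background), so the between-channel background correlation is near
#' zero as in real channel pairs; each channel additionally carries a mild
#' exclusion imprint of the other's structures (`exclusion`), emulating
#' volume exclusion / bleed-through compensation, which makes the
#' background-set correlation slightly negative so the below-threshold
#' correlation profile crosses zero decisively at the structure/background
#' boundary.
#'
#' The realized fields are orthonormalized before mixing, so prior to
#' quantization the empirical Pearson correlation equals `spec$rho`
#' exactly; quantization to the requested bit depth perturbs it only
#' slightly (well within 0.05 at 64 x 64). Channels are min-max rescaled to
#' `[0, 1]` (an affine map, preserving correlation) and snapped to the
#' grey-level grid.
#'
#' @param spec A [fixture_spec()].
#' @param n_spots Bright structures per underlying field (default 8).
#' @param exclusion Strength of the cross-channel exclusion imprint, scaled
#'   internally by `sqrt(1 - |rho|)` and capped so the channel-specific
#'   component keeps at least 5% of the variance. Default 0.3.
#' @return List of two [intensity_image()]s, `a` and `b`.
#' @export
make_correlated_pair <- function(spec, n_spots = 8L, exclusion = 0.3) {
  dims <- spec$shape
  G <- as.integer(2^spec$bit_depth)
  with_seed(spec$seed, {
    fields <- c(list(fluor_field(dims, n_spots = n_spots, noise_amp = 0)),
                lapply(1:2, function(i) fluor_field(dims, n_spots = n_spots)))
    M <- vapply(fields, as.vector, numeric(prod(dims)))
    M <- scale(M, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(M))           # orthonormal realized fields
    rho <- spec$rho
    s <- sign(rho + (rho == 0))
    # z1 = a Q1 + b Q2 ; z2 = s (a Q1 - g Q2) + d Q3, unit norms, so the
    # realized correlation is exactly s (a^2 - b g) = rho
    g <- exclusion * sqrt(1 - abs(rho))
    solve_a2 <- function(g) {
      if (g == 0 || abs(rho) >= 1) return(abs(rho))
      stats::uniroot(function(a2) a2 - sqrt(1 - a2) * g - abs(rho),
                     c(abs(rho), 1), tol = 1e-14)$root
    }
    a2 <- solve_a2(g)
    if (1 - a2 - g^2 < 0.05) {
      g <- sqrt(max(1 - a2 - 0.05, 0))
      a2 <- solve_a2(g)
    }
    aw <- sqrt(a2); bw <- sqrt(1 - a2)
    dw <- sqrt(max(1 - a2 - g^2, 0))
    z1 <- aw * Q[, 1] + bw * Q[, 2]
    z2 <- s * (aw * Q[, 1] - g * Q[, 2]) + dw * Q[, 3]
    tune <- function(z) {
      z <- (z - min(z)) / (max(z) - min(z))
      round(z * (G - 1)) / (G - 1)
    }
    a <- array(tune(z1), dims)
    b <- array(tune(z2), dims)
    list(a = intensity_image(a, G), b = intensity_image(b, G))
  })
}
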