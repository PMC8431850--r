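# Independent brute-force oracles, deliberately written with naive loops so
# they share no code path with the package implementations.

# Otsu: exhaustive search over interior bin edges, classes split by bin
# membership, between-class variance from explicit class means.
brute_otsu <- function(v, nbins) {
  mn <- min(v); mx <- max(v)
  bin <- pmin(floor((v - mn) / (mx - mn) * nbins) + 1L, nbins)
  best <- -Inf; best_edge <- NA_real_
  for (k in seq_len(nbins - 1L)) {
    in0 <- bin <= k
    n0 <- sum(in0); n1 <- sum(!in0)
    if (n0 == 0L || n1 == 0L) next
    mids <- mn + (bin - 0.5) * (mx - mn) / nbins
    mu0 <- mean(mids[in0]); mu1 <- mean(mids[!in0])
    w0 <- n0 / length(v)
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best + 1e-15) { best <- bcv; best_edge <- mn + k * (mx - mn) / nbins }
  }
  best_edge
}

# Exhaustive nearest-seed assignment: for every query pixel, the squared
# distance to every seed pixel of every object; ties to the earlier object.
brute_nearest_seed <- function(seed_masks, query_idx, dims) {
  co_q <- arrayInd(query_idx, dims)
  best <- rep(NA_integer_, length(query_idx))
  bd <- rep(Inf, length(query_idx))
  for (o in seq_along(seed_masks)) {
    sc <- which(seed_masks[[o]])
    if (!length(sc)) next
    co_s <- arrayInd(sc, dims)
    for (i in seq_along(query_idx)) {
      d <- min(colSums((t(co_s) - co_q[i, ])^2))
      if (d < bd[i]) { bd[i] <- d; best[i] <- o }
    }
  }
  best
}

# Euler characteristic by explicit cell enumeration on the closed cubical
# complex (full connectivity): collect distinct vertices/edges/faces/cubes
# of the union of closed unit pixels as coordinate-key strings.
brute_euler_full <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  cells <- lapply(0:nd, function(k) character(0))
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (p in seq_len(nrow(co))) {
    base <- co[p, ]
    verts <- sweep(corners, 2L, base, `+`)   # nd-cube corner coordinates
    # enumerate all sub-cells of this pixel cube: choose spanned axes
    for (r in seq_len(nrow(corners))) {
      span <- corners[r, ] == 1L             # reuse 0/1 grid as span chooser
      k <- sum(span)
      fixed_axes <- which(!span)
      combos <- if (length(fixed_axes))
        as.matrix(do.call(expand.grid, rep(list(0:1), length(fixed_axes))))
      else matrix(0L, 1, 0)
      for (cmb in seq_len(nrow(combos))) {
        lo <- base
        lo[fixed_axes] <- base[fixed_axes] + combos[cmb, ]
        key <- paste(c(k, lo, span), collapse = ",")
        cells[[k + 1L]] <- c(cells[[k + 1L]], key)
      }
    }
  }
  total <- 0L
  for (k in 0:nd)
    total <- total + (-1L)^k * length(unique(cells[[k + 1L]]))
  total
}

# GLCM by explicit pair enumeration.
brute_glcm <- function(quantized, mask, offset, levels) {
  dims <- dim(mask)
  co <- arrayInd(which(mask), dims)
  g <- matrix(0, levels, levels)
  for (p in seq_len(nrow(co))) {
    q <- co[p, ] + offset
    if (any(q < 1L) || any(q > dims)) next
    qm <- matrix(q, 1)
    if (!mask[qm]) next
    i <- quantized[matrix(co[p, ], 1)] + 1L
    j <- quantized[qm] + 1L
    g[i, j] <- g[i, j] + 1
  }
  g <- g + t(g)
  if (sum(g) > 0) g / sum(g) else g
}

# Point-in-convex-hull test by exhaustive supporting-plane search over all
# point triplets (3D) or pairs (2D); exact for integer coordinates.
brute_in_hull <- function(query, pts, tol = 1e-9) {
  nd <- ncol(pts)
  inside <- rep(TRUE, nrow(query))
  if (nd == 2L) {
    for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts))) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      nrm <- c(-d[2L], d[1L])
      vals <- as.vector(pts %*% nrm) - sum(nrm * pts[i, ])
      if (max(vals) <= tol)  # supporting line: all points on one side
        inside <- inside & (as.vector(query %*% nrm) - sum(nrm * pts[i, ]) <= tol)
    }
  } else {
    n <- nrow(pts)
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      u <- pts[j, ] - pts[i, ]; v <- pts[k, ] - pts[i, ]
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      if (all(nrm == 0)) next
      vals <- as.vector(pts %*% nrm) - sum(nrm * pts[i, ])
      if (max(vals) <= tol)
        inside <- inside & (as.vector(query %*% nrm) - sum(nrm * pts[i, ]) <= tol)
      else if (min(vals) >= -tol)
        inside <- inside & (as.vector(query %*% nrm) - sum(nrm * pts[i, ]) >= -tol)
    }
  }
  inside
}

# Connected components by flood fill (queue), for generator checks.
brute_components <- function(mask, connectivity = "full") {
  dims <- dim(mask)
  offs <- rbind(microquant:::half_offsets(length(dims), connectivity),
                -microquant:::half_offsets(length(dims), connectivity))
  seen <- array(FALSE, dims)
  ncomp <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      cc <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1L) || any(nb > dims)) next
        nbm <- matrix(nb, 1)
        lin <- 1L + sum((nb - 1L) * cumprod(c(1L, dims[-length(dims)])))
        if (mask[nbm] && !seen[lin]) { seen[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
  }
  ncomp
}

# Fixture helper: standard seeded correlated pair used across coloc tests.
coloc_pair <- function(rho, bits, seed, shape = c(64L, 64L)) {
  make_correlated_pair(fixture_spec(shape = shape, rho = rho,
                                    bit_depth = bits, seed = seed))
}

# Whether a pair's below-threshold correlation profile is monotone in the
# sense required for search equivalence: no defined correlation above zero
# at any candidate below the first crossing.
profile_monotone <- function(a, b, reg) {
  env <- microquant:::cs_engine(a, b, reg)
  ks <- env$kmax:0L
  cnts <- microquant:::cs_counts_vec(env, ks)
  change <- which(c(TRUE, diff(cnts) != 0))
  rs <- vapply(change, function(i) microquant:::cs_corr(env, ks[i]), numeric(1))
  i0 <- which(!is.na(rs) & rs <= 0)[1]
  if (is.na(i0)) return(TRUE)
  below <- rs[-seq_len(i0)]
  !any(!is.na(below) & below > 0)
}
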