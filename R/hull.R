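# Convex hull machinery for solidity.
#
# The hull is taken over the *corner points* of the object's pixels (the
# standard convex-hull-image convention, which makes convex digital shapes
# have solidity exactly 1) and filled by boundary-inclusive pixel-center
# testing. All coordinates are doubled internally so corners are integers
# and orientation tests are exact.

# Corner points (doubled coordinates) of the foreground pixels of a mask.
mask_corner_points <- function(mask) {
  co <- which_coords(mask) * 2L       # doubled pixel centers
  nd <- ncol(co)
  offs <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 1L)), nd)))
  pts <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
    sweep(co, 2L, offs[r, ], `+`)))
  unique(pts)
}

# Keep only points that are min/max along every axis line through them;
# extreme points of the set always survive this filter.
reduce_candidates <- function(pts) {
  nd <- ncol(pts)
  for (ax in seq_len(nd)) {
    others <- setdiff(seq_len(nd), ax)
    key <- do.call(paste, c(lapply(others, function(a) pts[, a]), sep = "_"))
    v <- pts[, ax]
    lo <- stats::ave(v, key, FUN = min)
    hi <- stats::ave(v, key, FUN = max)
    pts <- pts[v == lo | v == hi, , drop = FALSE]
  }
  pts
}

# Halfspace representation (A x <= b) of the convex hull of 2D points.
hull_halfspaces_2d <- function(pts) {
  h <- grDevices::chull(pts[, 2L], pts[, 1L])  # (x, y) args; returns order
  v <- pts[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(NULL)
  A <- matrix(0, n, 2L); b <- numeric(n)
  ctr <- colMeans(v)
  for (e in seq_len(n)) {
    p <- v[e, ]; q <- v[if (e == n) 1L else e + 1L, ]
    d <- q - p
    nrm <- c(-d[2L], d[1L])   # normal in (y, x) coords
    if (sum(nrm * (ctr - p)) > 0) nrm <- -nrm
    A[e, ] <- nrm
    b[e] <- sum(nrm * p)
  }
  list(A = A, b = b)
}

# Incremental 3D convex hull; returns halfspaces. Points must have full
# affine rank (checked by the caller).
hull_halfspaces_3d <- function(pts) {
  n <- nrow(pts)
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  # initial tetrahedron: spread points
  i1 <- which.min(pts[, 1] * 4 + pts[, 2] * 2 + pts[, 3] * 1e-9)
  d1 <- rowSums(sweep(pts, 2L, pts[i1, ])^2)
  i2 <- which.max(d1)
  e12 <- pts[i2, ] - pts[i1, ]
  ar <- vapply(seq_len(n), function(i)
    sum(cross3(e12, pts[i, ] - pts[i1, ])^2), numeric(1))
  i3 <- which.max(ar)
  nrm0 <- cross3(e12, pts[i3, ] - pts[i1, ])
  vol <- abs(as.vector(sweep(pts, 2L, pts[i1, ]) %*% nrm0))
  i4 <- which.max(vol)
  if (vol[i4] < 1e-9) return(NULL)  # coplanar; caller falls back
  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, , drop = FALSE])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nrm * (interior - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1L, orient))
  face_normal <- function(f) {
    nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    c(nrm, sum(nrm * pts[f[1], ]))
  }
  planes <- t(apply(faces, 1L, face_normal))
  for (p in setdiff(seq_len(n), verts)) {
    dists <- planes[, 1:3, drop = FALSE] %*% pts[p, ] - planes[, 4]
    visible <- which(dists > 1e-9)
    if (length(visible) == 0L) next
    vis_faces <- faces[visible, , drop = FALSE]
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                   vis_faces[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[ekey %in% names(which(table(ekey) == 1L)), ,
                     drop = FALSE]
    faces <- faces[-visible, , drop = FALSE]
    planes <- planes[-visible, , drop = FALSE]
    if (nrow(horizon) == 0L) next
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1L, orient))
    faces <- rbind(faces, newf)
    planes <- rbind(planes, t(apply(newf, 1L, face_normal)))
  }
  list(A = planes[, 1:3, drop = FALSE], b = planes[, 4])
}

# Number of grid pixel centers inside (boundary inclusive) the convex hull
# of the mask's pixel corner points; degenerate point sets are handled in
# their affine span.
hull_fill_count <- function(mask, tol = 1e-7) {
  dims <- dim(mask)
  nd <- length(dims)
  npx <- sum(mask)
  if (npx <= 2L) return(npx)  # solidity 1 by convention
  pts <- reduce_candidates(mask_corner_points(mask))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  rank <- sum(sv$d > 1e-7 * max(sv$d, 1))
  # all grid pixel centers of the bounding box, doubled coordinates
  bb <- lapply(seq_len(nd), function(ax)
    seq(min(pts[, ax]) + 1L, max(pts[, ax]) - 1L, by = 2L))
  if (any(vapply(bb, length, integer(1)) == 0L)) bb <- lapply(dims, function(n) seq(0L, 2L * (n - 1L), by = 2L))
  q <- as.matrix(do.call(expand.grid, bb))
  if (rank == nd) {
    hs <- if (nd == 2L) hull_halfspaces_2d(pts) else hull_halfspaces_3d(pts)
    if (!is.null(hs)) {
      scale <- sqrt(rowSums(hs$A^2))
      inside <- rep(TRUE, nrow(q))
      for (f in seq_len(nrow(hs$A)))
        inside <- inside & (q %*% hs$A[f, ] <= hs$b[f] + tol * max(scale[f], 1))
      return(sum(inside))
    }
    rank <- nd - 1L  # numerically flat; fall through to span handling
  }
  basis <- sv$v[, seq_len(rank), drop = FALSE]
  qc <- sweep(q, 2L, ctr)
  resid <- qc - qc %*% basis %*% t(basis)
  onspan <- sqrt(rowSums(resid^2)) <= tol * 10
  qp <- qc[onspan, , drop = FALSE] %*% basis
  pp <- sweep(pts, 2L, ctr) %*% basis
  if (rank == 1L) {
    inside <- qp[, 1] >= min(pp[, 1]) - tol & qp[, 1] <= max(pp[, 1]) + tol
    return(sum(inside))
  }
  hs <- hull_halfspaces_2d(pp)
  if (is.null(hs)) return(npx)
  inside <- rep(TRUE, nrow(qp))
  for (f in seq_len(nrow(hs$A)))
    inside <- inside & (qp %*% hs$A[f, ] <= hs$b[f] + tol)
  sum(inside)
}
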