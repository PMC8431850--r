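# Exact Euclidean distance transforms (squared), used by the object-set
# combination strategies for nearest-object assignment and seeded growth.
#
# Separable lower-envelope algorithm: each axis pass computes, for every
# line, d(p) = min_q ((p - q)^2 + f(q)) over the previous pass's output.
# With seed cost 0 and unit pixel spacing all attained minima are integers,
# so squared distances are exact and ties can be detected exactly.

MQ_EDT_INF <- 1e18

dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Squared Euclidean distance from every cell to the nearest TRUE cell of
# `seed` (2D or 3D logical array). Cells with no reachable seed get a value
# >= MQ_EDT_INF.
edt_squared <- function(seed) {
  dims <- dim(seed)
  nd <- length(dims)
  f <- array(ifelse(seed, 0, MQ_EDT_INF), dims)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    g <- aperm(f, perm)
    gd <- dim(g)
    gm <- matrix(g, nrow = dims[ax])
    for (j in seq_len(ncol(gm))) gm[, j] <- dt1d(gm[, j])
    f <- aperm(array(gm, gd), order(perm))
  }
  f
}

# Assign each query pixel (linear indices `query_idx`) to the nearest seed
# set among `seed_masks` (list of logical arrays). Ties go to the earlier
# entry of the list. Returns integer vector of list positions (NA when no
# seed set reaches a query pixel).
nearest_seed_assign <- function(seed_masks, query_idx, dims) {
  n <- length(query_idx)
  if (n == 0L) return(integer(0))
  best_d <- rep(Inf, n)
  best_o <- rep(NA_integer_, n)
  for (o in seq_along(seed_masks)) {
    dmap <- edt_squared(seed_masks[[o]])
    dq <- dmap[query_idx]
    better <- dq < best_d  # strict: ties keep the earlier (lower-order) object
    best_d[better] <- dq[better]
    best_o[better] <- o
  }
  best_o[best_d >= MQ_EDT_INF] <- NA_integer_
  best_o
}
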