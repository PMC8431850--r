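# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Neighborhood displacement vectors. Only "positive" half-space offsets are
# returned (each unordered pixel pair appears once when shifting).
half_offsets <- function(ndim, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  grid <- do.call(expand.grid, rep(list(-1:1), ndim))
  grid <- as.matrix(grid)
  keep <- rowSums(abs(grid)) > 0
  grid <- grid[keep, , drop = FALSE]
  if (connectivity == "face") grid <- grid[rowSums(abs(grid)) == 1, , drop = FALSE]
  # keep one representative of each {d, -d} pair: first nonzero component > 0
  pos <- apply(grid, 1, function(d) d[match(TRUE, d != 0)] > 0)
  grid[pos, , drop = FALSE]
}

# Index arrays for shifting an array by an integer offset; returns NULL if the
# shifted overlap is empty. Used for adjacency and GLCM pair enumeration.
shift_overlap <- function(dims, offset) {
  nd <- length(dims)
  from <- vector("list", nd)
  to <- vector("list", nd)
  for (ax in seq_len(nd)) {
    d <- offset[ax]
    n <- dims[ax]
    if (abs(d) >= n) return(NULL)
    if (d >= 0) {
      from[[ax]] <- seq_len(n - d)
      to[[ax]] <- seq_len(n - d) + d
    } else {
      from[[ax]] <- seq_len(n + d) - d
      to[[ax]] <- seq_len(n + d)
    }
  }
  list(from = from, to = to)
}

# Extract a subarray by a list of index vectors.
index_array <- function(x, idx) {
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

assign_array <- function(x, idx, value) {
  do.call(`[<-`, c(list(x), idx, list(value = value)))
}

# Coordinates (0-based, one row per element of `which`) of TRUE cells.
which_coords <- function(mask) {
  stopifnot(is.logical(mask) || is.numeric(mask))
  d <- dim(mask)
  w <- which(as.logical(mask))
  if (length(w) == 0L) return(matrix(numeric(0), 0, length(d)))
  arrayInd(w, d) - 1L
}

axis_names <- function(ndim) if (ndim == 2L) c("y", "x") else c("z", "y", "x")

stop_mq <- function(msg, class) {
  stop(structure(class = c(class, "mq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
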