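#' Pixels disputed between two object sets
#'
#' The disputed region of two label images is the set of pixels claimed by
#' objects from both sets, i.e. the intersection of their foregrounds.
#'
#' @param initial,addition [label_image()]s of identical shape.
#' @return Logical array, `TRUE` exactly where both inputs are foreground.
#' @export
overlap_mask <- function(initial, addition) {
  if (!identical(dim(initial$labels), dim(addition$labels)))
    stop_mq("label images must have identical shape", "mq_dim_error")
  initial$labels > 0L & addition$labels > 0L
}

#' Combine two object sets into one
#'
#' Merges two independently segmented object sets into a single label image.
#' Overlap between the sets (the disputed region) is resolved by one of four
#' strategies:
#'
#' * `preserve`: every pixel of the initial set keeps its object; addition
#'   objects contribute only their pixels outside the initial foreground, and
#'   vanish if fully covered.
#' * `discard`: the initial set is kept intact; an addition object is added
#'   whole only if it shares no pixel with the initial foreground.
#' * `merge`: starts from `preserve`, reassigns each disputed pixel to the
#'   nearest initial-set object (Euclidean distance to that object's
#'   undisputed pixels), then fuses touching output objects that originate
#'   from different input sets (including initial objects bridged by an
#'   addition object).
#' * `segment`: the union of both foregrounds is re-segmented; undisputed
#'   pixels keep their source object and disputed pixels are assigned by
#'   seeded nearest-seed growth where each object's undisputed pixel set is
#'   its seed. Objects with no undisputed pixels are dropped.
#'
#' Distance ties are broken towards the object that comes first in
#' (source set, original id) order. Output ids are relabeled sequentially
#' from 1 in (source set, original id) order; for `merge`, fused groups take
#' the rank of their first member.
#'
#' @param initial,addition [label_image()]s of identical shape.
#' @param strategy One of `"merge"`, `"preserve"`, `"discard"`, `"segment"`.
#' @param connectivity `"full"` (8-neighbor in 2D, 26 in 3D; default) or
#'   `"face"` (4 / 6); used by `merge` to decide which objects touch.
#' @return A list with `labels` (the combined [label_image()]) and `report`,
#'   a one-row `data.frame` with `n_initial`, `n_added`, `n_dropped`
#'   (addition objects dropped), `n_dropped_initial` (initial objects lost in
#'   degenerate `segment`/`merge` cases), `n_disputed_pixels` and `strategy`.
#' @export
combine_objects <- function(initial, addition,
                            strategy = c("merge", "preserve", "discard",
                                         "segment"),
                            connectivity = c("full", "face")) {
  strategy <- match.arg(strategy)
  connectivity <- match.arg(connectivity)
  L1 <- initial$labels
  L2 <- addition$labels
  if (!identical(dim(L1), dim(L2)))
    stop_mq("label images must have identical shape", "mq_dim_error")
  dims <- dim(L1)
  disputed <- L1 > 0L & L2 > 0L
  ids1 <- sort(unique(L1[L1 > 0L]))
  ids2 <- sort(unique(L2[L2 > 0L]))
  n1 <- length(ids1)

  # working labels: initial objects as 1..n1, addition objects as n1 + rank
  rank1 <- integer(max(c(0L, ids1)) + 1L)
  rank1[ids1 + 1L] <- seq_along(ids1)
  rank2 <- integer(max(c(0L, ids2)) + 1L)
  rank2[ids2 + 1L] <- n1 + seq_along(ids2)
  W1 <- array(0L, dims); W1[L1 > 0L] <- rank1[L1[L1 > 0L] + 1L]
  W2 <- array(0L, dims); W2[L2 > 0L] <- rank2[L2[L2 > 0L] + 1L]

  out <- W1
  dropped2 <- integer(0)
  dropped1 <- integer(0)

  if (strategy == "preserve" || strategy == "merge") {
    add_px <- L2 > 0L & L1 == 0L
    out[add_px] <- W2[add_px]
    dropped2 <- setdiff(unique(W2[W2 > 0L]), unique(out[out > 0L]))
  } else if (strategy == "discard") {
    bad <- unique(W2[disputed])
    keep_px <- L2 > 0L & !(W2 %in% bad)
    out[keep_px] <- W2[keep_px]
    dropped2 <- bad
  } else { # segment
    add_px <- L2 > 0L & L1 == 0L
    out[add_px] <- W2[add_px]
    seeds1 <- lapply(seq_len(n1), function(o) W1 == o & !disputed)
    seeds2 <- lapply(n1 + seq_along(ids2), function(o) W2 == o & !disputed)
    seeds <- c(seeds1, seeds2)
    has_seed <- vapply(seeds, any, logical(1))
    q_idx <- which(disputed)
    if (any(has_seed) && length(q_idx)) {
      owners <- which(has_seed)
      assign_to <- nearest_seed_assign(seeds[owners], q_idx, dims)
      out[q_idx] <- owners[assign_to]
    }
    # drop seedless objects; if nothing has a seed (identical foregrounds)
    # disputed pixels keep their initial owner and only addition objects drop
    seedless <- which(!has_seed)
    dropped1 <- seedless[seedless <= n1]
    dropped2 <- seedless[seedless > n1]
    if (any(has_seed)) {
      present <- unique(out[out > 0L])
      dropped1 <- union(dropped1, setdiff(seq_len(n1), present))
      dropped2 <- union(dropped2, setdiff(n1 + seq_along(ids2), present))
    } else {
      dropped1 <- integer(0)
      dropped2 <- n1 + seq_along(ids2)
    }
  }

  if (strategy == "merge") {
    # reassign disputed pixels to the nearest initial object (by its
    # undisputed pixels); fully-disputed initial objects keep their pixels
    seeds <- lapply(seq_len(n1), function(o) W1 == o & !disputed)
    has_seed <- vapply(seeds, any, logical(1))
    q_idx <- which(disputed)
    if (any(has_seed) && length(q_idx)) {
      owners <- which(has_seed)
      assign_to <- nearest_seed_assign(seeds[owners], q_idx, dims)
      out[q_idx] <- owners[assign_to]
    }
    dropped1 <- setdiff(seq_len(n1), unique(out[out > 0L]))
    dropped2 <- setdiff(n1 + seq_along(ids2), unique(out[out > 0L]))
    out <- fuse_touching(out, n1, connectivity)
  }

  # sequential relabel in (source set, original id) order = working-rank order
  present <- sort(unique(out[out > 0L]))
  remap <- integer(max(c(0L, present)) + 1L)
  remap[present + 1L] <- seq_along(present)
  final <- array(0L, dims)
  final[out > 0L] <- remap[out[out > 0L] + 1L]

  n_added <- sum(present > n1)
  if (strategy == "merge") {
    # addition objects absorbed by fusion still contributed pixels
    n_added <- length(ids2) - length(dropped2)
  }
  report <- data.frame(
    n_initial = n1,
    n_added = n_added,
    n_dropped = length(dropped2),
    n_dropped_initial = length(dropped1),
    n_disputed_pixels = sum(disputed),
    strategy = strategy,
    stringsAsFactors = FALSE)
  list(labels = label_image(final), report = report)
}

# Fuse touching objects that originate from different source sets (working
# labels <= n1 are initial-set). Components of the cross-set adjacency graph
# collapse to the smallest member rank.
fuse_touching <- function(lab, n1, connectivity) {
  dims <- dim(lab)
  offs <- half_offsets(length(dims), connectivity)
  edges <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(offs))) {
    sh <- shift_overlap(dims, offs[r, ])
    if (is.null(sh)) next
    a <- index_array(lab, sh$from)
    b <- index_array(lab, sh$to)
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) next
    pair <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
    edges <- rbind(edges, pair)
  }
  if (nrow(edges) == 0L) return(lab)
  edges <- unique(edges)
  cross <- xor(edges[, 1] <= n1, edges[, 2] <= n1)
  edges <- edges[cross, , drop = FALSE]
  if (nrow(edges) == 0L) return(lab)
  # union-find over working ranks
  maxr <- max(lab)
  parent <- seq_len(maxr)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(maxr), find, integer(1))
  pos <- lab > 0L
  lab[pos] <- root[lab[pos]]
  lab
}
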