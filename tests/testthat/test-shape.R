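test_that("single pixels and solid squares have the symmetry-forced values", {
  lab <- array(0L, c(9, 9)); lab[5, 5] <- 1L
  t1 <- measure_shapes(label_image(lab))
  expect_equal(t1$size, 1)
  expect_equal(t1$solidity, 1)
  expect_equal(t1$euler, 1)
  mu_cols <- grep("^mu_", names(t1), value = TRUE)
  high <- mu_cols[vapply(mu_cols, function(n)
    sum(as.integer(strsplit(sub("mu_", "", n), "")[[1]])) >= 1, logical(1))]
  expect_true(all(t1[, high] == 0))

  lab2 <- array(0L, c(9, 9)); lab2[3:7, 3:7] <- 1L
  t2 <- measure_shapes(label_image(lab2))
  expect_equal(t2$centroid_y, 4)      # 0-based center of rows 3..7
  expect_equal(t2$centroid_x, 4)
  expect_equal(t2$extent, 1)
  expect_equal(t2$solidity, 1)
  expect_equal(t2$inertia_eigval_1, t2$inertia_eigval_2)
  expect_equal(t2$eccentricity, 0)
  expect_equal(t2$bbox_min_y, 2); expect_equal(t2$bbox_max_y, 7)  # half-open
})

test_that("moments, centroid and bbox equal brute-force summation", {
  for (s in 1:4) {
    lab <- make_blob_labels(fixture_spec(shape = c(16L, 16L), n_objects = 1L,
                                         radius = c(3, 5), seed = 600L + s),
                            touching = TRUE, at_border = TRUE)
    tab <- measure_shapes(lab)
    co <- which(lab$labels == 1L, arr.ind = TRUE) - 1
    n <- nrow(co); ctr <- colMeans(co)
    expect_equal(tab$size, n)
    expect_equal(c(tab$centroid_y, tab$centroid_x), unname(ctr))
    expect_equal(c(tab$bbox_min_y, tab$bbox_min_x),
                 unname(apply(co, 2, min)))
    expect_equal(c(tab$bbox_max_y, tab$bbox_max_x),
                 unname(apply(co, 2, max) + 1))
    for (p in 0:3) for (q in 0:(3 - p)) {
      mu <- sum((co[, 1] - ctr[1])^p * (co[, 2] - ctr[2])^q)
      expect_equal(tab[[paste0("mu_", p, q)]], mu, tolerance = 1e-10)
      expect_equal(tab[[paste0("eta_", p, q)]], mu / n^(1 + (p + q) / 2),
                   tolerance = 1e-10)
    }
    Tm <- crossprod(sweep(co, 2, ctr)) / n
    expect_equal(tab$inertia_yy, Tm[1, 1])
    expect_equal(tab$inertia_yx, Tm[1, 2])
    expect_equal(tab$inertia_xx, Tm[2, 2])
    ev <- sort(eigen(Tm)$values, decreasing = TRUE)
    expect_equal(c(tab$inertia_eigval_1, tab$inertia_eigval_2), ev)
  }
  # 3D moments on a small blob
  lab3 <- make_blob_labels(fixture_spec(shape = c(16L, 16L, 16L),
                                        n_objects = 1L, radius = c(3, 4),
                                        seed = 610L), touching = TRUE)
  t3 <- measure_shapes(lab3, which = c("size", "moments", "centroid"))
  co3 <- which(lab3$labels == 1L, arr.ind = TRUE) - 1
  ctr3 <- colMeans(co3)
  mu111 <- sum((co3[, 1] - ctr3[1]) * (co3[, 2] - ctr3[2]) * (co3[, 3] - ctr3[3]))
  expect_equal(t3$mu_111, mu111, tolerance = 1e-10)
})

test_that("Euler numbers match the cubical-complex counting oracle", {
  ring <- array(FALSE, c(7, 7)); ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  expect_equal(euler_number(ring), 0L)
  expect_equal(euler_number(ring), brute_euler_full(ring))

  shell <- array(FALSE, c(7, 7, 7))
  shell[2:6, 2:6, 2:6] <- TRUE; shell[3:5, 3:5, 3:5] <- FALSE
  expect_equal(euler_number(shell), 2L)
  expect_equal(euler_number(shell), brute_euler_full(shell))

  square <- array(FALSE, c(5, 5)); square[2:4, 2:4] <- TRUE
  expect_equal(euler_number(square), 1L)

  # additivity over disjoint objects, 2D and 3D, against the oracle
  set.seed(53)
  for (rep in 1:4) {
    m <- array(runif(64) > 0.55, c(8, 8))
    if (!any(m)) next
    expect_equal(euler_number(m), brute_euler_full(m))
  }
  m3 <- array(runif(216) > 0.6, c(6, 6, 6))
  if (any(m3)) expect_equal(euler_number(m3), brute_euler_full(m3))

  # face connectivity: diagonal pixels are separate components
  diagm <- array(FALSE, c(4, 4)); diagm[1, 1] <- diagm[2, 2] <- TRUE
  expect_equal(euler_number(diagm, "face"), 2L)
  expect_equal(euler_number(diagm, "full"), 1L)
})

test_that("solidity follows the corner-point hull convention", {
  plus <- array(FALSE, c(3, 3)); plus[2, ] <- TRUE; plus[, 2] <- TRUE
  expect_equal(solidity(plus), 5 / 9)
  ltro <- array(FALSE, c(2, 2)); ltro[1, 1] <- ltro[1, 2] <- ltro[2, 1] <- TRUE
  expect_equal(solidity(ltro), 3 / 4)
  # convex shapes: exactly 1 in 2D and 3D
  rect <- array(FALSE, c(8, 9)); rect[2:6, 3:8] <- TRUE
  expect_equal(solidity(rect), 1)
  box <- array(FALSE, c(7, 8, 9)); box[2:6, 2:7, 3:8] <- TRUE
  expect_equal(solidity(box), 1)
  # degenerate objects
  one <- array(FALSE, c(4, 4)); one[2, 2] <- TRUE
  expect_equal(solidity(one), 1)
  line <- array(FALSE, c(6, 6)); line[2, 2:5] <- TRUE
  expect_equal(solidity(line), 1)
  # a diagonal pixel line is NOT degenerate under the corner-point hull:
  # the hull is a band that also contains off-diagonal centers
  diagl <- array(FALSE, c(6, 6)); diagl[cbind(2:5, 2:5)] <- TRUE
  pts <- microquant:::reduce_candidates(microquant:::mask_corner_points(diagl))
  centers <- (which(array(TRUE, c(6, 6)), arr.ind = TRUE) - 1) * 2
  expect_equal(solidity(diagl), 4 / sum(brute_in_hull(centers, pts)))
  plane3 <- array(FALSE, c(5, 5, 5)); plane3[3, 2:4, 2:4] <- TRUE
  expect_equal(solidity(plane3), 1)
})

test_that("3D hull fill matches the exhaustive supporting-plane oracle", {
  for (s in 1:3) {
    lab <- make_blob_labels(fixture_spec(shape = c(16L, 16L, 16L),
                                         n_objects = 1L, radius = c(3, 4.5),
                                         seed = 700L + s), touching = TRUE)
    m <- lab$labels == 1L
    got <- microquant:::hull_fill_count(m)
    pts <- microquant:::reduce_candidates(microquant:::mask_corner_points(m))
    centers <- (which(array(TRUE, dim(m)), arr.ind = TRUE) - 1) * 2
    inside <- brute_in_hull(centers, pts, tol = 1e-9)
    expect_equal(got, sum(inside))
  }
})

test_that("rotating a mask by 90 degrees permutes axes, preserving features", {
  lab <- make_blob_labels(fixture_spec(shape = c(20L, 20L), n_objects = 1L,
                                       radius = c(4, 6), seed = 710L),
                          touching = TRUE)
  m <- lab$labels
  rot <- t(m[nrow(m):1, ])               # 90-degree rotation
  t1 <- measure_shapes(label_image(m))
  t2 <- measure_shapes(label_image(rot))
  for (f in c("size", "euler", "solidity", "perimeter", "extent"))
    expect_equal(t1[[f]], t2[[f]])
  expect_equal(sort(c(t1$inertia_eigval_1, t1$inertia_eigval_2)),
               sort(c(t2$inertia_eigval_1, t2$inertia_eigval_2)))
  # bbox extents swap axes
  expect_equal(t1$bbox_max_y - t1$bbox_min_y, t2$bbox_max_x - t2$bbox_min_x)
})

test_that("feature selection validates names and 2D-only features", {
  lab <- array(0L, c(6, 6)); lab[2:4, 2:4] <- 1L
  t1 <- measure_shapes(label_image(lab), which = c("size", "solidity"))
  expect_equal(names(t1), c("object_id", "size", "solidity"))
  expect_error(measure_shapes(label_image(lab), which = "zernike"),
               "valid names")
  lab3 <- array(0L, c(4, 4, 4)); lab3[2:3, 2:3, 2:3] <- 1L
  expect_error(measure_shapes(label_image(lab3), which = "perimeter"),
               "2D-only")
  # form factor of a digital disc under the crack-length convention
  disc <- array(0L, c(21, 21))
  cc <- which(array(TRUE, c(21, 21)), arr.ind = TRUE) - 1
  disc[sqrt(rowSums((cc - 10)^2)) <= 8] <- 1L
  td <- measure_shapes(label_image(disc), which = c("perimeter", "form_factor"))
  expect_equal(td$form_factor, 4 * pi * sum(disc) / td$perimeter^2)
})
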