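img2 <- function(v, gl = 256L) intensity_image(matrix(v, length(v), 1), gl)

test_that("Pearson correlation handles exact and undefined cases", {
  a <- img2(c(0.1, 0.4, 0.7, 0.9))
  expect_equal(pearson_r(a, a), 1)
  b <- img2(1 - c(0.1, 0.4, 0.7, 0.9))
  expect_equal(pearson_r(a, b), -1)
  expect_equal(pearson_r(img2(c(0, 0, 1, 1)), img2(c(0, 1, 0, 1))), 0)
  expect_true(is.na(pearson_r(a, img2(rep(0.5, 4)))))
  expect_true(is.na(pearson_r(a, a, mask = c(TRUE, FALSE, FALSE, FALSE))))
})

test_that("orthogonal regression recovers exact and noisy linear relations", {
  x <- seq(0.05, 0.4, length.out = 50)
  r <- costes_regression(img2(x), img2(2 * x + 0.1))
  expect_equal(r$slope, 2, tolerance = 1e-9)
  expect_equal(r$intercept, 0.1, tolerance = 1e-9)
  r2 <- costes_regression(img2(x), img2(x))
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)

  # noisy pair against the closed-form covariance-eigenvector solution
  set.seed(23)
  y <- pmin(pmax(0.8 * x + 0.05 + rnorm(50, 0, 0.02), 0), 1)
  r3 <- costes_regression(img2(x), img2(y))
  S <- stats::cov(cbind(x, y))
  ev <- eigen(S)$vectors[, 1]
  slope_oracle <- ev[2] / ev[1]
  expect_equal(r3$slope, slope_oracle, tolerance = 1e-9)
  # OLS option
  r4 <- costes_regression(img2(x), img2(y), type = "ols")
  expect_equal(r4$slope, unname(stats::coef(stats::lm(y ~ x))[2]),
               tolerance = 1e-9)
  expect_error(costes_regression(img2(rep(0.5, 50)), img2(x)),
               class = "mq_degenerate_error")
})

test_that("below-threshold correlation matches direct evaluation of the set", {
  set.seed(29)
  av <- round(runif(9) * 255) / 255
  bv <- round(pmin(pmax(av * 0.7 + 0.1 + rnorm(9, 0, 0.1), 0), 1) * 255) / 255
  a <- img2(av); b <- img2(bv)
  reg <- costes_regression(a, b)
  tA <- sort(av)[5]                      # include 5 pixels of channel A
  sel <- av <= tA & bv <= reg$slope * tA + reg$intercept
  expect_equal(below_threshold_corr(a, b, tA, reg$slope, reg$intercept),
               if (sum(sel) >= 2) stats::cor(av[sel], bv[sel]) else NA_real_)
  # full-set case and empty-set case
  expect_equal(below_threshold_corr(a, b, 1, reg$slope, max(bv) + reg$intercept),
               pearson_r(a, b), tolerance = 1e-12)
  expect_true(is.na(below_threshold_corr(a, b, min(av) - 0.01,
                                         reg$slope, reg$intercept)))
})

test_that("canonical scan equals brute-force candidate evaluation", {
  pr <- coloc_pair(0.6, 8L, 301, shape = c(24L, 24L))
  reg <- costes_regression(pr$a, pr$b)
  res <- costes_threshold_canonical(pr$a, pr$b, reg = reg)
  # brute force: walk the same candidate grid with the public operation
  k0 <- round(max(pr$a$values) * 255)
  found <- NULL; nvisited <- 0L
  for (j in 0:k0) {
    t <- (k0 - j) / 255
    r <- below_threshold_corr(pr$a, pr$b, t, reg$slope, reg$intercept)
    if (!is.na(r)) nvisited <- nvisited + 1L
    if (!is.na(r) && r <= 0) { found <- t; break }
  }
  expect_equal(res$tA, found)
  expect_true(res$converged)
  expect_equal(res$evaluations, nvisited)
  expect_equal(res$tB, reg$slope * res$tA + reg$intercept, tolerance = 1e-12)

  # perfectly anti-correlated pair: the joint-below coupling makes every
  # candidate set degenerate (membership collapses to single pixels), so
  # the scan runs dry without a defined correlation
  x <- seq(0.1, 0.9, length.out = 64)
  res2 <- costes_threshold_canonical(img2(x), img2(1 - x))
  expect_false(res2$converged)
  expect_equal(res2$evaluations, 0L)

  # perfectly correlated pair: never drops to zero
  res3 <- costes_threshold_canonical(img2(x), img2(x))
  expect_false(res3$converged)
  expect_equal(res3$tA, 0)
})

test_that("accurate mode equals the canonical scan on its grid", {
  for (s in 302:305) {
    pr <- coloc_pair(0.4, 8L, s, shape = c(32L, 32L))
    reg <- costes_regression(pr$a, pr$b)
    acc <- costes_threshold_accurate(pr$a, pr$b, reg = reg)
    can <- costes_threshold_canonical(pr$a, pr$b, reg = reg)  # 1/255 grid
    expect_equal(acc$tA, can$tA)
    expect_lte(acc$evaluations, can$evaluations)
  }
  # an image pair using 10 distinct grey values (linearly coupled, so the
  # below-set changes only at those values) caps the evaluation count
  set.seed(41)
  av <- sample(seq(0, 1, length.out = 10), 256, replace = TRUE)
  bv <- 0.9 * av + 0.05
  res <- costes_threshold_accurate(img2(av), img2(bv))
  expect_lte(res$evaluations, 10L)
})

test_that("fast and faster agree with accurate on monotone profiles", {
  agree <- 0L; total <- 0L
  for (s in 311:318) {
    rho <- c(0, 0.3, 0.6, 0.9)[1 + (s %% 4)]
    bits <- if (s %% 2 == 0) 8L else 16L
    pr <- coloc_pair(rho, bits, s)
    reg <- costes_regression(pr$a, pr$b)
    acc <- costes_threshold_accurate(pr$a, pr$b, reg = reg)
    fst <- costes_threshold_fast(pr$a, pr$b, reg = reg)
    fsr <- costes_threshold_faster(pr$a, pr$b, reg = reg)
    if (profile_monotone(pr$a, pr$b, reg)) {
      expect_equal(fst$tA, acc$tA)
      expect_equal(fsr$tA, acc$tA)
    }
    total <- total + 1L
    if (fst$tA == acc$tA && fsr$tA == acc$tA) agree <- agree + 1L
    # work ordering and the bisection shrink bound
    expect_lte(fst$evaluations, acc$evaluations)
    G <- pr$a$grey_levels
    expect_lte(fsr$cycles, ceiling(log(G) / log(6 / 5)) + 6)
  }
  expect_gte(agree / total, 0.5)  # agreement beyond the monotone subset

  # perfectly anti-correlated pair: every mode runs dry identically
  x <- seq(0.1, 0.9, length.out = 64)
  for (f in list(costes_threshold_fast, costes_threshold_faster)) {
    r <- f(img2(x), img2(1 - x))
    expect_false(r$converged)
    expect_equal(r$tA, 0)
    expect_equal(r$evaluations, 0L)
  }
})

test_that("fast mode saves evaluations on strongly correlated pairs", {
  pr <- coloc_pair(0.9, 8L, 321)
  reg <- costes_regression(pr$a, pr$b)
  acc <- costes_threshold_accurate(pr$a, pr$b, reg = reg)
  fst <- costes_threshold_fast(pr$a, pr$b, reg = reg)
  expect_lt(fst$evaluations, acc$evaluations)
})

test_that("colocalization statistics match hand arithmetic", {
  # 2x2 images, printed arithmetic:
  # a = (0.2, 0.8, 0.4, 0.6), b = (0.1, 0.9, 0.7, 0.3), thresholds (0.5, 0.5)
  a <- intensity_image(matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2))
  b <- intensity_image(matrix(c(0.1, 0.9, 0.7, 0.3), 2, 2))
  st <- coloc_stats(a, b, costes_mode = "off", thresholds = c(0.5, 0.5))
  # M1: sum a where b > 0.5 -> 0.8 + 0.4 = 1.2, over sum a = 2.0
  expect_equal(st$manders_m1, 1.2 / 2)
  # M2: sum b where a > 0.5 -> 0.9 + 0.3 = 1.2, over sum b = 2.0
  expect_equal(st$manders_m2, 1.2 / 2)
  expect_equal(st$pearson, stats::cor(c(0.2, 0.8, 0.4, 0.6),
                                      c(0.1, 0.9, 0.7, 0.3)))

  # thresholds at 0 on strictly positive channels -> both coefficients 1
  ap <- intensity_image(matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2))
  st2 <- coloc_stats(ap, ap, costes_mode = "off", thresholds = c(0, 0))
  expect_equal(st2$manders_m1, 1)
  expect_equal(st2$manders_m2, 1)

  # disjoint supports -> 0
  az <- intensity_image(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  bz <- intensity_image(matrix(c(0, 0, 0.5, 0.5), 2, 2))
  st3 <- coloc_stats(az, bz, costes_mode = "off", thresholds = c(0.1, 0.1))
  expect_equal(st3$manders_m1, 0)
  expect_equal(st3$manders_m2, 0)

  # Costes coefficients use the automated thresholds
  pr <- coloc_pair(0.6, 8L, 331, shape = c(32L, 32L))
  st4 <- coloc_stats(pr$a, pr$b, costes_mode = "accurate")
  cres <- costes_threshold_accurate(pr$a, pr$b)
  va <- as.vector(pr$a$values); vb <- as.vector(pr$b$values)
  expect_equal(st4$costes_c1, sum(va[vb > cres$tB]) / sum(va))
  expect_equal(st4$costes_c2, sum(vb[va > cres$tA]) / sum(vb))
})
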