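#' Pearson correlation between two channels
#'
#' Standard product-moment correlation over all pixels, or over a pixel mask.
#' When the masked set has fewer than 2 pixels, or a channel is constant
#' within it, the correlation is undefined and `NA` is returned (a distinct
#' "undefined" state, never coerced to a number by the threshold searches).
#'
#' @param a,b [intensity_image()]s of identical shape.
#' @param mask Optional logical array selecting the pixels to correlate.
#' @return Scalar correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(a, b, mask = NULL) {
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (length(va) != length(vb))
    stop_mq("channels must have identical shape", "mq_dim_error")
  if (!is.null(mask)) {
    m <- as.vector(mask)
    va <- va[m]; vb <- vb[m]
  }
  if (length(va) < 2L) return(NA_real_)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Orthogonal regression between two channels
#'
#' Total least squares (orthogonal) regression of channel B on channel A
#' over all pixels: the major principal axis of the joint distribution,
#' which is the regression the Costes threshold coupling is defined on.
#' Ordinary least squares is available as an option.
#'
#' @param a,b [intensity_image()]s of identical shape.
#' @param type `"orthogonal"` (default) or `"ols"`.
#' @return List with `slope` and `intercept` (`tB = slope * tA + intercept`).
#' @export
costes_regression <- function(a, b, type = c("orthogonal", "ols")) {
  type <- match.arg(type)
  x <- as.vector(a$values); y <- as.vector(b$values)
  if (length(x) != length(y))
    stop_mq("channels must have identical shape", "mq_dim_error")
  sxx <- stats::var(x); syy <- stats::var(y)
  if (sxx == 0)
    stop_mq("channel A is constant: regression undefined", "mq_degenerate_error")
  if (type == "ols") {
    slope <- stats::cov(x, y) / sxx
  } else {
    sxy <- stats::cov(x, y)
    if (sxy == 0) {
      if (syy > sxx)
        stop_mq("no defined orientation for orthogonal regression",
                "mq_degenerate_error")
      slope <- 0
    } else {
      slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    }
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Correlation of the below-threshold pixel set
#'
#' Pearson correlation over the pixels jointly below the coupled thresholds,
#' `{a <= tA and b <= slope * tA + intercept}`. This is the quantity the
#' Costes search drives to zero. Returns `NA` (undefined) when the set has
#' fewer than 2 pixels or a constant channel.
#'
#' @param a,b [intensity_image()]s.
#' @param tA Channel-A threshold.
#' @param slope,intercept Regression coefficients from [costes_regression()].
#' @return Scalar correlation or `NA`.
#' @export
below_threshold_corr <- function(a, b, tA, slope, intercept) {
  tB <- slope * tA + intercept
  mask <- a$values <= tA & b$values <= tB
  pearson_r(a, b, mask)
}

# ---------------------------------------------------------------------------
# Shared scan engine.
#
# Candidate thresholds live on the grey-level grid of channel A:
# t_k = k / (G - 1), k = 0 .. G-1. Membership of pixel i in the
# below-threshold set at t is a <= t AND b <= slope*t + intercept, i.e.
#   slope > 0:  t >= m_i,  m_i = max(a_i, (b_i - c)/slope)    (nested sets)
#   slope == 0: t >= a_i restricted to pixels with b_i <= c   (nested sets)
#   slope < 0:  a_i <= t <= u_i, u_i = (b_i - c)/slope        (interval sets)
# Sorting by entry (and exit) points gives prefix sums from which the count
# and the Pearson correlation of the set at any t follow in O(1).
# ---------------------------------------------------------------------------

cs_engine <- function(a, b, reg) {
  G <- a$grey_levels
  va <- as.vector(a$values); vb <- as.vector(b$values)
  s <- reg$slope; c0 <- reg$intercept
  env <- new.env(parent = emptyenv())
  env$G <- G
  env$kmax <- as.integer(round(max(va) * (G - 1)))
  env$kmin <- as.integer(round(min(va) * (G - 1)))
  env$evals <- 0L
  env$memo <- new.env(parent = emptyenv())
  if (s >= 0) {
    keep <- if (s == 0) vb <= c0 else rep(TRUE, length(va))
    m <- if (s == 0) va[keep] else pmax(va, (vb - c0) / s)
    o <- order(m)
    env$mode <- "nested"
    env$m_sorted <- m[o]
    xs <- va[keep][o]; ys <- vb[keep][o]
    env$Sx <- cumsum(xs); env$Sy <- cumsum(ys)
    env$Sxx <- cumsum(xs * xs); env$Syy <- cumsum(ys * ys)
    env$Sxy <- cumsum(xs * ys)
  } else {
    u <- (vb - c0) / s
    valid <- va <= u
    av <- va[valid]; uv <- u[valid]; bv <- vb[valid]
    oa <- order(av); ou <- order(uv)
    env$mode <- "interval"
    env$a_sorted <- av[oa]
    env$u_sorted <- uv[ou]
    env$A <- list(Sx = cumsum(av[oa]), Sy = cumsum(bv[oa]),
                  Sxx = cumsum(av[oa]^2), Syy = cumsum(bv[oa]^2),
                  Sxy = cumsum(av[oa] * bv[oa]))
    env$U <- list(Sx = cumsum(av[ou]), Sy = cumsum(bv[ou]),
                  Sxx = cumsum(av[ou]^2), Syy = cumsum(bv[ou]^2),
                  Sxy = cumsum(av[ou] * bv[ou]))
  }
  env
}

# Vectorized set sizes for a vector of candidate grid positions.
cs_counts_vec <- function(env, ks) {
  ts <- ks / (env$G - 1)
  if (env$mode == "nested") {
    findInterval(ts + 1e-12, env$m_sorted)
  } else {
    findInterval(ts + 1e-12, env$a_sorted) -
      findInterval(ts - 1e-12, env$u_sorted)
  }
}

cs_count <- function(env, k) cs_counts_vec(env, k)

# In nested mode the set (hence the correlation) is a function of its size,
# so all prefix correlations can be precomputed in one vectorized pass.
cs_prepare_nested <- function(env) {
  if (!is.null(env$rn)) return(invisible())
  N <- length(env$m_sorted)
  if (N == 0L) { env$rn <- numeric(0); env$seen <- logical(0); return(invisible()) }
  n <- seq_len(N)
  vx <- pmax(n * env$Sxx - env$Sx^2, 0)
  vy <- pmax(n * env$Syy - env$Sy^2, 0)
  bad <- n < 2L | vx <= 1e-18 | vy <= 1e-18
  r <- rep(NA_real_, N)
  r[!bad] <- (n[!bad] * env$Sxy[!bad] - env$Sx[!bad] * env$Sy[!bad]) /
    sqrt(vx[!bad] * vy[!bad])
  env$rn <- r
  env$seen <- logical(N)
  invisible()
}

# Correlation of the set at candidate k. Each *distinct* set whose
# correlation is computed counts as one Pearson evaluation; revisiting the
# same set is free (accurate/fast/faster all skip unchanged sets).
cs_corr <- function(env, k) {
  if (env$mode == "nested") {
    cs_prepare_nested(env)
    n <- cs_count(env, k)
    if (n < 1L) return(NA_real_)
    r <- env$rn[n]
    if (!is.na(r) && !env$seen[n]) {
      env$evals <- env$evals + 1L
      env$seen[n] <- TRUE
    }
    return(r)
  }
  t <- k / (env$G - 1)
  na <- findInterval(t + 1e-12, env$a_sorted)
  nu <- findInterval(t - 1e-12, env$u_sorted)
  ckey <- paste0("i", na, "_", nu)
  chit <- get0(ckey, envir = env$memo, inherits = FALSE)
  if (!is.null(chit)) return(chit[[1L]])
  n <- na - nu
  if (n < 2L) r <- NA_real_ else {
    gA <- function(f) if (na > 0) env$A[[f]][na] else 0
    gU <- function(f) if (nu > 0) env$U[[f]][nu] else 0
    Sx <- gA("Sx") - gU("Sx"); Sy <- gA("Sy") - gU("Sy")
    Sxx <- gA("Sxx") - gU("Sxx"); Syy <- gA("Syy") - gU("Syy")
    Sxy <- gA("Sxy") - gU("Sxy")
    vx <- n * Sxx - Sx^2; vy <- n * Syy - Sy^2
    r <- if (vx <= 1e-18 || vy <= 1e-18) NA_real_ else
      (n * Sxy - Sx * Sy) / sqrt(vx * vy)
  }
  if (!is.na(r)) env$evals <- env$evals + 1L
  assign(ckey, list(r), envir = env$memo)
  r
}

cs_result <- function(env, reg, mode, k, converged, cycles = NA_integer_) {
  tA <- k / (env$G - 1)
  structure(list(tA = tA, tB = reg$slope * tA + reg$intercept,
                 slope = reg$slope, intercept = reg$intercept,
                 mode = mode, evaluations = env$evals,
                 converged = converged, cycles = cycles),
            class = "mq_costes")
}

#' @export
print.mq_costes <- function(x, ...) {
  cat("<costes threshold> mode ", x$mode, ": tA = ",
      format(x$tA, digits = 6), ", tB = ", format(x$tB, digits = 6),
      ", evaluations = ", x$evaluations,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Costes automated threshold, canonical fixed-step scan
#'
#' Scans the channel-A threshold downward from `max(a)` in fixed steps,
#' returning the first candidate at which the correlation of the
#' below-threshold pixel set drops to zero or below. Undefined correlations
#' (tiny or constant sets) are skipped and the scan continues. If no
#' candidate qualifies the minimum candidate is returned with
#' `converged = FALSE`.
#'
#' @param a,b [intensity_image()]s of identical shape.
#' @param step Scan step on the 0-1 intensity scale; default `1/255`, the
#'   historical 8-bit step. `1/step` must be a whole number.
#' @param reg Optional precomputed [costes_regression()].
#' @return An object of class `mq_costes`: `tA`, `tB`, `slope`, `intercept`,
#'   `mode`, `evaluations` (Pearson computations on valid sets),
#'   `converged`.
#' @export
costes_threshold_canonical <- function(a, b, step = 1 / 255, reg = NULL) {
  if (is.null(reg)) reg <- costes_regression(a, b)
  nsteps <- round(1 / step)
  if (abs(nsteps * step - 1) > 1e-9)
    stop_mq("1/step must be a whole number", "mq_value_error")
  env <- cs_engine(a, b, reg)
  G <- env$G
  # candidates (kmax - j * G/nsteps) expressed on the grey grid; when the
  # step grid is coarser than the grey grid, thresholds fall between grey
  # levels -- represent candidates as exact threshold values instead
  k0 <- round(max(a$values) * nsteps)
  js <- 0:k0
  tcand <- (k0 - js) / nsteps
  kcand <- tcand * (G - 1)   # fractional grid positions are fine
  ev <- 0L
  for (k in kcand) {
    r <- cs_corr(env, k)
    if (!is.na(r)) ev <- ev + 1L   # canonical re-evaluates every candidate
    if (!is.na(r) && r <= 0) {
      env$evals <- ev
      return(cs_result(env, reg, "canonical", k, TRUE))
    }
  }
  env$evals <- ev
  cs_result(env, reg, "canonical", kcand[length(kcand)], FALSE)
}

#' Costes automated threshold, accurate mode
#'
#' Evaluates every representable grey level of channel A from the maximum
#' downward, but recomputes the Pearson correlation only when the candidate
#' changes the size of the below-threshold pixel set; skipped candidates
#' share their set (and hence their correlation) with the previous one, so
#' the returned threshold is identical to the exhaustive scan.
#'
#' @inheritParams costes_threshold_canonical
#' @return An `mq_costes` result.
#' @export
costes_threshold_accurate <- function(a, b, reg = NULL) {
  if (is.null(reg)) reg <- costes_regression(a, b)
  env <- cs_engine(a, b, reg)
  ks <- env$kmax:0L
  cnts <- cs_counts_vec(env, ks)
  change <- which(c(TRUE, diff(cnts) != 0))  # first candidate of each set
  for (i in change) {
    r <- cs_corr(env, ks[i])
    if (!is.na(r) && r <= 0)
      return(cs_result(env, reg, "accurate", ks[i], TRUE))
  }
  cs_result(env, reg, "accurate", 0L, FALSE)
}

#' Costes automated threshold, fast mode
#'
#' Downward scan whose step grows with the last observed correlation
#' (`max(1, floor(r / 0.35) + 1)` grey levels, i.e. unit steps once the
#' correlation is below 0.35). On the first candidate with correlation at or
#' below zero the scan backtracks to the previously evaluated candidate and
#' rescans that interval at unit steps, so on profiles monotone in the
#' threshold the result equals accurate mode. The pixel-count change gate of
#' accurate mode applies throughout.
#'
#' @inheritParams costes_threshold_canonical
#' @return An `mq_costes` result.
#' @export
costes_threshold_fast <- function(a, b, reg = NULL) {
  if (is.null(reg)) reg <- costes_regression(a, b)
  env <- cs_engine(a, b, reg)
  prev_cnt <- -1L
  last_r <- NA_real_
  prev_k <- NA_integer_
  k <- env$kmax
  while (k >= 0L) {
    cnt <- cs_count(env, k)
    if (cnt != prev_cnt) {
      prev_cnt <- cnt
      r <- cs_corr(env, k)
      if (!is.na(r)) {
        if (r <= 0) {
          # backtrack: unit rescan of the skipped interval
          top <- if (is.na(prev_k)) k else prev_k - 1L
          pc <- -1L
          for (kk in top:k) {
            cc <- cs_count(env, kk)
            if (cc == pc) next
            pc <- cc
            rr <- cs_corr(env, kk)
            if (!is.na(rr) && rr <= 0)
              return(cs_result(env, reg, "fast", kk, TRUE))
          }
          return(cs_result(env, reg, "fast", k, TRUE))
        }
        last_r <- r
        prev_k <- k
      }
    }
    stepk <- if (is.na(last_r)) 1L else max(1L, as.integer(floor(last_r / 0.35)) + 1L)
    k <- if (k > 0L && k - stepk < 0L) 0L else k - stepk
  }
  cs_result(env, reg, "fast", 0L, FALSE)
}

#' Costes automated threshold, faster mode (weighted bisection)
#'
#' Maintains a window of candidate grey levels, initialized to
#' `[min(a), max(a)]`. After a short warm-start (the top candidate plus up
#' to three count-change candidates below it, which resolves thresholds
#' sitting at the very top of the scan at the same cost as a plain scan),
#' each cycle evaluates one candidate in the upper sixth of the window and
#' discards the portion excluded by the correlation sign: a positive
#' correlation discards the upper ~1/6, a non-positive (or undefined)
#' correlation discards the lower ~5/6. The window therefore shrinks by at
#' least 1/6 per cycle. When the window is down to a few grey levels it is
#' resolved by a unit-step scan, so on correlation profiles with a single
#' zero crossing the result equals accurate mode.
#'
#' @inheritParams costes_threshold_canonical
#' @return An `mq_costes` result; `cycles` counts bisection iterations.
#' @export
costes_threshold_faster <- function(a, b, reg = NULL) {
  if (is.null(reg)) reg <- costes_regression(a, b)
  env <- cs_engine(a, b, reg)
  cycles <- 0L
  r_top <- cs_corr(env, env$kmax)
  if (!is.na(r_top) && r_top <= 0)
    return(cs_result(env, reg, "faster", env$kmax, TRUE, cycles))
  # warm start: gated unit scan of the next few count-change candidates
  peeks <- 0L
  k <- env$kmax
  pc <- cs_count(env, env$kmax)
  while (peeks < 3L && k > 0L) {
    k <- k - 1L
    cc <- cs_count(env, k)
    if (cc == pc) next
    pc <- cc
    r <- cs_corr(env, k)
    if (!is.na(r) && r <= 0)
      return(cs_result(env, reg, "faster", k, TRUE, cycles))
    peeks <- peeks + 1L
  }
  lo <- env$kmin
  hi <- k - 1L
  while (hi - lo > 2L) {
    w <- hi - lo
    cand <- hi - max(1L, w %/% 6L)
    r <- cs_corr(env, cand)
    cycles <- cycles + 1L
    if (!is.na(r) && r > 0) {
      hi <- cand - 1L     # threshold is strictly below the candidate
    } else {
      lo <- cand          # candidate itself qualifies (or is undefined low)
    }
  }
  # terminal unit-step scan of the remaining window, top down
  if (hi >= lo) {
    pc <- -1L
    for (k in hi:lo) {
      cc <- cs_count(env, k)
      if (cc == pc) next
      pc <- cc
      r <- cs_corr(env, k)
      if (!is.na(r) && r <= 0)
        return(cs_result(env, reg, "faster", k, TRUE, cycles))
    }
  }
  # no qualifying candidate in (or above) the window: scan below lo to match
  # the exhaustive result, which continues to the bottom of the grid
  if (lo > 0L) {
    pc <- -1L
    for (k in (lo - 1L):0L) {
      cc <- cs_count(env, k)
      if (cc == pc) next
      pc <- cc
      r <- cs_corr(env, k)
      if (!is.na(r) && r <= 0)
        return(cs_result(env, reg, "faster", k, TRUE, cycles))
    }
  }
  cs_result(env, reg, "faster", 0L, FALSE, cycles)
}

#' Colocalization statistics for a channel pair
#'
#' Whole-set Pearson correlation, Manders M1/M2 with user-supplied or
#' per-channel Otsu thresholds, and Costes C1/C2: the Manders coefficients
#' computed with the Costes automated thresholds `(tA, tB)`.
#'
#' @param a,b [intensity_image()]s of identical shape.
#' @param costes_mode `"accurate"` (default), `"fast"`, `"faster"`,
#'   `"canonical"`, or `"off"` (skip the Costes coefficients).
#' @param thresholds Optional numeric `c(tA, tB)` for the Manders
#'   coefficients; per-channel Otsu when omitted.
#' @param mask Optional logical array restricting all statistics.
#' @return A one-row `data.frame`: `pearson`, `manders_m1`, `manders_m2`,
#'   `costes_c1`, `costes_c2`, `costes_ta`, `costes_tb`.
#' @export
coloc_stats <- function(a, b,
                        costes_mode = c("accurate", "fast", "faster",
                                        "canonical", "off"),
                        thresholds = NULL, mask = NULL) {
  costes_mode <- match.arg(costes_mode)
  va <- a$values; vb <- b$values
  if (!identical(dim(va), dim(vb)))
    stop_mq("channels must have identical shape", "mq_dim_error")
  if (!is.null(mask)) {
    sel <- as.vector(mask)
    va <- as.vector(va)[sel]; vb <- as.vector(vb)[sel]
  } else {
    va <- as.vector(va); vb <- as.vector(vb)
  }
  if (is.null(thresholds)) {
    ta <- otsu_threshold(intensity_image(matrix(va, length(va), 1),
                                         a$grey_levels))
    tb <- otsu_threshold(intensity_image(matrix(vb, length(vb), 1),
                                         b$grey_levels))
  } else {
    ta <- thresholds[1]; tb <- thresholds[2]
  }
  manders <- function(x, y, ty) if (sum(x) == 0) 0 else sum(x[y > ty]) / sum(x)
  pear <- if (length(va) >= 2L && stats::sd(va) > 0 && stats::sd(vb) > 0)
    stats::cor(va, vb) else NA_real_
  c1 <- NA_real_; c2 <- NA_real_; cta <- NA_real_; ctb <- NA_real_
  if (costes_mode != "off") {
    ai <- intensity_image(matrix(va, length(va), 1), a$grey_levels)
    bi <- intensity_image(matrix(vb, length(vb), 1), b$grey_levels)
    cres <- switch(costes_mode,
                   accurate = costes_threshold_accurate(ai, bi),
                   fast = costes_threshold_fast(ai, bi),
                   faster = costes_threshold_faster(ai, bi),
                   canonical = costes_threshold_canonical(ai, bi))
    cta <- cres$tA; ctb <- cres$tB
    c1 <- manders(va, vb, ctb)
    c2 <- manders(vb, va, cta)
  }
  data.frame(pearson = pear,
             manders_m1 = manders(va, vb, tb),
             manders_m2 = manders(vb, va, ta),
             costes_c1 = c1, costes_c2 = c2,
             costes_ta = cta, costes_tb = ctb)
}
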