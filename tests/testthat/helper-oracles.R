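# Independent oracles used by the unit and acceptance tests. These are
# deliberately slow implementations-by-definition, structurally unrelated
# to the package's algorithms.

# ---------------------------------------------------------------------------
# Exhaustive oracle for the penalized pinball objective. The objective is
# piecewise-linear and convex in the coefficients, so its minimum is
# attained at an intersection of p kink hyperplanes (zero residuals
# y_i = B_i beta and/or zero penalty differences D2_j beta = 0): enumerate
# every p-subset of those hyperplanes, solve each p x p system, and take
# the smallest objective. A nested dense grid search over coefficient
# space is run as well and the better of the two is returned; the grid
# alone can stall on the flat ridges of the pinball surface.
grid_search_objective <- function(B, y, tau, lambda, D2, rounds = 8,
                                  pts = 21) {
  p <- ncol(B)
  A <- rbind(B, D2)
  cc <- c(y, rep(0, nrow(D2)))
  obj_at <- function(beta) {
    r <- y - drop(B %*% beta)
    v <- sum(r * (tau - (r < 0)))
    if (nrow(D2)) v <- v + lambda * sum(abs(drop(D2 %*% beta)))
    v
  }
  best_obj <- Inf
  combos <- utils::combn(nrow(A), p)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    M <- A[idx, , drop = FALSE]
    beta <- tryCatch(solve(M, cc[idx]), error = function(e) NULL)
    if (is.null(beta)) next
    v <- obj_at(beta)
    if (v < best_obj) best_obj <- v
  }
  # nested grid refinement as an independent cross-check
  lo <- rep(min(y) - 1, p)
  hi <- rep(max(y) + 1, p)
  best <- NULL
  for (r in seq_len(rounds)) {
    axes <- lapply(seq_len(p), function(k) seq(lo[k], hi[k], length.out = pts))
    G <- as.matrix(do.call(expand.grid, axes))
    R <- matrix(y, nrow(G), length(y), byrow = TRUE) - tcrossprod(G, B)
    vals <- rowSums(R * (tau - (R < 0)))
    if (nrow(D2)) vals <- vals + lambda * rowSums(abs(tcrossprod(G, D2)))
    i <- which.min(vals)
    best <- G[i, ]
    best_obj <- min(best_obj, vals[i])
    step <- (hi - lo) / (pts - 1)
    lo <- best - 3 * step
    hi <- best + 3 * step
  }
  best_obj
}

# ---------------------------------------------------------------------------
# Brute-force dip statistic by definition: dip = min over unimodal CDFs G
# (convex below the mode, concave above, atom allowed at the mode) of
# sup |F_n - G|, found by bisection on the distance d. Feasibility of
# "some unimodal G stays within d of the ECDF" is checked exactly for
# every mode placement with a piecewise-linear frontier s_min(value) =
# minimal arriving slope of a convex monotone function threading the band
# [i/n - d, (i-1)/n + d]; the concave side is the mirror image (reflect
# time and probability). Ties are collapsed into unique locations whose
# left-limit and point-value constraints differ, which is where a mode
# atom may sit.

.front_new <- function(lo, hi) {
  if (lo > hi + 1e-15) return(NULL)
  list(v = c(lo, hi), s = c(0, 0))
}

.front_eval <- function(f, v) {
  nb <- length(f$v)
  if (v <= f$v[1]) return(f$s[1])
  if (v >= f$v[nb]) {
    if (!is.null(f$ext_delta) && v > f$v[nb])
      return((v - f$ext_v) / f$ext_delta)
    return(f$s[nb])
  }
  stats::approx(f$v, f$s, xout = v, ties = min)$y
}

.front_clip <- function(f, lo, hi) {
  nb <- length(f$v)
  vmax_nat <- if (!is.null(f$ext_delta)) Inf else f$v[nb]
  a <- max(lo, f$v[1])
  b <- min(hi, vmax_nat)
  if (a > b + 1e-15) return(NULL)
  keep <- f$v > a & f$v < b
  vv <- c(a, f$v[keep], b)
  ss <- vapply(vv, function(v) .front_eval(f, v), numeric(1))
  list(v = vv, s = ss)
}

.front_step <- function(f, delta, lo, hi) {
  if (is.null(f)) return(NULL)
  if (delta <= 0) return(.front_clip(f, lo, hi))
  f2 <- list(v = f$v + delta * f$s, s = f$s,
             ext_v = f$v[length(f$v)], ext_delta = delta)
  .front_clip(f2, lo, hi)
}

dip_oracle <- function(x, tol = 1e-12) {
  x <- sort(x)
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  u <- unique(x)
  m <- length(u)
  hi_i <- cumsum(tabulate(match(x, u), m))
  lo_i <- c(1, utils::head(hi_i, -1) + 1)

  feasible <- function(d) {
    pb_lo <- pmax(hi_i / n - d, 0)
    pb_hi <- pmin((lo_i - 1) / n + d, 1)
    L <- vector("list", m)
    f <- .front_new(pb_lo[1], pb_hi[1])
    L[1] <- list(f)
    if (m > 1) for (i in 1:(m - 1)) {
      f <- .front_step(f, u[i + 1] - u[i], pb_lo[i + 1], pb_hi[i + 1])
      L[i + 1] <- list(f)
      if (is.null(f)) break
    }
    R <- vector("list", m)
    f <- .front_new(1 - pb_hi[m], 1 - pb_lo[m])
    R[m] <- list(f)
    if (m > 1) for (i in (m - 1):1) {
      f <- .front_step(f, u[i + 1] - u[i], 1 - pb_hi[i], 1 - pb_lo[i])
      R[i] <- list(f)
      if (is.null(f)) break
    }
    # mode with possible atom at location i
    for (i in seq_len(m)) {
      llo <- max((lo_i[i] - 1) / n - d, 0)
      lhi <- min((lo_i[i] - 1) / n + d, 1)
      rlo <- max(hi_i[i] / n - d, 0)
      rhi <- min(hi_i[i] / n + d, 1)
      fl <- if (i == 1) .front_new(llo, lhi) else {
        if (is.null(L[[i - 1]])) NULL else
          .front_step(L[[i - 1]], u[i] - u[i - 1], llo, lhi)
      }
      if (is.null(fl)) next
      fr <- if (i == m) .front_new(1 - rhi, 1 - rlo) else {
        if (is.null(R[[i + 1]])) NULL else
          .front_step(R[[i + 1]], u[i + 1] - u[i], 1 - rhi, 1 - rlo)
      }
      if (is.null(fr)) next
      if (fl$v[1] <= (1 - fr$v[1]) + 1e-15) return(TRUE)
    }
    # mode strictly inside a gap: one of the junction slopes binds
    if (m > 1) for (i in 1:(m - 1)) {
      fl <- L[[i]]
      fr <- R[[i + 1]]
      if (is.null(fl) || is.null(fr)) next
      delta <- u[i + 1] - u[i]
      if ((1 - fr$v[1]) >= min(fl$v + fl$s * delta) - 1e-15) return(TRUE)
      if (max((1 - fr$v) - fr$s * delta) >= fl$v[1] - 1e-15) return(TRUE)
    }
    FALSE
  }

  lo <- 1 / (2 * n)
  hi <- 0.25
  if (feasible(lo)) return(lo)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# ---------------------------------------------------------------------------
# small helpers for building traces in tests
make_flat_trace <- function(n = 200, tb = 37, interval_min = 30) {
  tb_trace((seq_len(n) - 1) * interval_min / 60, rep(tb, n))
}

make_noisy_sine_trace <- function(n = 5000, seed = 1, mesor = 36.4,
                                  amp = 1, noise = 0.3) {
  set.seed(seed)
  t_h <- (seq_len(n) - 1) * 0.2
  tb_trace(t_h, mesor + amp * sin(2 * pi * t_h / 24) + rnorm(n, 0, noise))
}
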