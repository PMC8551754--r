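#' Pinball (check) loss
#'
#' The quantile-regression loss `rho_tau(u) = u * (tau - 1[u < 0])`. Its
#' minimizer over constants is the `tau`-th sample quantile.
#'
#' @param residual Numeric vector of residuals, degrees C.
#' @param tau Quantile level, strictly inside (0, 1).
#' @return Nonnegative loss values; zero iff the residual is zero.
#' @export
pinball_loss <- function(residual, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1) {
    stop_tbwave("`tau` must lie strictly inside (0, 1)",
                class = "tbwave_validation_error")
  }
  residual * (tau - (residual < 0))
}

# Primal-dual interior point solver (Mehrotra predictor-corrector) for
#   min_beta sum_i rho_{tau_i}(y_i - x_i' beta)
# via the bounded-variable LP dual: max y'a s.t. X'a = X'(1 - tau),
# 0 <= a <= 1. Per-row tau lets the L1 roughness penalty ride along as
# pseudo-observations with tau = 1/2 and rows scaled by 2 * lambda.
ipm_pinball <- function(X, y, tau, tol = 1e-11, maxit = 200) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(tau) == 1L) tau <- rep(tau, n)
  f <- -y
  b <- drop(crossprod(X, 1 - tau))

  x <- 1 - tau            # primal-feasible interior start: X'x = b exactly
  s <- 1 - x
  lam <- tryCatch(
    drop(solve(crossprod(X) + diag(1e-10, p), crossprod(X, f))),
    error = function(e) rep(0, p))
  r <- f - drop(X %*% lam)
  dl <- max(1, mean(abs(r)))
  z <- pmax(r, 0) + dl
  w <- pmax(-r, 0) + dl

  scale_y <- max(1, max(abs(y)))
  best_lam <- -lam
  for (it in seq_len(maxit)) {
    rp <- b - drop(crossprod(X, x))
    rd <- f - drop(X %*% lam) - z + w
    ru <- 1 - x - s
    gap <- sum(x * z) + sum(s * w)
    mu <- gap / (2 * n)
    best_lam <- -lam
    if (!is.finite(mu)) break
    if (mu < tol * scale_y &&
        max(abs(rp)) < tol * (1 + max(abs(b))) &&
        max(abs(rd)) < tol * scale_y * 10) break

    dinv <- z / x + w / s
    D <- 1 / dinv
    XD <- X * D
    M <- crossprod(X, XD)
    # Solve M dlam = rhs through the QR factorization of sqrt(D) X
    # (condition number kappa instead of kappa^2): essential when penalty
    # rows are scaled by a huge lambda. One refinement step on top.
    qa <- qr(X * sqrt(D), LAPACK = TRUE)
    Rf <- qr.R(qa)
    piv <- qa$pivot
    dr <- abs(diag(Rf))
    rtol <- max(dr) * 1e-14
    if (any(dr < rtol)) diag(Rf) <- sign(diag(Rf) + (diag(Rf) == 0)) *
        pmax(dr, rtol)
    trisolve <- function(rhs) {
      out <- numeric(p)
      out[piv] <- backsolve(Rf, forwardsolve(t(Rf), rhs[piv]))
      out
    }
    psolve <- function(rhs) {
      dl <- trisolve(rhs)
      dl + trisolve(rhs - drop(M %*% dl))
    }

    newton <- function(rxz, rsw) {
      rhs2 <- rd - rxz / x + (rsw - w * ru) / s
      rhs <- rp + drop(crossprod(XD, rhs2))
      dlam <- psolve(rhs)
      dx <- D * (drop(X %*% dlam) - rhs2)
      ds <- ru - dx
      dz <- (rxz - z * dx) / x
      dw <- (rsw - w * ds) / s
      list(dx = dx, ds = ds, dlam = dlam, dz = dz, dw = dw)
    }
    steplen <- function(v, dv) {
      neg <- is.finite(dv) & dv < 0
      if (!any(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
    }
    sane <- function(dir) all(vapply(dir, function(d)
      all(is.finite(d)), logical(1)))

    # affine (predictor) direction
    aff <- newton(-x * z, -s * w)
    if (!sane(aff)) break
    ap <- min(steplen(x, aff$dx), steplen(s, aff$ds))
    ad <- min(steplen(z, aff$dz), steplen(w, aff$dw))
    mu_aff <- (sum((x + ap * aff$dx) * (z + ad * aff$dz)) +
               sum((s + ap * aff$ds) * (w + ad * aff$dw))) / (2 * n)
    sigma <- min(1, max(0, mu_aff / mu))^3

    # corrector
    dir <- newton(sigma * mu - x * z - aff$dx * aff$dz,
                  sigma * mu - s * w - aff$ds * aff$dw)
    if (!sane(dir)) break
    ap <- 0.9995 * min(steplen(x, dir$dx), steplen(s, dir$ds))
    ad <- 0.9995 * min(steplen(z, dir$dz), steplen(w, dir$dw))
    ap <- min(1, ap); ad <- min(1, ad)

    x <- x + ap * dir$dx
    s <- s + ap * dir$ds
    lam <- lam + ad * dir$dlam
    z <- z + ad * dir$dz
    w <- w + ad * dir$dw
  }
  best_lam
}

# L1 roughness penalty on the spline coefficients: second divided
# differences on the Greville abscissae, scaled so the rows reduce to the
# plain second difference where knots are equally spaced. The null space
# is then exactly the linear-in-time functions (coefficients linear in the
# Greville points), so a large lambda shrinks the curve to the best
# straight-line quantile fit rather than to an index-space artifact.
roughness_matrix <- function(knots_full, degree) {
  p <- length(knots_full) - degree - 1L
  if (p < 3L) return(matrix(0, 0, p))
  g <- vapply(seq_len(p), function(j)
    mean(knots_full[(j + 1):(j + degree)]), numeric(1))
  d <- diff(g)
  M <- matrix(0, p - 2L, p)
  for (j in seq_len(p - 2L)) {
    c_j <- (d[j] + d[j + 1]) / 2
    M[j, j] <- c_j / d[j]
    M[j, j + 1] <- -c_j / d[j] - c_j / d[j + 1]
    M[j, j + 2] <- c_j / d[j + 1]
  }
  M
}

#' Fit a penalized quantile-regression smooth over time
#'
#' The non-stationary waveform fit: a cubic B-spline curve `f(t)` minimizing
#' the penalized pinball objective
#' `sum_i rho_tau(tb_i - f(t_i)) + lambda * sum_j |D2_j coef|`, where `D2`
#' takes second divided differences of the coefficients on the Greville
#' abscissae (plain second differences wherever knots are equally spaced).
#' Both terms are linear-programmable, and the fit is computed as an exact
#' LP by a primal-dual interior-point method, so the achieved objective
#' matches the LP optimum to high accuracy. As `lambda` grows the curve
#' shrinks to the best straight-line quantile fit.
#'
#' Interior knots are spaced `knot_spacing_h` apart (floor 48 h, at least
#' twice the daily period), which is what keeps the curve tracking slow
#' drift in the level of the cycle rather than the cycle itself; readings
#' above/below the fitted 45th/55th quantile curves would otherwise not
#' separate active from resting phases.
#'
#' @param trace A [tb_trace()] segment (see [segment_trace()]).
#' @param tau Quantile level in (0, 1); the phase split uses 0.45 and 0.55.
#' @param knot_spacing_h Interior knot spacing, hours; must be >= 48.
#' @param lambda Roughness penalty weight (>= 0) on the L1 norm of the
#'   (divided) second differences of the spline coefficients.
#' @param degree Spline degree (default cubic).
#' @param min_duration_h Minimum segment span required for fitting, hours.
#' @return An object of class `tb_quantile_curve` with fields `tau`,
#'   `knots_h` (interior knots), `degree`, `coefficients`, `lambda`,
#'   `objective` and `span`.
#' @export
fit_quantile_curve <- function(trace, tau, knot_spacing_h = 72, lambda = 1,
                               degree = 3, min_duration_h = 72) {
  validate_tb_trace(trace)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop_tbwave("`tau` must lie strictly inside (0, 1)",
                class = "tbwave_validation_error")
  }
  assert_scalar_num(lambda, "lambda", lower = 0)
  assert_scalar_num(knot_spacing_h, "knot_spacing_h", lower = 48)
  t_h <- trace$time_h
  span <- range(t_h)
  if (diff(span) < min_duration_h) {
    stop_tbwave(sprintf("segment spans %.1f h < required %.1f h",
                        diff(span), min_duration_h),
                class = "tbwave_fit_error")
  }
  # equally spaced interior knots with spacing >= knot_spacing_h: with
  # P-spline (second-difference) penalties, equal spacing makes the
  # penalty null space exactly the linear-in-time functions
  nseg <- max(1, floor(diff(span) / knot_spacing_h))
  interior <- if (nseg > 1) {
    span[1] + diff(span) * seq_len(nseg - 1) / nseg
  } else numeric()
  knots_full <- c(rep(span[1], degree + 1L), interior,
                  rep(span[2], degree + 1L))
  p <- length(interior) + degree + 1L
  if (length(t_h) < p) {
    stop_tbwave(sprintf("degenerate design: %d points for %d coefficients",
                        length(t_h), p),
                class = "tbwave_fit_error")
  }
  B <- splines::splineDesign(knots_full, t_h, ord = degree + 1L)
  D2 <- roughness_matrix(knots_full, degree)
  if (lambda > 0 && nrow(D2)) {
    Xa <- rbind(B, 2 * lambda * D2)
    ya <- c(trace$tb_c, rep(0, nrow(D2)))
    taua <- c(rep(tau, length(t_h)), rep(0.5, nrow(D2)))
  } else {
    Xa <- B; ya <- trace$tb_c; taua <- rep(tau, length(t_h))
  }
  beta <- ipm_pinball(Xa, ya, taua)
  objective_of <- function(bb) {
    sum(pinball_loss(trace$tb_c - drop(B %*% bb), tau)) +
      lambda * sum(abs(drop(D2 %*% bb)))
  }
  obj <- objective_of(beta)
  if (lambda > 0 && nrow(D2)) {
    # candidate restricted to the penalty null space (straight lines):
    # exact for penalty-dominated fits where the augmented LP is badly
    # scaled; keep whichever candidate achieves the lower objective
    g <- vapply(seq_len(p), function(j)
      mean(knots_full[(j + 1):(j + degree)]), numeric(1))
    N <- cbind(1, g)
    gam <- ipm_pinball(B %*% N, trace$tb_c, tau)
    beta0 <- drop(N %*% gam)
    if (objective_of(beta0) < obj) {
      beta <- beta0
      obj <- objective_of(beta0)
    }
  }
  structure(list(tau = tau, knots_h = interior, degree = degree,
                 coefficients = beta, lambda = lambda, objective = obj,
                 span = span, knots_full = knots_full,
                 n = length(t_h)),
            class = "tb_quantile_curve")
}

#' @export
print.tb_quantile_curve <- function(x, ...) {
  cat(sprintf(
    "<tb_quantile_curve> tau = %.2f, %d coefficients (degree %d), lambda = %g\n",
    x$tau, length(x$coefficients), x$degree, x$lambda))
  cat(sprintf("  span %.1f-%.1f h, objective %.6g\n",
              x$span[1], x$span[2], x$objective))
  invisible(x)
}

#' Evaluate a fitted quantile curve
#'
#' Spline evaluation at arbitrary times within the fitted span;
#' extrapolation is refused.
#'
#' @param curve A `tb_quantile_curve`.
#' @param times Decimal hours within the fitted span.
#' @return Numeric vector of curve values, degrees C.
#' @export
evaluate_curve <- function(curve, times) {
  if (!inherits(curve, "tb_quantile_curve")) {
    stop_tbwave("not a tb_quantile_curve", class = "tbwave_validation_error")
  }
  eps <- 1e-8
  if (any(times < curve$span[1] - eps | times > curve$span[2] + eps)) {
    stop_tbwave("evaluation time outside fitted span",
                class = "tbwave_range_error")
  }
  times <- pmin(pmax(times, curve$span[1]), curve$span[2])
  B <- splines::splineDesign(curve$knots_full, times, ord = curve$degree + 1L)
  drop(B %*% curve$coefficients)
}

#' @export
predict.tb_quantile_curve <- function(object, times, ...) {
  evaluate_curve(object, times)
}

#' Resolve quantile-curve crossing by pointwise rearrangement
#'
#' Two independently fitted quantile curves can cross. The partition rule
#' needs `q45 <= q55` everywhere, so the evaluated series are rearranged
#' pointwise to (min, max). Where the curves do not cross the output equals
#' the input.
#'
#' @param lower,upper Fitted `tb_quantile_curve` objects with
#'   `lower$tau < upper$tau` and identical spans.
#' @param times Evaluation grid, decimal hours within the common span.
#' @return List with elements `lower`, `upper` (numeric series) and
#'   `n_rearranged`, the number of grid points where the inputs crossed.
#' @export
rearrange_noncrossing <- function(lower, upper, times) {
  if (lower$tau >= upper$tau) {
    stop_tbwave("`lower` must have the smaller tau",
                class = "tbwave_validation_error")
  }
  if (max(abs(lower$span - upper$span)) > 1e-8) {
    stop_tbwave("curves were fitted on different spans",
                class = "tbwave_validation_error")
  }
  lo <- evaluate_curve(lower, times)
  up <- evaluate_curve(upper, times)
  list(lower = pmin(lo, up), upper = pmax(lo, up),
       n_rearranged = sum(lo > up))
}

#' Select the roughness penalty by blocked cross-validation
#'
#' Body temperature readings are strongly autocorrelated, so folds are
#' contiguous blocks of time rather than random subsets. For each candidate
#' `lambda` the curve is refitted with each block held out and scored by
#' held-out pinball loss; the minimizing `lambda` is returned.
#'
#' @param trace A [tb_trace()] segment.
#' @param tau Quantile level.
#' @param lambdas Candidate penalty weights.
#' @param k Number of contiguous folds.
#' @param ... Passed to [fit_quantile_curve()].
#' @return List with `lambda` (the selected value) and `cv_loss` (mean
#'   held-out pinball loss per candidate).
#' @export
cv_lambda <- function(trace, tau, lambdas = 10^seq(-1, 3, by = 1), k = 5,
                      ...) {
  n <- length(trace$time_h)
  fold <- cut(seq_len(n), breaks = k, labels = FALSE)
  losses <- vapply(lambdas, function(lam) {
    tot <- 0
    for (f in seq_len(k)) {
      tr <- trace
      keep <- fold != f
      tr$time_h <- trace$time_h[keep]
      tr$tb_c <- trace$tb_c[keep]
      tr$truth_labels <- NULL
      cur <- fit_quantile_curve(tr, tau, lambda = lam, ...)
      ho_t <- pmin(pmax(trace$time_h[!keep], cur$span[1]), cur$span[2])
      pred <- evaluate_curve(cur, ho_t)
      tot <- tot + sum(pinball_loss(trace$tb_c[!keep] - pred, tau))
    }
    tot / n
  }, numeric(1))
  list(lambda = lambdas[which.min(losses)],
       cv_loss = stats::setNames(losses, lambdas))
}
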