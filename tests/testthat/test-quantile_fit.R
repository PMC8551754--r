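test_that("pinball loss matches the check-loss formula", {
  expect_equal(pinball_loss(1, 0.55), 0.55)
  expect_equal(pinball_loss(-1, 0.55), 0.45)
  for (tau in c(0.1, 0.45, 0.9)) expect_equal(pinball_loss(0, tau), 0)
  expect_true(all(pinball_loss(rnorm(50), 0.45) >= 0))
  expect_error(pinball_loss(1, 0), class = "tbwave_validation_error")
  expect_error(pinball_loss(1, 1), class = "tbwave_validation_error")
})

test_that("constant trace fits flat with zero objective", {
  tr <- make_flat_trace(n = 400, tb = 37)
  for (tau in c(0.45, 0.55)) {
    cur <- fit_quantile_curve(tr, tau, min_duration_h = 0)
    expect_lt(cur$objective, 1e-6)
    expect_equal(evaluate_curve(cur, c(0, 33.3, 99.5)), rep(37, 3),
                 tolerance = 1e-6)
  }
})

test_that("lambda -> inf limit: values 36 x4 / 38 x6 at tau 0.55 give 38", {
  # scalar oracle: the minimizer of sum rho_0.55(y - c) over constants
  y <- c(rep(36, 4), rep(38, 6))
  cgrid <- seq(35, 39, by = 0.001)
  loss <- vapply(cgrid, function(c) sum(pinball_loss(y - c, 0.55)),
                 numeric(1))
  expect_equal(cgrid[which.min(loss)], 38)

  # readings clustered at (essentially) one design location, so the
  # penalty-dominated fit collapses to the scalar minimizer above
  tr <- tb_trace(seq(0, 0.1, length.out = 10), y)
  cur <- fit_quantile_curve(tr, 0.55, lambda = 1e6, degree = 1,
                            min_duration_h = 0)
  expect_equal(evaluate_curve(cur, c(0, 0.05, 0.1)), rep(38, 3),
               tolerance = 0.05)
})

test_that("lambda -> inf tends to the flat empirical tau-quantile", {
  # the exact lambda -> inf limit is the best straight-line quantile fit;
  # a fixture with whole cycles and positive density at the quantile makes
  # that line flat to well within the tolerance (see methods vignette)
  set.seed(4)
  t_h <- (0:4799) * 0.2  # 960 h = 40 whole cycles
  tr <- tb_trace(t_h, 36.4 + 0.5 * sin(2 * pi * t_h / 24) +
                   rnorm(4800, 0, 0.2))
  for (tau in c(0.45, 0.55)) {
    cur <- fit_quantile_curve(tr, tau, lambda = 1e6, min_duration_h = 0)
    v <- evaluate_curve(cur, tr$time_h)
    expect_lt(max(abs(v - empirical_quantile(tr$tb_c, tau))), 0.05)
  }
})

test_that("objective matches dense grid search on tiny instances", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    t_h <- sort(runif(n, 0, 10))
    y <- 37 + rnorm(n)
    tr <- tb_trace(t_h, y)
    tau <- sample(c(0.3, 0.45, 0.55, 0.7), 1)
    lam <- sample(c(0, 0.5, 2), 1)
    deg <- sample(1:2, 1)
    cur <- fit_quantile_curve(tr, tau, lambda = lam, degree = deg,
                              min_duration_h = 0)
    B <- splines::splineDesign(cur$knots_full, t_h, ord = deg + 1)
    D2 <- tbwave:::roughness_matrix(cur$knots_full, deg)
    oracle <- grid_search_objective(B, y, tau, lam, D2)
    expect_lt(cur$objective, oracle + 1e-3)
    expect_gt(cur$objective, oracle - 1e-3)
  }
})

test_that("coverage: fraction below the tau-curve approximates tau", {
  tr <- make_noisy_sine_trace(n = 5000, seed = 9)
  for (tau in c(0.45, 0.55)) {
    cur <- fit_quantile_curve(tr, tau)
    frac <- mean(tr$tb_c < evaluate_curve(cur, tr$time_h))
    expect_gt(frac, tau - 0.03)
    expect_lt(frac, tau + 0.03)
  }
})

test_that("recomputing the objective from the stored fields agrees to 1e-8", {
  tr <- make_noisy_sine_trace(n = 1500, seed = 12)
  cur <- fit_quantile_curve(tr, 0.55, lambda = 2)
  B <- splines::splineDesign(cur$knots_full, tr$time_h, ord = cur$degree + 1)
  D2 <- tbwave:::roughness_matrix(cur$knots_full, cur$degree)
  obj <- sum(pinball_loss(tr$tb_c - drop(B %*% cur$coefficients), 0.55)) +
    cur$lambda * sum(abs(drop(D2 %*% cur$coefficients)))
  expect_equal(cur$objective, obj, tolerance = 1e-8)
})

test_that("fit preconditions are enforced", {
  short <- make_flat_trace(n = 10, tb = 37)  # spans 4.5 h
  expect_error(fit_quantile_curve(short, 0.5),
               class = "tbwave_fit_error")
  expect_error(fit_quantile_curve(short, 1.5, min_duration_h = 0),
               class = "tbwave_validation_error")
  expect_error(fit_quantile_curve(short, 0.5, knot_spacing_h = 24,
                                  min_duration_h = 0),
               class = "tbwave_validation_error")
  tiny <- tb_trace(c(0, 1, 2), c(36, 37, 36))
  expect_error(fit_quantile_curve(tiny, 0.5, min_duration_h = 0),
               class = "tbwave_fit_error")  # fewer points than coefficients
})

test_that("evaluate_curve refuses extrapolation and is continuous at knots", {
  tr <- make_noisy_sine_trace(n = 2000, seed = 3)
  cur <- fit_quantile_curve(tr, 0.55)
  expect_error(evaluate_curve(cur, max(tr$time_h) + 5),
               class = "tbwave_range_error")
  expect_error(evaluate_curve(cur, -1), class = "tbwave_range_error")
  for (k in cur$knots_h) {
    eps <- 1e-7
    v <- evaluate_curve(cur, c(k - eps, k, k + eps))
    expect_lt(max(abs(diff(v))), 1e-4)
  }
})

test_that("rearrangement enforces non-crossing and is identity otherwise", {
  tr <- make_noisy_sine_trace(n = 2000, seed = 5)
  lo <- fit_quantile_curve(tr, 0.45)
  up <- fit_quantile_curve(tr, 0.55)
  rc <- rearrange_noncrossing(lo, up, tr$time_h)
  expect_true(all(rc$lower <= rc$upper))
  vlo <- evaluate_curve(lo, tr$time_h)
  vup <- evaluate_curve(up, tr$time_h)
  ok <- vlo <= vup
  expect_equal(rc$lower[ok], vlo[ok])
  expect_equal(rc$upper[ok], vup[ok])
  expect_equal(rc$n_rearranged, sum(!ok))

  # identical curves are returned unchanged
  rc2 <- rearrange_noncrossing(lo, lo2 <- fit_quantile_curve(tr, 0.55),
                               tr$time_h)
  expect_true(all(rc2$lower <= rc2$upper))
  expect_error(rearrange_noncrossing(up, lo, tr$time_h),
               class = "tbwave_validation_error")
})

test_that("blocked cross-validation returns a candidate lambda", {
  tr <- make_noisy_sine_trace(n = 1200, seed = 8)
  cv <- cv_lambda(tr, 0.55, lambdas = c(0.1, 10), k = 3,
                  min_duration_h = 0)
  expect_true(cv$lambda %in% c(0.1, 10))
  expect_length(cv$cv_loss, 2L)
  expect_true(all(is.finite(cv$cv_loss)))
})
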