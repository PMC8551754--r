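test_that("kde_mode handles degenerate and well-separated inputs", {
  expect_equal(kde_mode(rep(37, 5)), 37)
  expect_equal(kde_mode(36.2), 36.2)
  expect_error(kde_mode(numeric()), class = "tbwave_validation_error")

  set.seed(1)
  expect_lt(abs(kde_mode(rnorm(5000, 37, 0.5)) - 37), 0.15)
  x <- c(rnorm(3500, 38, 0.3), rnorm(1500, 35, 0.3))
  expect_lt(abs(kde_mode(x) - 38), 0.15)
})

test_that("kde_mode bias on the normal decreases with sample size", {
  err_at <- function(n) {
    mean(vapply(1:20, function(r) {
      set.seed(1000 + r)
      abs(kde_mode(rnorm(n, 37, 0.5)) - 37)
    }, numeric(1)))
  }
  expect_lt(err_at(5000), err_at(500))
})

test_that("empirical quantiles use the linear-interpolation convention", {
  expect_equal(empirical_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(empirical_quantile(c(0, 10), 0.10), 1.0)
  set.seed(2)
  x <- rnorm(100)
  q <- empirical_quantile(x, c(0.1, 0.9))
  expect_lte(q[1], q[2])
  expect_error(empirical_quantile(x, 0), class = "tbwave_validation_error")
  expect_error(empirical_quantile(numeric(), 0.5),
               class = "tbwave_validation_error")
})

test_that("skewness is antisymmetric, affine-stable, and matches theory", {
  expect_equal(skewness(c(-1, 0, 1), "moment"), 0)
  expect_equal(skewness(c(-1, 0, 1), "quantile"), 0)
  set.seed(3)
  x <- rexp(200) + rnorm(200, sd = 0.1)
  for (m in c("moment", "quantile")) {
    expect_equal(skewness(-x, m), -skewness(x, m))
    expect_equal(skewness(3 + 2 * x, m), skewness(x, m), tolerance = 1e-10)
  }
  set.seed(4)
  expect_lt(abs(skewness(rexp(50000), "moment") - 2), 0.15)
  expect_error(skewness(rep(1, 10), "moment"),
               class = "tbwave_undefined_error")
  expect_error(skewness(c(1, 2), "moment"),
               class = "tbwave_validation_error")
})

test_that("classify_skew is seeded, directional, and guards small n", {
  set.seed(5)
  sym <- rnorm(2000)
  expect_equal(classify_skew(sym, seed = 1), "symmetric")
  expect_identical(classify_skew(sym, seed = 1), classify_skew(sym, seed = 1))
  expect_equal(classify_skew(rexp(2000), seed = 1), "right")
  expect_equal(classify_skew(-rexp(2000), seed = 1), "left")
  expect_error(classify_skew(rnorm(10), seed = 1),
               class = "tbwave_insufficient_data_error")
})

test_that("dip statistic matches the brute-force oracle on small samples", {
  set.seed(6)
  for (rep in 1:12) {
    n <- sample(4:50, 1)
    x <- switch(rep %% 4 + 1,
                rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 6)),
                round(rnorm(n), 1),
                runif(n))
    expect_equal(dip_statistic(x), dip_oracle(x), tolerance = 1e-9)
  }
})

test_that("dip statistic basics: bounds, affine invariance, spaced sample", {
  for (n in c(5, 17, 40)) {
    expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  }
  set.seed(7)
  x <- rnorm(100)
  expect_equal(dip_statistic(2.5 * x + 7), dip_statistic(x))
  expect_gte(dip_statistic(x), 1 / 200)
  expect_lte(dip_statistic(x), 0.25)
  # separated mixture has a larger dip than a normal of the same size
  set.seed(8)
  mix <- c(rnorm(1000), rnorm(1000, 6))
  set.seed(8)
  uni <- rnorm(2000)
  expect_gt(dip_statistic(mix), dip_statistic(uni))
  expect_error(dip_statistic(c(1, 2, 3)),
               class = "tbwave_insufficient_data_error")
})

test_that("dip test p-values are bounded, seeded, and directionally sane", {
  set.seed(9)
  mix <- c(rnorm(1000, 35, 0.3), rnorm(1000, 38, 0.3))
  r1 <- dip_test(mix, n_mc = 199, seed = 4)
  expect_lt(r1$dip_p, 0.05)
  expect_true(r1$bimodal)
  expect_identical(r1, dip_test(mix, n_mc = 199, seed = 4))
  expect_gte(r1$dip_p, 1 / 200)
  expect_lte(r1$dip_p, 1)

  uni <- rnorm(2000, 37, 0.5)
  r2 <- dip_test(uni, n_mc = 199, seed = 4)
  expect_gte(r2$dip_p, 0.05)
  expect_error(dip_test(uni, n_mc = 50), class = "tbwave_validation_error")
})

test_that("shape_report assembles consistent full and partial reports", {
  cfg <- shape_config(n_mc = 199, n_boot = 200, seed = 2)
  tr <- simulate_trace(sim_config(duration_days = 10, seed = 10))
  full <- shape_report(tr$tb_c, cfg)
  expect_true(full$bimodal)          # plateau wave marginal is bimodal
  expect_identical(full$bimodal, full$dip_p < 0.05)
  expect_lte(full$q10_c, full$q90_c)

  rest <- tr$tb_c[tr$truth_labels == "REST"]
  rest_rep <- shape_report(rest, cfg)
  expect_false(rest_rep$bimodal)     # a single plateau is unimodal

  partial <- shape_report(rnorm(10, 37), cfg)
  expect_false(is.na(partial$mode_c))
  expect_false(is.na(partial$q10_c))
  expect_true(is.na(partial$dip_stat))
  expect_true(is.na(partial$skew_class))
  expect_error(shape_report(numeric(), cfg),
               class = "tbwave_validation_error")
})

test_that("shape statistics are invariant to reading order", {
  set.seed(11)
  x <- c(rnorm(500, 35), rnorm(500, 38))
  xs <- sample(x)
  cfg <- shape_config(n_mc = 199, n_boot = 200, seed = 5)
  a <- shape_report(x, cfg)
  b <- shape_report(xs, cfg)
  for (f in c("mode_c", "q10_c", "q90_c", "skew", "dip_stat", "dip_p")) {
    expect_equal(a[[f]], b[[f]])
  }
})
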