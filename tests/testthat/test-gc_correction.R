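test_that("a constant depth profile fits a constant model", {
  set.seed(1)
  tbl <- synthetic_window_table(gc = stats::runif(100, 0.25, 0.65),
                                raw_depth = 30)
  model <- fit_gc_model(tbl)
  expect_true(all(abs(model$grid$expected_depth - 30) <= 1e-6 * 30))
  corr <- correct_depth(tbl, model)
  expect_equal(corr$corrected_depth, corr$raw_depth, tolerance = 1e-6)
})

test_that("a local-linear fit with span 1 reproduces an exact line", {
  set.seed(2)
  gc <- stats::runif(200, 0.25, 0.65)
  truth <- 30 * (1 + 0.5 * (gc - 0.5))
  tbl <- synthetic_window_table(gc = gc, raw_depth = truth)
  model <- fit_gc_model(tbl, span = 1)
  expect_equal(predict(model, gc), truth, tolerance = 1e-6)
})

test_that("the fitted curve tracks a noisy linear signal (binned oracle)", {
  set.seed(3)
  n <- 5000
  gc <- stats::runif(n, 0.25, 0.65)
  truth <- 30 * (1 + 0.5 * (gc - 0.5))
  tbl <- synthetic_window_table(gc = gc, raw_depth = truth + stats::rnorm(n))
  model <- fit_gc_model(tbl)
  central <- stats::quantile(gc, c(0.05, 0.95))
  at <- seq(central[1], central[2], length.out = 50)
  expect_lt(max(abs(predict(model, at) - 30 * (1 + 0.5 * (at - 0.5)))), 0.5)
  # independent oracle: fine-binned means agree with the curve
  bins <- cut(gc, breaks = seq(0.25, 0.65, length.out = 41))
  bin_mean <- tapply(tbl$raw_depth, bins, mean)
  bin_mid <- seq(0.255, 0.645, by = 0.01)
  ok <- !is.na(bin_mean) & bin_mid > central[1] & bin_mid < central[2]
  expect_lt(max(abs(predict(model, bin_mid[ok]) - bin_mean[ok])), 0.6)
})

test_that("correction divides by expected depth and rescales to reference", {
  model <- sexlinkr:::new_gc_model(
    grid = tibble::tibble(gc = c(0.3, 0.5), expected_depth = c(40, 40)),
    span = 0.3, degree = 1, reference_depth = 30,
    gc_range = c(0.3, 0.5), constant = FALSE
  )
  tbl <- synthetic_window_table(gc = 0.4, raw_depth = 20)
  expect_equal(correct_depth(tbl, model)$corrected_depth, 15)
  # evaluation outside the fitted range clamps; undefined GC gets factor 1
  expect_equal(predict(model, c(0.1, 0.9)), c(40, 40))
  expect_equal(predict(model, NA_real_), 30)
})

test_that("a known multiplicative GC bias is flattened", {
  set.seed(4)
  gc <- stats::runif(200, 0.25, 0.65)
  b <- gc_bias_curve(gc, 1)
  tbl <- synthetic_window_table(gc = gc, raw_depth = 30 * b)
  model <- fit_gc_model(tbl)
  corr <- correct_depth(tbl, model)
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lte(cv(corr$corrected_depth), 0.02)
  expect_gte(cv(corr$raw_depth), 5 * cv(corr$corrected_depth))
  # oracle: dividing by the true bias curve gives the same flat profile
  oracle <- 30 * b / b * model$reference_depth / 30
  expect_equal(corr$corrected_depth, oracle, tolerance = 0.02)
  # mean preservation on the fitting sample
  expect_lt(abs(global_raw_mean(corr, "corrected_depth") /
                  model$reference_depth - 1), 0.02)
})

test_that("correction is idempotent up to tolerance", {
  set.seed(5)
  gc <- stats::runif(300, 0.25, 0.65)
  tbl <- synthetic_window_table(gc = gc, raw_depth = 30 * gc_bias_curve(gc, 1))
  corr <- correct_depth(tbl, fit_gc_model(tbl))
  tbl2 <- dplyr::mutate(corr, raw_depth = corrected_depth)
  model2 <- fit_gc_model(tbl2)
  rng <- range(model2$grid$expected_depth)
  expect_lt(rng[2] / rng[1] - 1, 0.02)
})

test_that("monotone bias in gives flat depth out", {
  set.seed(6)
  gc <- stats::runif(5000, 0.25, 0.65)
  b <- exp(0.6 * (gc - 0.5))  # strictly monotone bias
  tbl <- synthetic_window_table(gc = gc, raw_depth = 30 * b)
  corr <- correct_depth(tbl, fit_gc_model(tbl))
  expect_lte(abs(stats::cor(corr$corrected_depth, corr$gc)), 0.1)
})

test_that("degenerate inputs are handled per contract", {
  small <- synthetic_window_table(gc = stats::runif(10), raw_depth = 5)
  expect_error(fit_gc_model(small), "smaller window size")

  flat_gc <- synthetic_window_table(gc = rep(0.5, 50), raw_depth = 12)
  model <- fit_gc_model(flat_gc)
  expect_true(model$constant)
  expect_equal(model$grid$expected_depth, 12)

  varied <- synthetic_window_table(gc = seq(0.3, 0.6, length.out = 30),
                                   raw_depth = 12)
  expect_warning(correct_depth(varied, model), "constant")

  expect_error(fit_gc_model(flat_gc, span = 0), "span")
  expect_error(fit_gc_model(flat_gc, degree = 2), "degree")
})

test_that("tidy, glance and autoplot expose the fitted model", {
  set.seed(7)
  tbl <- synthetic_window_table(gc = stats::runif(60, 0.3, 0.6),
                                raw_depth = 20)
  model <- fit_gc_model(tbl)
  expect_named(tidy(model), c("gc", "expected_depth"))
  g <- glance(model)
  expect_equal(g$reference_depth, 20)
  expect_s3_class(autoplot(model, tbl), "ggplot")
})
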