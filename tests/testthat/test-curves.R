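test_that("logistic evaluation matches the closed form on both orientations", {
  rise <- logistic_fit(20, 0.3, 0.5, "rising")
  xs <- c(0.5, 1, 3, 10, 25)
  expect_equal(logistic_eval(rise, xs), 20 / (1 + 0.3 * exp(-0.5 * xs)))
  expect_equal(logistic_eval(rise, 1e6), 20)  # asymptote

  fall <- wzs_iteration_fit()
  # published round-1 point: the fitted function passes through the
  # log2 of the printed round-1 variant count (14,311,513 -> 23.77)
  expect_equal(logistic_eval(fall, 1), 23.78, tolerance = 1e-3)
  expect_equal(logistic_eval(fall, 1),
               log2(wzs_iteration_series()$y_raw[1]), tolerance = 1e-3)
  # falling form has a pole where b*exp(-c x) reaches 1
  steep <- logistic_fit(10, 1.5, 0.5, "falling")
  expect_error(logistic_eval(steep, 0.5), "undefined")
})

test_that("analytic tangent slope agrees with central finite differences", {
  set.seed(60)
  # evaluation windows keep the slope large enough that the central
  # difference is not dominated by floating-point cancellation
  cases <- list(list(fit = logistic_fit(20, 0.3, 0.5, "rising"), hi = 20),
                list(fit = logistic_fit(21.34, 0.7039, 1.9272, "falling"), hi = 6))
  h <- 1e-4
  for (cs in cases) {
    f <- cs$fit
    for (x in sort(stats::runif(10, 1.5, cs$hi))) {
      num <- (logistic_eval(f, x + h) - logistic_eval(f, x - h)) / (2 * h)
      expect_equal(tangent_slope(f, x), num, tolerance = 1e-6)
    }
  }
  fits <- lapply(cases, `[[`, "fit")
  expect_gt(tangent_slope(fits[[1]], 5), 0)
  expect_lt(tangent_slope(fits[[2]], 5), 0)
})

test_that("noiseless curves are recovered to numerical precision", {
  x <- 1:30
  for (orient in c("rising", "falling")) {
    s <- if (orient == "rising") 1 else -1
    y <- 20 / (1 + s * 0.3 * exp(-0.5 * x))
    fit <- fit_logistic(tibble::tibble(x = x, y_raw = 2^y, y = y), orient)
    expect_equal(fit$a, 20, tolerance = 1e-6)
    expect_equal(fit$b, 0.3, tolerance = 1e-6)
    expect_equal(fit$c, 0.5, tolerance = 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  expect_error(fit_logistic(curve_series(1:3, c(2, 3, 4)), "rising"),
               "at least 4")
})

test_that("refitting the published series reproduces the published fits", {
  it <- fit_logistic(wzs_iteration_series(), "falling")
  expect_equal(it$a, 21.34, tolerance = 0.001)
  expect_equal(it$b, 0.7039, tolerance = 0.001)
  expect_equal(it$c, 1.9272, tolerance = 0.001)
  expect_equal(it$r, 0.9999, tolerance = 0.001)

  cov <- fit_logistic(wzs_coverage_series(), "rising")
  expect_equal(cov$a, 23.48, tolerance = 0.001)
  expect_equal(cov$b, 0.2202, tolerance = 0.005)
  expect_equal(cov$c, 0.6047, tolerance = 0.005)
  expect_equal(cov$r, 0.9954, tolerance = 0.001)
})

test_that("threshold coverage is found by bisection and rounds up", {
  du <- pig_breed_coverage_fits()$DU
  thr <- threshold_coverage(du, tau = 1e-4)
  expect_equal(thr$x_star, 18.2, tolerance = 0.01)
  expect_equal(thr$recommendation, 19)
  expect_false(thr$boundary)

  # grid-search oracle
  grid <- seq(1, 40, by = 1e-3)
  slopes <- tangent_slope(du, grid)
  best <- grid[grid > log(du$b) / du$c][which.min(abs(slopes[grid > log(du$b) / du$c] - 1e-4))]
  expect_equal(thr$x_star, best, tolerance = 2e-3)

  # monotone in tau
  expect_gt(threshold_coverage(du, 1e-5)$x_star, thr$x_star)

  # tau above the attainable slope: boundary warning
  expect_warning(deg <- threshold_coverage(logistic_fit(5, 0.5, 0.1, "rising"), tau = 10),
                 "never exceeds")
  expect_true(deg$boundary)
  expect_error(threshold_coverage(wzs_iteration_fit(), 1e-4), "rising")
})

test_that("optimal iteration count scans the falling slope magnitude", {
  wzs <- wzs_iteration_fit()
  expect_equal(optimal_iterations(wzs, tau = 1e-4), 7)
  expect_gt(abs(tangent_slope(wzs, 6)), 1e-4)
  expect_lte(abs(tangent_slope(wzs, 7)), 1e-4)
  # equals a linear scan
  scan <- which(vapply(2:1000, function(n) abs(tangent_slope(wzs, n)) <= 1e-4,
                       logical(1)))[1] + 1L
  expect_equal(optimal_iterations(wzs), scan)
  # already converged at round 2
  flat <- logistic_fit(20, 0.5, 8, "falling")
  expect_equal(optimal_iterations(flat, 1e-4), 2)
  expect_error(optimal_iterations(logistic_fit(20, 0.5, 1e-4, "falling"), 1e-12),
               "no round")
  expect_error(optimal_iterations(pig_breed_coverage_fits()$DU), "falling")
})

test_that("multi-breed recommendation is driven by the slowest breed", {
  fits <- pig_breed_coverage_fits()
  rec <- multi_breed_recommendation(fits, tau = 1e-4)
  expect_equal(rec$x_star_max, 18.2, tolerance = 0.01)
  expect_equal(rec$recommendation, 19)
  per <- vapply(fits, function(f) threshold_coverage(f, 1e-4)$x_star, numeric(1))
  expect_equal(rec$x_star_max, max(per))
  expect_identical(names(which.max(per)), "DU")
  single <- multi_breed_recommendation(fits["WZS"], 1e-4)
  expect_equal(single$x_star_max, threshold_coverage(fits$WZS, 1e-4)$x_star)
})

test_that("curve series validates its invariants and tidiers work", {
  expect_error(curve_series(c(1, 2, 2), c(5, 6, 7)), "diff")
  expect_error(curve_series(1:3, c(5, 0, 7)))
  fit <- wzs_iteration_fit()
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b", "c"))
  expect_equal(td$estimate, c(21.34, 0.7039, 1.9272))
  gl <- glance(fit)
  expect_identical(gl$orientation, "falling")
  p <- autoplot(fit_logistic(wzs_coverage_series(), "rising"))
  expect_s3_class(p, "ggplot")
})
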