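test_that("detachment rates are sediment mass per area and time, averaged per box", {
  one <- tibble::tibble(
    box_id = "b1",
    intervals = list(tibble::tibble(start_s = 0, duration_s = 5,
                                    sediment_kg = 0.1))
  )
  expect_equal(detachment_rate(one)$asd, 0.1 / (0.0625 * 5))
  two <- tibble::tibble(
    box_id = "b2",
    intervals = list(tibble::tibble(start_s = c(0, 10), duration_s = 5,
                                    sediment_kg = c(0.1, 0.3)))
  )
  expect_equal(detachment_rate(two)$asd,
               mean(c(0.1, 0.3) / (0.0625 * 5)))
  zero <- tibble::tibble(
    box_id = "b3",
    intervals = list(tibble::tibble(start_s = 0, duration_s = 5,
                                    sediment_kg = 0))
  )
  expect_equal(detachment_rate(zero)$asd, 0)
  bad <- tibble::tibble(
    box_id = "b4",
    intervals = list(tibble::tibble(start_s = 0, duration_s = 0,
                                    sediment_kg = 0.1))
  )
  expect_error(detachment_rate(bad), class = "rhizo_invalid_argument")
})

test_that("normalisation divides by the extrapolated zero-RLD rate", {
  rld <- c(0, 0, 5, 10, 20, 40)
  rates <- tibble::tibble(rld = rld, asd = 2 * exp(-0.08 * rld))
  out <- relative_detachment(rates)
  expect_equal(attr(out, "a0"), 2, tolerance = 1e-6)
  expect_equal(out$ratio, exp(-0.08 * rld), tolerance = 1e-6)
  # bare boxes alone give ratios ~1
  bare <- tibble::tibble(rld = rep(0, 4), asd = rep(1.5, 4))
  expect_equal(relative_detachment(bare)$ratio, rep(1, 4))
  # no bare controls and too few RLD levels -> cannot extrapolate
  thin <- tibble::tibble(rld = c(5, 5, 10), asd = c(1, 1.1, 0.8))
  expect_error(relative_detachment(thin), class = "rhizo_insufficient_data")
})

test_that("noisy synthetic batches recover the bare-soil rate within 10%", {
  runs <- gen_erosion_runs(n_boxes = 18, seed = 21)
  out <- runs |> detachment_rate() |> relative_detachment()
  expect_lt(abs(attr(out, "a0") - 0.5) / 0.5, 0.10)
})

test_that("empirical fits recover noiseless generating parameters exactly", {
  pts <- tibble::tibble(rld = seq(0, 56, length.out = 12),
                        ratio = exp(-0.095 * seq(0, 56, length.out = 12)))
  m <- fit_empirical(pts, "exponential")
  expect_equal(unname(m$estimate["b"]), -0.095, tolerance = 1e-8)
  expect_lt(m$se[["b"]], 1e-8)

  rldp <- c(2, 6, 10, 14, 18, 25, 30, 40)
  piece <- tibble::tibble(
    rld = rldp,
    ratio = ifelse(rldp <= 19, exp(-0.069 * rldp), 0.268)
  )
  mp <- fit_empirical(piece, "piecewise", breakpoint = 19)
  expect_equal(unname(mp$estimate["plateau"]), 0.268)
  expect_equal(unname(mp$estimate["b"]), -0.069, tolerance = 1e-8)

  dp <- tibble::tibble(rld = seq(0, 50, 5),
                       ratio = 0.2 + 0.8 * exp(-0.1 * seq(0, 50, 5)))
  md <- fit_empirical(dp, "decay_plateau")
  expect_equal(unname(md$estimate["b"]), -0.1, tolerance = 1e-6)
  expect_equal(unname(md$estimate["plateau"]), 0.2, tolerance = 1e-6)
})

test_that("empirical fits demand enough points", {
  few <- tibble::tibble(rld = c(0, 5, 10), ratio = exp(-0.1 * c(0, 5, 10)))
  expect_error(fit_empirical(few, "exponential"),
               class = "rhizo_insufficient_data")
  no_plateau <- tibble::tibble(rld = c(0, 5, 10, 15, 25),
                               ratio = c(1, 0.6, 0.4, 0.3, 0.27))
  expect_error(fit_empirical(no_plateau, "piecewise", breakpoint = 30),
               class = "rhizo_insufficient_data")
})

test_that("printed exponents reproduce the printed reduction factors", {
  wt <- manual_model(b = -0.095)
  expect_equal(evaluate_empirical(wt, 25), 0.09, tolerance = 0.04)
  hairy <- manual_model(b = -0.066)
  expect_equal(evaluate_empirical(hairy, c(25, 35, 45)),
               c(0.19, 0.10, 0.05), tolerance = 0.04)
  # model is 1 at RLD 0, non-increasing, bounded in (0, 1]
  grid <- seq(0, 56, 1)
  vals <- evaluate_empirical(wt, grid)
  expect_equal(vals[1], 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(evaluate_empirical(wt, -1), class = "rhizo_invalid_argument")
})

test_that("fitting noisy synthetic data recovers the exponent within 2 SE", {
  runs <- gen_erosion_runs(n_boxes = 18, sigma = 0.3, seed = 31)
  est <- runs |>
    detachment_rate() |>
    relative_detachment() |>
    fit_empirical()
  expect_lt(abs(est$estimate[["b"]] - (-0.095)), 2 * est$se[["b"]])
})

test_that("Monte-Carlo bands collapse at zero SE and widen with SE", {
  grid <- c(0, 10, 25, 40)
  degenerate <- manual_model(b = -0.095, b_se = 0)
  band0 <- monte_carlo_band(degenerate, grid, draws = 500, seed = 1)
  expect_equal(band0$lower, band0$fit)
  expect_equal(band0$upper, band0$fit)

  narrow <- monte_carlo_band(manual_model(-0.095, 0.003), grid,
                             draws = 2000, seed = 2)
  wide <- monte_carlo_band(manual_model(-0.095, 0.009), grid,
                           draws = 2000, seed = 2)
  expect_true(all((wide$upper - wide$lower)[-1] >
                    (narrow$upper - narrow$lower)[-1]))
  # median containment and determinism
  expect_true(all(narrow$lower <= narrow$fit & narrow$fit <= narrow$upper))
  again <- monte_carlo_band(manual_model(-0.095, 0.003), grid,
                            draws = 2000, seed = 2)
  expect_identical(narrow$lower, again$lower)
  expect_error(monte_carlo_band(manual_model(-0.095), grid),
               class = "rhizo_invalid_model")
})

test_that("band comparison flags separated curves only", {
  grid <- seq(0, 50, 10)
  a <- monte_carlo_band(manual_model(-0.095, 1e-4), grid,
                        draws = 1000, seed = 5)
  b <- monte_carlo_band(manual_model(-0.066, 1e-4), grid,
                        draws = 1000, seed = 6)
  cmp <- compare_bands(a, b)
  expect_false(cmp$significant[cmp$rld == 0])
  expect_true(all(cmp$significant[cmp$rld >= 20]))
  self <- compare_bands(a, a)
  expect_false(any(self$significant))
  short <- monte_carlo_band(manual_model(-0.066, 1e-4), grid[-1],
                            draws = 100, seed = 7)
  expect_error(compare_bands(a, short), class = "rhizo_invalid_argument")
})

test_that("tidy, glance, predict and autoplot work on erosion models", {
  pts <- tibble::tibble(rld = seq(0, 56, length.out = 12),
                        ratio = exp(-0.08 * seq(0, 56, length.out = 12)))
  m <- fit_empirical(pts)
  td <- tidy(m)
  expect_equal(td$term, "b")
  expect_s3_class(glance(m), "tbl_df")
  expect_equal(predict(m, tibble::tibble(rld = 0)), 1)
  band <- monte_carlo_band(m, pts$rld, draws = 200, seed = 3)
  expect_s3_class(autoplot(m, band = band), "ggplot")
  expect_s3_class(autoplot(band), "ggplot")
})
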