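pub_env <- env_summary(range = c(-1.401, 2.532))

test_that("crossover is -b2/b3 and satisfies its defining identity", {
  expect_equal(round(crossover(as_gxe_fit(0, 0, 4.113, -12.464)), 3), 0.330)
  expect_equal(round(crossover(as_gxe_fit(0, 0, 7.405, -12.651)), 3), 0.585)
  expect_equal(crossover(as_gxe_fit(1, 1, 0, -5)), 0)
  expect_error(crossover(as_gxe_fit(1, 1, 2, 0)), "no interaction")
  expect_warning(crossover(as_gxe_fit(1, 1, 5, 1e-12)), "negligible")

  set.seed(1)
  for (rep in 1:50) {
    b2 <- runif(1, -10, 10)
    b3 <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    xc <- crossover(as_gxe_fit(0, 0, b2, b3))
    expect_equal(xc * b3 + b2, 0, tolerance = 1e-12)
  }
})

test_that("RoS roots sit exactly at the critical t and match the grid oracle", {
  set.seed(2)
  for (rep in 1:100) {
    fit <- random_fit()
    ros <- ros_on_x(fit, pub_env)
    V <- fit$vcov
    tcrit <- ros$t_critical
    for (root in c(ros$lower, ros$upper)) {
      if (is.na(root)) next
      tv <- (fit$coefficients[["b2"]] + fit$coefficients[["b3"]] * root) /
        sqrt(V["b2", "b2"] + root^2 * V["b3", "b3"] +
               2 * root * V["b2", "b3"])
      expect_equal(abs(tv), tcrit, tolerance = 1e-6)
    }
    boundaries <- ros_grid_oracle(
      fit$coefficients[["b2"]], fit$coefficients[["b3"]],
      V["b2", "b2"], V["b3", "b3"], V["b2", "b3"], df = fit$df_residual
    )
    roots_in_window <- sort(c(ros$lower, ros$upper))
    roots_in_window <- roots_in_window[!is.na(roots_in_window) &
                                         abs(roots_in_window) < 10]
    expect_equal(length(boundaries), length(roots_in_window))
    if (length(boundaries)) {
      expect_equal(roots_in_window, boundaries, tolerance = 1e-3)
    }
  }
})

test_that("a null group difference yields no significant region", {
  fit <- as_gxe_fit(10, 1, 0, 0.0, vcov = diag(c(1, 1, 1, 1)), df = 80)
  fit$coefficients[["b3"]] <- 0
  ros <- ros_on_x(fit, pub_env)
  expect_false(ros$left_side_significant)
  expect_false(ros$right_side_significant)
})

test_that("PoI reproduces printed-table values and the integration oracle", {
  expect_equal(round(poi(as_gxe_fit(0, 0, 4.113, -12.464), pub_env), 2), 0.62)
  expect_equal(round(poi(as_gxe_fit(0, 0, 7.405, -12.651), pub_env), 2), 0.49)
  expect_equal(round(poi(as_gxe_fit(0, 0, 8.926, -10.909), pub_env), 2), 0.37)

  # crossover exactly mid-range -> 0.5
  mid <- (pub_env$lower + pub_env$upper) / 2
  expect_equal(poi(as_gxe_fit(0, 0, -mid * -4, -4), pub_env), 0.5)

  set.seed(3)
  for (rep in 1:50) {
    b2 <- runif(1, -15, 15)
    b3 <- runif(1, 0.5, 15) * sample(c(-1, 1), 1)
    fit <- as_gxe_fit(0, 0, b2, b3)
    right_better <- (b3 < 0)
    expect_equal(
      poi(fit, pub_env),
      poi_integration_oracle(b2, b3, pub_env$lower, pub_env$upper,
                             right_better = right_better),
      tolerance = 1e-6
    )
  }
})

test_that("PoI clamps when the crossover leaves the evaluation range", {
  # crossover above the range: no for-better area remains
  expect_equal(poi(as_gxe_fit(0, 0, 30, -6), pub_env), 0)
  # crossover below the range: everything is for-better
  expect_equal(poi(as_gxe_fit(0, 0, -30, -6), pub_env), 1)
  # reflection about the crossover gives 0.5 exactly
  b2 <- 5
  b3 <- -8
  xc <- -b2 / b3
  half <- 0.9
  refl <- env_summary(range = c(xc - half, xc + half))
  expect_equal(poi(as_gxe_fit(0, 0, b2, b3), refl), 0.5)
})

test_that("PoI follows the for-better side under polarity and interaction sign", {
  env <- pub_env
  base <- poi(as_gxe_fit(0, 0, 7.405, -12.651), env)
  # positive interaction with higher-is-worse: for-better side flips left
  flipped <- poi(as_gxe_fit(0, 0, -7.405, 12.651), env)
  expect_equal(base + flipped, 1)
  # higher-is-better outcome flips the orientation back
  better <- poi(as_gxe_fit(0, 0, -7.405, 12.651), env,
                polarity = outcome_polarity(FALSE))
  expect_equal(better, base)
})

test_that("PA is the normal tail beyond the crossover and is monotone", {
  env <- env_summary(mean = 0.57, sd = 0.98)
  expect_equal(pa(0.57, env), 0.5)
  expect_equal(pa(0.57 + 2 * 0.98, env), 1 - pnorm(2))
  expect_equal(round(pa(0.57 + 2 * 0.98, env), 4), 0.0228)
  xs <- seq(-2, 3, by = 0.25)
  expect_true(all(diff(vapply(xs, pa, 0, env = env)) < 0))
  expect_equal(pa(0.3, env, for_better_right = FALSE),
               1 - pa(0.3, env, for_better_right = TRUE))
})

test_that("pattern classification follows the RoS/PoI/PA decision rules", {
  expect_equal(
    classify_pattern(left_side_significant = TRUE,
                     right_side_significant = TRUE, poi = 0.49, pa = 0.28),
    "differential_susceptibility"
  )
  expect_equal(
    classify_pattern(left_side_significant = TRUE,
                     right_side_significant = FALSE, poi = 0.18, pa = 0.10),
    "diathesis_stress"
  )
  expect_equal(
    classify_pattern(left_side_significant = FALSE,
                     right_side_significant = TRUE, poi = 0.62, pa = 0.37),
    "vantage_sensitivity"
  )
  expect_equal(
    classify_pattern(left_side_significant = FALSE,
                     right_side_significant = FALSE, poi = 0.5, pa = 0.5),
    "no_interaction"
  )
  # both sides significant but PoI outside the band: inconclusive
  expect_equal(
    classify_pattern(left_side_significant = TRUE,
                     right_side_significant = TRUE, poi = 0.95, pa = 0.5),
    "inconclusive"
  )
})

test_that("ds_indices bundles crossover, RoS, PoI, PA and the label", {
  set.seed(4)
  n <- 400
  xv <- rnorm(n, 0.57, 0.98)
  z <- rbinom(n, 1, 0.5)
  y <- 76.5 - 2.7 * xv + 7.4 * z - 12.7 * xv * z + rnorm(n, sd = 12)
  ids <- sprintf("i%d", 1:n)
  mod <- gxeds:::new_moderator_group(ids, z, character(0), "sim")
  dat <- gxe_data(data.frame(individual_id = ids, lesms = xv, outcome = y),
                  outcome = "outcome", moderator = mod)
  fit <- fit_gxe(dat)
  idx <- ds_indices(fit, env_summary(x = dat$x))
  expect_equal(idx$crossover,
               -fit$coefficients[["b2"]] / fit$coefficients[["b3"]])
  expect_true(idx$poi >= 0 && idx$poi <= 1)
  expect_true(idx$pa >= 0 && idx$pa <= 1)
  expect_equal(idx$pattern, "differential_susceptibility")
})

test_that("interaction plots draw crossing lines and shade significant flanks", {
  set.seed(8)
  n <- 600
  xv <- rnorm(n, 0.57, 0.98)
  z <- rbinom(n, 1, 0.5)
  y <- 76.5 - 2.7 * xv + 7.4 * z - 12.7 * xv * z + rnorm(n, sd = 10)
  ids <- sprintf("i%d", 1:n)
  mod <- gxeds:::new_moderator_group(ids, z, character(0), "sim")
  dat <- gxe_data(data.frame(individual_id = ids, lesms = xv, outcome = y),
                  outcome = "outcome", moderator = mod)
  fit <- fit_gxe(dat)
  env <- env_summary(x = dat$x)
  file <- withr::local_tempfile(fileext = ".png")
  p <- plot_interaction(fit, env, file = file)
  expect_true(file.exists(file))
  segs <- gxeds:::significant_segments(fit, env)
  expect_equal(nrow(segs), 2) # both flanks shaded for a crossover effect

  # no covariance -> no shading, but the lines still intersect at -b2/b3
  f0 <- as_gxe_fit(10, 1, 2, -4)
  expect_equal(nrow(gxeds:::significant_segments(f0, env)), 0)
  p0 <- plot_interaction(f0, env)
  b <- f0$coefficients
  xc <- crossover(f0)
  y_ref <- b[["b0"]] + b[["b1"]] * xc
  y_risk <- b[["b0"]] + b[["b2"]] + (b[["b1"]] + b[["b3"]]) * xc
  expect_equal(y_ref, y_risk)
})
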