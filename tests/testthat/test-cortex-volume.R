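test_that("slice summation is plain area times spacing", {
  sl <- data.frame(kidney_area_cm2 = c(2, 4, 4, 2),
                   cortex_area_cm2 = c(1, 2, 2, 1))
  v <- volume_from_slices(sl, spacing_cm = 0.5)
  expect_equal(v$whole_kidney_cm3, 6)
  expect_equal(v$cortex_cm3, 3)
  one <- data.frame(kidney_area_cm2 = 7.3, cortex_area_cm2 = 2.9)
  expect_equal(volume_from_slices(one, 0.4)$whole_kidney_cm3, 7.3 * 0.4)
  expect_error(volume_from_slices(sl[0, ], 0.5),
               class = "nephest_domain_error")
  bad <- data.frame(kidney_area_cm2 = 2, cortex_area_cm2 = 3)
  expect_error(volume_from_slices(bad, 0.5), class = "nephest_domain_error")
})

test_that("summation is additive over partitions and order-invariant", {
  set.seed(3)
  sl <- data.frame(kidney_area_cm2 = runif(20, 1, 10))
  sl$cortex_area_cm2 <- sl$kidney_area_cm2 * runif(20, 0.2, 0.6)
  sl$spacing_cm <- 0.3
  whole <- volume_from_slices(sl)
  split1 <- volume_from_slices(sl[1:7, ])
  split2 <- volume_from_slices(sl[8:20, ])
  expect_equal(whole$cortex_cm3, split1$cortex_cm3 + split2$cortex_cm3)
  shuf <- volume_from_slices(sl[sample(20), ])
  expect_equal(shuf$whole_kidney_cm3, whole$whole_kidney_cm3)
  expect_true(whole$cortex_cm3 / whole$whole_kidney_cm3 >= 0 &&
                whole$cortex_cm3 / whole$whole_kidney_cm3 <= 1)
})

test_that("the ellipsoid phantom converges to the closed-form volume", {
  true_v <- 4 / 3 * pi * 3 * 2 * 5
  ph <- mri_phantom(c(3, 2, 5), 0.5, 0.1)
  expect_equal(ph$true$whole_kidney_cm3, true_v)
  v <- volume_from_slices(ph$slices)
  expect_lt(abs(v$whole_kidney_cm3 - true_v),
            max(ph$slices$kidney_area_cm2) * 0.1)  # one-slice bound
  # discretisation error shrinks monotonically as spacing halves
  errs <- vapply(c(0.4, 0.2, 0.1), function(sp) {
    abs(volume_from_slices(mri_phantom(c(3, 2, 5), 0.5, sp)$slices
                           )$whole_kidney_cm3 - true_v)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # shell fraction 0.5 leaves 1 - 0.5^3 of the whole as cortex
  expect_equal(ph$true$cortex_cm3 / ph$true$whole_kidney_cm3, 0.875)
})

test_that("noiseless linear volumes are recovered to 6 decimals", {
  set.seed(10)
  d <- data.frame(a = runif(30, 8, 13), sexm = rbinom(30, 1, 0.5),
                  egfr = runif(30, 20, 90))
  d$cortex_volume_cm3 <- 5 + 7.5 * d$a - 12 * d$sexm + 0.3 * d$egfr
  fit <- fit_cortex_volume_model(d, features = c("a", "sexm", "egfr"))
  expect_equal(unname(fit$coefficients), c(5, 7.5, -12, 0.3),
               tolerance = 1e-6)
  # training rows predict their own response
  pr <- predict_cortex_volume(fit, d)
  expect_equal(as.numeric(pr), d$cortex_volume_cm3, tolerance = 1e-8)
})

test_that("identity regression has slope 1 and intercept 0", {
  d <- data.frame(x = 1:10 + 0.5, cortex_volume_cm3 = 1:10 + 0.5)
  fit <- fit_cortex_volume_model(d, features = "x")
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-10)
})

test_that("noisy coefficients land within 3 standard errors", {
  set.seed(77)
  n <- 200
  d <- data.frame(a = runif(n, 8, 13), bw = rnorm(n, 3.1, 0.5))
  beta <- c(10, 6, 9)
  d$cortex_volume_cm3 <- beta[1] + beta[2] * d$a + beta[3] * d$bw +
    rnorm(n, 0, 8)
  fit <- fit_cortex_volume_model(d, features = c("a", "bw"))
  se <- fit$fit_diagnostics$coef_se
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))
})

test_that("collinear designs are refused with the columns named", {
  d <- data.frame(x = 1:10, y = 2 * (1:10), cortex_volume_cm3 = rnorm(10))
  err <- tryCatch(fit_cortex_volume_model(d, features = c("x", "y")),
                  error = identity)
  expect_s3_class(err, "nephest_domain_error")
  expect_match(conditionMessage(err), "y")
})

test_that("prediction guards: missing features, flooring, intervals", {
  d <- data.frame(x = 1:20, cortex_volume_cm3 = 10 + 2 * (1:20))
  fit <- fit_cortex_volume_model(d, features = "x")
  expect_error(predict_cortex_volume(fit, data.frame(z = 1)),
               class = "nephest_domain_error")
  d2 <- data.frame(x = seq(-1, 1, by = 0.5),
                   cortex_volume_cm3 = c(8, 9, 11, 10, 12))
  f2 <- fit_cortex_volume_model(d2, features = "x")
  expect_warning(p <- predict_cortex_volume(f2, data.frame(x = -100)),
                 "floored")
  expect_identical(as.numeric(p), 0)
  expect_true(attr(p, "flagged"))
  # prediction interval widens away from the feature mean
  set.seed(5)
  d3 <- data.frame(x = rnorm(50, 10, 2))
  d3$cortex_volume_cm3 <- 3 * d3$x + rnorm(50)
  f3 <- fit_cortex_volume_model(d3, features = "x")
  grid <- data.frame(x = mean(d3$x) + c(0, 2, 4, 8))
  pr <- predict_cortex_volume(f3, grid, interval = "prediction")
  width <- attr(pr, "upper") - attr(pr, "lower")
  expect_true(all(diff(width) > 0))
})
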