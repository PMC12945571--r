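# closed-form normal-equations oracle for the log-log least-squares fit,
# independent of the lm() route used by the package
oracle_power_fit <- function(inr, ru) {
  x <- log(inr); y <- log(ru)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = exp(mean(y) - b * mean(x)), b = b)
}

published_profile_points <- function() {
  tibble::tibble(inr = c(0.94, 1.84, 2.81, 4.10),
                 ru_percent = c(1.4, 2.2, 3.2, 4.2))
}

test_that("noise-free power laws are recovered exactly", {
  pts <- tibble::tibble(inr = c(1, 2, 4), ru_percent = c(2, 4, 8))
  prof <- fit_power_profile(pts)
  expect_equal(prof$coefficient_a, 2, tolerance = 1e-9)
  expect_equal(prof$exponent_b, 1, tolerance = 1e-9)
  expect_equal(predict_ru(prof, 3), 6, tolerance = 1e-9)

  # random exact power laws, including negative exponents
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.5, 5); b <- runif(1, -1.5, 1.5)
    x <- sort(runif(5, 1, 4))
    prof <- fit_power_profile(tibble::tibble(inr = x, ru_percent = a * x^b))
    expect_equal(prof$coefficient_a, a, tolerance = 1e-9)
    expect_equal(prof$exponent_b, b, tolerance = 1e-9)
  }

  # two points: interpolating power law, zero residual
  two <- tibble::tibble(inr = c(1.2, 3.1), ru_percent = c(1.9, 4.4))
  prof2 <- fit_power_profile(two)
  expect_equal(predict_ru(prof2, two$inr), two$ru_percent, tolerance = 1e-9)
})

test_that("log-log fit of the published profile points matches the closed-form oracle", {
  pts <- published_profile_points()
  prof <- fit_power_profile(pts)
  orc <- oracle_power_fit(pts$inr, pts$ru_percent)
  expect_equal(prof$coefficient_a, unname(orc["a"]), tolerance = 1e-9)
  expect_equal(prof$exponent_b, unname(orc["b"]), tolerance = 1e-9)
  # frozen values computed from the closed form ahead of the build
  expect_equal(prof$coefficient_a, 1.443177, tolerance = 1e-6)
  expect_equal(prof$exponent_b, 0.7539204, tolerance = 1e-6)
  expect_equal(predict_ru(prof, 2.5), 2.879617, tolerance = 1e-6)
})

test_that("prediction is domain-guarded and monotone for rising profiles", {
  prof <- fit_power_profile(published_profile_points(), domain = c(1, 4))
  expect_error(predict_ru(prof, 5), class = "inrmu_domain_error")
  expect_error(predict_ru(prof, 0.5), class = "inrmu_domain_error")
  expect_silent(predict_ru(prof, 5, extrapolate = TRUE))
  x <- seq(1, 4, by = 0.1)
  expect_true(all(diff(predict_ru(prof, x)) > 0)) # b > 0 here

  expect_error(fit_power_profile(published_profile_points()[1, ]),
               class = "inrmu_invalid_input")
  expect_error(
    fit_power_profile(tibble::tibble(inr = c(1, -2), ru_percent = c(1, 2))),
    class = "inrmu_invalid_input"
  )
})

test_that("profiles round-trip through JSON and support tidy/glance/autoplot", {
  prof <- fit_power_profile(published_profile_points())
  path <- withr::local_tempfile(fileext = ".json")
  write_profile_json(prof, path)
  back <- read_profile_json(path)
  expect_equal(back$coefficient_a, prof$coefficient_a, tolerance = 1e-12)
  expect_equal(back$exponent_b, prof$exponent_b, tolerance = 1e-12)
  expect_equal(back$inr_domain, prof$inr_domain)
  expect_equal(as.data.frame(back$fit_points), as.data.frame(prof$fit_points))

  td <- tidy(prof)
  expect_equal(td$term, c("coefficient_a", "exponent_b"))
  expect_equal(td$estimate, c(prof$coefficient_a, prof$exponent_b))
  gl <- glance(prof)
  expect_equal(gl$n_points, 4L)
  expect_gt(gl$r.squared, 0.95)
  expect_s3_class(autoplot(prof, budget_share = 3.3), "ggplot")
})

test_that("budget allocation follows the linear sharing conventions", {
  thirds <- allocate_budget(10, "thirds")
  expect_equal(nrow(thirds), 3)
  expect_equal(sum(thirds$share_percent), 10, tolerance = 1e-9)
  expect_equal(round(thirds$share_percent[1], 1), 3.3)

  half <- allocate_budget(10, "half_reference")
  expect_equal(half$share_percent, c(5, 5))

  expect_equal(allocate_budget(9, "thirds")$share_percent, rep(3, 3))
  expect_error(allocate_budget(10, "quarters"), class = "inrmu_invalid_input")
  expect_error(allocate_budget(-1, "thirds"), class = "inrmu_invalid_input")

  # shares always sum to the total for any positive total
  for (tot in c(0.5, 6, 10, 12.5)) {
    for (sc in c("thirds", "half_reference")) {
      expect_equal(sum(allocate_budget(tot, sc)$share_percent), tot,
                   tolerance = 1e-9)
    }
  }
  # quadrature of equal thirds is below the linear total
  expect_lt(budget_quadrature(thirds$share_percent), 10)
})

test_that("budget check uses a strict inequality", {
  expect_true(check_budget(3.2, 3.3)$pass)
  expect_equal(check_budget(3.2, 3.3)$margin, 0.1, tolerance = 1e-9)
  expect_false(check_budget(3.3, 3.3)$pass)
  expect_false(check_budget(9.8, 3.3)$pass)
  expect_lt(check_budget(9.8, 3.3)$margin, 0)
})
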